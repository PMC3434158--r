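#' Number of combinations, exact
#'
#' The number of distinct k-element subsets of n items, n! / (k! (n-k)!),
#' computed by stepwise exact multiplication/division (every intermediate is
#' an integer, so the result is exact for all sizes used here).
#'
#' @param n Non-negative integer.
#' @param k Non-negative integer, at most `n`.
#' @return The binomial coefficient as a (integer-valued) number.
#' @examples
#' n_combinations(4, 3) # 4
#' n_combinations(4, 2) # 6
#' @export
n_combinations <- function(n, k) {
  if (length(n) != 1L || length(k) != 1L || !is.numeric(n) || !is.numeric(k) ||
      is.na(n) || is.na(k) || n != round(n) || k != round(k)) {
    stop("n and k must be single integers")
  }
  if (n < 0 || k < 0) stop("n and k must be non-negative")
  if (k > n) stop("k must not exceed n (got k = ", k, ", n = ", n, ")")
  k <- min(k, n - k)
  res <- 1
  if (k > 0) {
    for (i in seq_len(k)) res <- res * (n - k + i) / i
  }
  round(res)
}

#' All k-step combinations of time steps
#'
#' Enumerates every way of choosing k of y time steps, in lexicographic
#' order. These are the candidate patterns of k-step consistent site use;
#' their number is [n_combinations]`(y, k)`.
#'
#' @param y Number of time steps surveyed.
#' @param k Level of consistency, between 2 and `y`.
#' @return A list of integer vectors, each a sorted k-subset of `1:y`.
#' @examples
#' year_combinations(4, 3) # 1-2-3, 1-2-4, 1-3-4, 2-3-4
#' @export
year_combinations <- function(y, k) {
  if (length(y) != 1L || length(k) != 1L || y != round(y) || k != round(k)) {
    stop("y and k must be single integers")
  }
  if (k < 2 || k > y) {
    stop("the consistency level k must satisfy 2 <= k <= y (got k = ", k,
         ", y = ", y, ")")
  }
  # combn enumerates subsets in lexicographic order
  combs <- utils::combn(as.integer(y), as.integer(k))
  lapply(seq_len(ncol(combs)), function(i) combs[, i])
}

#' Maximum possible instances of k-step consistency
#'
#' For each k-subset of time steps, at most `min(population size over the
#' subset)` individuals could have used the same sites throughout; summing
#' this minimum over all subsets gives the ceiling M_k against which observed
#' consistency is judged.
#'
#' @param pop_sizes Numeric vector of per-time-step population sizes (the row
#'   sums of the survey matrix).
#' @param k Level of consistency, between 2 and `length(pop_sizes)`.
#' @return M_k, a non-negative integer-valued number.
#' @examples
#' max_possible_consistency(c(9, 9, 8, 8), 2) # 49
#' max_possible_consistency(c(9, 9, 8, 8), 3) # 32
#' @export
max_possible_consistency <- function(pop_sizes, k) {
  if (anyNA(pop_sizes) || any(pop_sizes < 0)) {
    stop("population sizes must be non-negative")
  }
  y <- length(pop_sizes)
  if (length(k) != 1L || k != round(k) || k < 2 || k > y) {
    stop("the consistency level k must satisfy 2 <= k <= y (got k = ", k,
         ", y = ", y, ")")
  }
  pop_sizes <- as.numeric(pop_sizes)
  cm <- utils::combn(y, as.integer(k))
  sub <- matrix(pop_sizes[cm], nrow = nrow(cm))
  sum(do.call(pmin, lapply(seq_len(nrow(sub)), function(i) sub[i, ])))
}
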