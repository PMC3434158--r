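#' Random survey matrix for group-occupied sites
#'
#' Draws every cell independently as a uniform integer on
#' `[count_range[1], count_range[2]]`, emulating repeated surveys of a
#' region where any number of individuals can occupy a site in any time
#' step. Uses the current RNG state; seed the stream with [set.seed] for
#' reproducibility.
#'
#' @param n_sites Number of sites (columns).
#' @param n_steps Number of time steps (rows).
#' @param count_range Length-2 integer vector, inclusive bounds for the
#'   per-site per-step counts.
#' @return A survey matrix of dimension `n_steps` x `n_sites`.
#' @examples
#' set.seed(1)
#' m <- random_group_matrix(50, 5, c(0, 250))
#' @export
random_group_matrix <- function(n_sites, n_steps, count_range = c(0, 250)) {
  if (length(count_range) != 2 || count_range[1] > count_range[2]) {
    stop("count_range must be c(low, high) with low <= high")
  }
  if (any(count_range < 0)) stop("counts must be non-negative")
  span <- count_range[2] - count_range[1] + 1
  vals <- count_range[1] +
    sample.int(span, n_sites * n_steps, replace = TRUE) - 1L
  as_survey_matrix(matrix(vals, nrow = n_steps, ncol = n_sites))
}

#' Random survey matrix for a territorial species
#'
#' For each time step draws a population size N uniformly on
#' `[pop_range[1], pop_range[2]]` and places the N territory holders on N
#' distinct, uniformly chosen sites (territories), giving a binary
#' presence/absence matrix whose row sums equal the drawn population sizes.
#'
#' @param n_sites Number of territories; must be at least `pop_range[2]`.
#' @param n_steps Number of time steps.
#' @param pop_range Length-2 integer vector, inclusive bounds on the
#'   per-step population size.
#' @return A binary survey matrix of dimension `n_steps` x `n_sites`.
#' @examples
#' set.seed(1)
#' m <- random_territorial_matrix(100, 5, c(25, 75))
#' range(rowSums(m)) # within pop_range
#' @export
random_territorial_matrix <- function(n_sites, n_steps,
                                      pop_range = c(25, 75)) {
  if (length(pop_range) != 2 || pop_range[1] > pop_range[2]) {
    stop("pop_range must be c(low, high) with low <= high")
  }
  if (pop_range[1] < 0) stop("population sizes must be non-negative")
  if (pop_range[2] > n_sites) {
    stop("cannot place ", pop_range[2], " territory holders on ", n_sites,
         " territories")
  }
  m <- matrix(0L, nrow = n_steps, ncol = n_sites)
  for (t in seq_len(n_steps)) {
    n <- pop_range[1] + sample.int(pop_range[2] - pop_range[1] + 1, 1) - 1L
    if (n > 0) m[t, sample.int(n_sites, n)] <- 1L
  }
  as_survey_matrix(m)
}

#' Thin a survey matrix by random survey error
#'
#' Simulates imperfect detection: in each time step independently, a
#' fraction `error_rate` of the individuals present (rounded half-up) is
#' selected uniformly without replacement from the pooled individuals of
#' that step and removed from their sites. The observed row sum is exactly
#' `N_t - round(error_rate * N_t)`. Binary presence/absence matrices go
#' through the same individual-level mechanism: a missed territory holder
#' zeroes its cell.
#'
#' @param m A survey matrix (the true population).
#' @param error_rate Proportion of individuals missed per time step, in
#'   `[0, 1)`.
#' @return The observed survey matrix after thinning.
#' @examples
#' set.seed(1)
#' m <- dc_example_matrix("groups")
#' rowSums(apply_survey_error(m, 0.5))
#' @export
apply_survey_error <- function(m, error_rate) {
  m <- as_survey_matrix(m)
  if (length(error_rate) != 1 || is.na(error_rate) ||
      error_rate < 0 || error_rate >= 1) {
    stop("error_rate must be a single proportion in [0, 1)")
  }
  if (error_rate == 0) return(m)
  out <- m
  s <- ncol(m)
  for (t in seq_len(nrow(m))) {
    n_t <- sum(m[t, ])
    miss <- floor(error_rate * n_t + 0.5) # round half-up
    if (miss > 0) {
      pool <- rep.int(seq_len(s), m[t, ]) # one entry per individual
      removed <- pool[sample.int(n_t, miss)]
      out[t, ] <- m[t, ] - tabulate(removed, nbins = s)
    }
  }
  out
}
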