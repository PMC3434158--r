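#' Observed instances of consistency at a single site
#'
#' A site with counts over y time steps contributes one instance of k-step
#' consistency for every individual "slot" occupied in exactly k steps. With
#' the counts sorted in non-increasing order c(1) >= ... >= c(y) (and
#' c(y+1) := 0), the number of slots occupied in exactly k steps is
#' c(k) - c(k+1): the k-th largest count is the number of slots filled at
#' least k times, so differencing the sorted counts isolates the exactly-k
#' instances. A site visited in only one time step contributes nothing --
#' single use is not consistent use -- so levels run k = 2...y. Binary
#' presence/absence data are the special case where every count is 0 or 1.
#'
#' @param site_counts Non-negative integer vector: the site's count in each
#'   of y >= 2 time steps.
#' @return Named integer vector of instances, names `"2"` ... `"y"`.
#' @examples
#' site_observed_consistency(c(3, 2, 1, 0)) # one 2-step, one 3-step instance
#' site_observed_consistency(c(3, 3, 3, 3)) # three 4-step instances
#' @export
site_observed_consistency <- function(site_counts) {
  if (anyNA(site_counts) || any(site_counts < 0)) {
    stop("site counts must be non-negative")
  }
  if (any(site_counts != round(site_counts))) {
    stop("site counts must be whole numbers")
  }
  y <- length(site_counts)
  if (y < 2) stop("at least 2 time steps are required")
  s <- c(sort(site_counts, decreasing = TRUE), 0)
  out <- as.integer(s[2:y] - s[3:(y + 1)])
  names(out) <- 2:y
  out
}

#' Observed instances of consistency for a region
#'
#' Sums [site_observed_consistency] over all sites of a survey matrix,
#' giving the raw observed instances O_k of k-step consistent site use for
#' each level k = 2...y.
#'
#' @param m A survey matrix (see [as_survey_matrix]).
#' @return Named integer vector O_k, names `"2"` ... `"y"`, with the per-site
#'   contributions (levels x sites) attached as attribute `"per_site"`.
#' @examples
#' observed_consistency(dc_example_matrix("territorial")) # 7, 4, 1
#' @export
observed_consistency <- function(m) {
  m <- as_survey_matrix(m)
  y <- nrow(m)
  # sort every column in non-increasing order with a single order() call
  srt <- matrix(m[order(col(m), -m)], nrow = y)
  padded <- rbind(srt, 0L)
  per_site <- srt[2:y, , drop = FALSE] - padded[3:(y + 1), , drop = FALSE]
  storage.mode(per_site) <- "integer"
  dimnames(per_site) <- list(2:y, colnames(m))
  out <- as.integer(rowSums(per_site))
  names(out) <- 2:y
  attr(out, "per_site") <- per_site
  out
}

#' Adjust observed consistency for nesting in higher levels
#'
#' A site used consistently over k+q steps also realises every k-step
#' pattern nested inside: choose(k+q, k) of them. The adjusted count
#' comparable to the combinatorial maximum M_k is therefore
#' `sum over q = 0...(y-k) of O_(k+q) * choose(k+q, k)`; the top level
#' k = y is unchanged. Equivalently, the adjusted O_k is the sum over all
#' sites and all k-subsets of time steps of the minimum count in the subset
#' (the identity the test suite checks by brute-force enumeration).
#'
#' @param obs Named vector of raw observed instances O_k covering
#'   k = 2...y (as returned by [observed_consistency]).
#' @param y Number of time steps.
#' @return Named numeric vector of adjusted counts, names `"2"` ... `"y"`.
#' @examples
#' adjust_observed(c(`2` = 7, `3` = 4, `4` = 1), y = 4) # 25, 8, 1
#' @export
adjust_observed <- function(obs, y) {
  ks <- 2:y
  if (!all(as.character(ks) %in% names(obs))) {
    stop("obs must be a named vector covering levels k = 2...y")
  }
  o <- as.numeric(obs[as.character(ks)])
  out <- vapply(ks, function(k) {
    higher <- k:y
    sum(o[higher - 1L] * vapply(higher, n_combinations, numeric(1), k = k))
  }, numeric(1))
  names(out) <- ks
  out
}

#' Distributional consistency of a survey matrix
#'
#' Fits the distributional consistency (DC) index to a site-by-time survey
#' matrix of counts of unmarked individuals. For each level of consistency
#' k = 2...y the index compares the adjusted observed instances of k-step
#' consistent site use ([observed_consistency], [adjust_observed]) with the
#' combinatorial maximum achievable given the observed population sizes
#' ([max_possible_consistency]); DC is the mean of the per-level ratios
#' R_k = adjusted O_k / M_k. DC is 1 when every time step occupies exactly
#' the same sites with the same counts (up to population-size changes), and
#' 0 when no site is used in more than one time step.
#'
#' Levels with M_k = 0 (possible when enough time steps record zero
#' individuals) carry no information -- no consistency was possible -- and
#' are excluded from the mean; they are reported in `levels_excluded`. A
#' matrix with no individuals at all has no defined DC and raises an error:
#' "no animals observed" is a different finding from "completely
#' inconsistent".
#'
#' @param x A survey matrix: rows = time steps, columns = sites
#'   (see [as_survey_matrix]).
#' @param max_steps Guard on the number of time steps: the y-choose-k subset
#'   enumeration grows combinatorially, so matrices with more than
#'   `max_steps` rows are refused. Raise it deliberately for long series.
#' @return An object of class `"dc"`: a list with elements
#'   \describe{
#'     \item{dc}{the DC index in \[0, 1\].}
#'     \item{y, n_sites}{matrix dimensions.}
#'     \item{levels}{the consistency levels 2...y.}
#'     \item{M, O, O_adj, R}{per-level maximum, raw observed, adjusted
#'       observed, and ratio (named by level; R is NA for excluded levels).}
#'     \item{levels_excluded}{levels with M_k = 0, excluded from the mean.}
#'     \item{pop_sizes}{per-time-step population sizes (row sums).}
#'   }
#' @examples
#' fit <- dc(dc_example_matrix("territorial"))
#' fit
#' summary(fit)
#' coef(fit)
#' @seealso [summary.dc], [aggregate_sites], [simulate_dispersal]
#' @export
dc <- function(x, max_steps = 25) {
  m <- as_survey_matrix(x)
  y <- nrow(m)
  if (y > max_steps) {
    stop("matrix has ", y, " time steps; subset enumeration is refused above ",
         "max_steps = ", max_steps, " (raise max_steps to override)")
  }
  pop <- as.numeric(rowSums(m))
  if (all(pop == 0)) {
    stop("DC is undefined for an all-zero survey matrix: no individuals ",
         "were observed, so no level of consistency was possible")
  }
  ks <- 2:y
  M <- vapply(ks, function(k) max_possible_consistency(pop, k), numeric(1))
  names(M) <- ks
  O <- observed_consistency(m)
  per_site <- attr(O, "per_site")
  attr(O, "per_site") <- NULL
  O_adj <- adjust_observed(O, y)
  include <- M > 0
  if (!any(include)) {
    stop("DC is undefined: no level of consistency was possible (fewer ",
         "than two time steps observed any individuals)")
  }
  R <- rep(NA_real_, length(ks))
  names(R) <- ks
  R[include] <- O_adj[include] / M[include]
  structure(
    list(
      dc = mean(R[include]),
      y = y,
      n_sites = ncol(m),
      levels = ks,
      M = M,
      O = O,
      O_adj = O_adj,
      R = R,
      levels_excluded = ks[!include],
      pop_sizes = pop,
      per_site = per_site,
      call = match.call()
    ),
    class = "dc"
  )
}

#' @rdname dc
#' @export
distributional_consistency <- dc
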