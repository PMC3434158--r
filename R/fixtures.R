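#' Built-in example survey matrices
#'
#' Four small survey matrices used throughout the documentation and tests:
#' \describe{
#'   \item{territorial}{4 years x 16 territories, presence/absence, with
#'     yearly populations 9, 9, 8, 8; the standard worked example for the
#'     DC calculation.}
#'   \item{consistent}{4 individuals occupying the same 4 of 16 sites in
#'     all 4 years; DC = 1.}
#'   \item{inconsistent}{4 individuals occupying a fresh set of sites every
#'     year, so no site is reused; DC = 0.}
#'   \item{groups}{4 years x 16 sites with multiple individuals per site,
#'     illustrating group occupancy counting.}
#' }
#'
#' @param name Which example to return.
#' @return A survey matrix with time-step rownames `"1"`... and site
#'   colnames `"1"`...
#' @examples
#' dc(dc_example_matrix("consistent"))$dc # 1
#' @export
dc_example_matrix <- function(name = c("territorial", "consistent",
                                       "inconsistent", "groups")) {
  name <- match.arg(name)
  m <- switch(
    name,
    territorial = rbind(
      c(1, 0, 0, 0, 1, 1, 1, 1, 0, 0, 0, 1, 1, 1, 0, 1),
      c(0, 1, 0, 0, 1, 1, 0, 0, 1, 1, 0, 1, 1, 0, 1, 1),
      c(0, 0, 1, 0, 0, 0, 1, 0, 1, 0, 1, 1, 0, 1, 1, 1),
      c(0, 0, 0, 1, 0, 0, 0, 1, 0, 1, 1, 0, 1, 1, 1, 1)
    ),
    consistent = rbind(
      c(1, 1, 1, 1, rep(0, 12)),
      c(1, 1, 1, 1, rep(0, 12)),
      c(1, 1, 1, 1, rep(0, 12)),
      c(1, 1, 1, 1, rep(0, 12))
    ),
    inconsistent = rbind(
      c(1, 0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0),
      c(0, 1, 0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1, 0, 0),
      c(0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1, 0),
      c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1)
    ),
    groups = rbind(
      c(1, 0, 0, 0, 1, 2, 1, 2, 0, 0, 0, 3, 1, 2, 0, 3),
      c(0, 2, 0, 0, 2, 1, 0, 0, 2, 3, 0, 2, 3, 0, 2, 3),
      c(0, 0, 3, 0, 0, 0, 3, 0, 1, 0, 2, 1, 0, 3, 2, 3),
      c(0, 0, 0, 1, 0, 0, 0, 2, 0, 1, 3, 0, 2, 2, 2, 3)
    )
  )
  as_survey_matrix(m, time_labels = seq_len(nrow(m)),
                   site_labels = seq_len(ncol(m)))
}
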