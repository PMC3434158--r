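#' Validate and coerce a survey matrix
#'
#' A survey matrix records the number of individuals observed at each site
#' (columns) in each time step (rows); the regional population size at each
#' time step is the corresponding row sum. Counts must be non-negative
#' integers -- they are counts of individuals and are never rounded -- and at
#' least two time steps are required, since consistency of site use is
#' undefined for a single survey.
#'
#' @param x A numeric matrix or data frame of counts, rows = time steps,
#'   columns = sites.
#' @param time_labels Optional character vector of row (time step) labels.
#' @param site_labels Optional character vector of column (site) labels.
#' @return An integer matrix with dimnames set from the labels (existing
#'   dimnames are kept when no labels are supplied).
#' @examples
#' m <- as_survey_matrix(rbind(c(1, 0, 2), c(1, 1, 0)))
#' rowSums(m) # per-step population sizes
#' @export
as_survey_matrix <- function(x, time_labels = NULL, site_labels = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("a survey matrix must be a numeric matrix or data frame of counts")
  }
  if (nrow(x) < 2) {
    stop("a survey matrix needs at least 2 time steps (rows); got ", nrow(x))
  }
  if (ncol(x) < 1) {
    stop("a survey matrix needs at least 1 site (column)")
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop("survey counts must all be finite and non-missing")
  }
  if (any(x < 0)) {
    stop("survey counts must be non-negative")
  }
  if (any(x != round(x))) {
    stop("survey counts must be whole numbers (counts of individuals); ",
         "non-integer cells are rejected, not rounded")
  }
  storage.mode(x) <- "integer"
  if (!is.null(time_labels)) {
    stopifnot(length(time_labels) == nrow(x))
    rownames(x) <- as.character(time_labels)
  }
  if (!is.null(site_labels)) {
    stopifnot(length(site_labels) == ncol(x))
    colnames(x) <- as.character(site_labels)
  }
  x
}
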