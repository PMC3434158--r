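#' Aggregate sites into coarser spatial units
#'
#' Coarsens the grain of the analysis by pooling the counts of member sites
#' into aggregated sites. Row sums (per-step population sizes) are preserved
#' exactly: aggregation moves individuals between columns, never in or out
#' of the region. With every site in a single group the matrix collapses to
#' one column and DC is 1 whenever each time step observed at least one
#' individual.
#'
#' @param m A survey matrix.
#' @param grouping Assignment of each original site (column) to an
#'   aggregated site: a vector of group labels, one per column of `m`
#'   (character, factor, or integer). Groups keep the order in which they
#'   first appear.
#' @return A survey matrix with one column per group.
#' @examples
#' m <- dc_example_matrix("territorial")
#' pairs <- rep(1:8, each = 2)
#' a <- aggregate_sites(m, pairs)
#' rowSums(a) == rowSums(m) # individuals conserved
#' @export
aggregate_sites <- function(m, grouping) {
  m <- as_survey_matrix(m)
  if (length(grouping) != ncol(m)) {
    stop("grouping must assign every site: expected ", ncol(m),
         " labels, got ", length(grouping))
  }
  if (anyNA(grouping)) stop("grouping must not contain missing assignments")
  g <- factor(grouping, levels = unique(grouping))
  out <- t(rowsum(t(m), group = g, reorder = FALSE))
  rownames(out) <- rownames(m)
  as_survey_matrix(out)
}

#' Restrict a survey matrix to a sub-region
#'
#' Narrows the extent of the analysis to a subset of sites. Population sizes
#' are recomputed from the retained columns: the region is the assemblage of
#' sites over which DC is defined, so individuals observed outside the
#' sub-region are outside its population.
#'
#' @param m A survey matrix.
#' @param sites Non-empty vector of column indices or site labels to keep.
#' @return The column-restricted survey matrix.
#' @examples
#' m <- dc_example_matrix("territorial")
#' dc(subset_region(m, 16))$dc # one always-occupied site: DC = 1
#' @export
subset_region <- function(m, sites) {
  m <- as_survey_matrix(m)
  if (length(sites) == 0) stop("sites must select at least one column")
  if (is.character(sites)) {
    missing <- setdiff(sites, colnames(m))
    if (length(missing)) {
      stop("unknown site labels: ", paste(missing, collapse = ", "))
    }
  } else if (any(sites < 1 | sites > ncol(m))) {
    stop("site indices must be between 1 and ", ncol(m))
  }
  m[, sites, drop = FALSE]
}

#' DC across a ladder of spatial scales
#'
#' Recomputes DC over a sequence of spatial scales: either coarsening grain
#' (a list of site groupings for [aggregate_sites]) or changing extent (a
#' list of site subsets for [subset_region]). One curve point is produced
#' per element, in order. The shape of the resulting scale-versus-DC curve
#' -- e.g. where it rises sharply towards 1 as sites merge -- is the object
#' of interest when probing the scales at which movement decisions operate.
#'
#' @param m A survey matrix.
#' @param scales A list: each element a grouping vector (`type = "grain"`)
#'   or a site subset (`type = "extent"`).
#' @param type Whether elements coarsen the grain or change the extent.
#' @return A data frame of class `"dc_scale_curve"` with columns `scale`
#'   (number of sites in the derived matrix), `dc`, and `levels_excluded`
#'   (comma-separated, empty when none).
#' @examples
#' m <- dc_example_matrix("territorial")
#' dc_scale_curve(m, list(rep(1:8, each = 2), rep(1, 16)), type = "grain")
#' @export
dc_scale_curve <- function(m, scales, type = c("grain", "extent")) {
  type <- match.arg(type)
  m <- as_survey_matrix(m)
  if (!is.list(scales)) stop("scales must be a list")
  rows <- lapply(scales, function(sc) {
    mm <- if (type == "grain") aggregate_sites(m, sc) else subset_region(m, sc)
    fit <- dc(mm)
    data.frame(scale = ncol(mm), dc = fit$dc,
               levels_excluded = paste(fit$levels_excluded, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) {
    out <- data.frame(scale = numeric(0), dc = numeric(0),
                      levels_excluded = character(0))
  }
  class(out) <- c("dc_scale_curve", "data.frame")
  attr(out, "type") <- type
  out
}

#' @export
plot.dc_scale_curve <- function(x, ...) {
  graphics::plot(x$scale, x$dc, type = "b", ylim = c(0, 1),
                 xlab = "number of sites", ylab = "DC", ...)
  invisible(x)
}
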