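#' @export
print.dc <- function(x, digits = 4, ...) {
  cat("Distributional consistency\n")
  cat("  ", x$y, " time steps x ", x$n_sites, " sites; population sizes: ",
      paste(x$pop_sizes, collapse = ", "), "\n", sep = "")
  cat("  DC = ", format(x$dc, digits = digits), "\n", sep = "")
  if (length(x$levels_excluded)) {
    cat("  levels excluded (no consistency possible): k = ",
        paste(x$levels_excluded, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Per-level decomposition of a DC fit
#'
#' @param object A `"dc"` object from [dc].
#' @param ... Unused.
#' @return A `"summary.dc"` object: the per-level table (k, M_k, O_k,
#'   adjusted O_k, R_k) plus the DC value.
#' @export
summary.dc <- function(object, ...) {
  tab <- data.frame(
    k = object$levels,
    M = as.numeric(object$M),
    O = as.numeric(object$O),
    O_adj = as.numeric(object$O_adj),
    R = as.numeric(object$R),
    row.names = NULL
  )
  structure(list(table = tab, dc = object$dc, y = object$y,
                 n_sites = object$n_sites,
                 levels_excluded = object$levels_excluded),
            class = "summary.dc")
}

#' @export
print.summary.dc <- function(x, digits = 4, ...) {
  cat("Distributional consistency: per-level decomposition\n")
  cat("  (M = maximum possible instances, O = observed, O_adj = observed\n")
  cat("   adjusted for nesting in higher levels, R = O_adj / M)\n\n")
  tab <- x$table
  tab$R <- round(tab$R, digits)
  print(tab, row.names = FALSE)
  cat("\nDC =", format(x$dc, digits = digits), "\n")
  if (length(x$levels_excluded)) {
    cat("Levels excluded (M_k = 0): k =",
        paste(x$levels_excluded, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.dc <- function(object, ...) {
  c(stats::setNames(as.numeric(object$R),
                    paste0("R", object$levels)),
    DC = object$dc)
}

#' @export
as.data.frame.dc <- function(x, ...) {
  summary(x)$table
}

#' Plot the per-level consistency ratios
#'
#' Bar plot of R_k against the level of consistency k, with the DC value
#' (their mean) drawn as a horizontal reference line.
#'
#' @param x A `"dc"` object.
#' @param ... Passed to [graphics::barplot].
#' @export
plot.dc <- function(x, ...) {
  r <- as.numeric(x$R)
  r[is.na(r)] <- 0
  graphics::barplot(r, names.arg = x$levels, ylim = c(0, 1),
                    xlab = "level of consistency k",
                    ylab = expression(R[k]), ...)
  graphics::abline(h = x$dc, lty = 2)
  invisible(x)
}
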