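#' Read a survey matrix from delimited text
#'
#' Reads a site-by-time survey matrix from a CSV/TSV file laid out with
#' rows = time steps and columns = sites, optionally with a header row of
#' site labels and a first column of time-step labels. Validation is
#' strict: rows must all have the same number of fields and every cell must
#' be a plain non-negative integer (decimal point only, no thousands
#' separators); violations are reported with their line number and column.
#' Lines starting with `#` are ignored, so files written by the
#' command-line interface (which embeds provenance comments) re-read
#' cleanly.
#'
#' @param path File to read.
#' @param sep Field delimiter.
#' @param header Whether the first non-comment line holds site labels.
#' @param time_labels Whether the first column holds time-step labels.
#' @param transpose If `TRUE`, the file is laid out sites-by-time and is
#'   transposed after reading (labels are swapped accordingly).
#' @param missing_as_zero If `TRUE`, blank cells are read as 0 (surveyed,
#'   none seen). By default a blank cell is an error: DC has no notion of
#'   an unsurveyed site-time, and silently treating one as zero would bias
#'   the observed consistency.
#' @return A survey matrix (see [as_survey_matrix]).
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write_survey_matrix(dc_example_matrix("territorial"), f)
#' m <- read_survey_matrix(f)
#' rowSums(m) # 9, 9, 8, 8
#' @export
read_survey_matrix <- function(path, sep = ",", header = TRUE,
                               time_labels = TRUE, transpose = FALSE,
                               missing_as_zero = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", raw) & nzchar(trimws(raw))
  line_no <- which(keep)
  lines <- raw[keep]
  if (length(lines) < 2) stop("file has fewer than 2 data lines: ", path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  # strsplit drops trailing empty fields; restore them from the separator
  # count so a trailing blank cell is a blank cell, not a ragged row
  n_sep <- (nchar(lines) - nchar(gsub(sep, "", lines, fixed = TRUE))) %/%
    nchar(sep)
  fields <- mapply(function(f, n) c(f, rep("", n + 1L - length(f))),
                   fields, n_sep, SIMPLIFY = FALSE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1) {
    bad <- which(widths != widths[1])[1]
    stop("ragged rows: line ", line_no[bad], " has ", widths[bad],
         " fields but line ", line_no[1], " has ", widths[1])
  }

  site_lab <- NULL
  if (header) {
    site_lab <- trimws(fields[[1]])
    fields <- fields[-1]
    line_no <- line_no[-1]
  }
  time_lab <- NULL
  if (time_labels) {
    time_lab <- vapply(fields, function(f) trimws(f[1]), character(1))
    fields <- lapply(fields, `[`, -1)
    if (header) site_lab <- site_lab[-1]
  }
  if (length(fields) < 2) {
    stop("a survey matrix needs at least 2 time-step rows")
  }

  parse_row <- function(f, ln) {
    f <- trimws(f)
    if (missing_as_zero) f[!nzchar(f)] <- "0"
    bad <- !grepl("^[0-9]+$", f)
    if (any(bad)) {
      j <- which(bad)[1]
      stop("line ", ln, ", column ", j, ": cell '", f[j],
           "' is not a non-negative integer count")
    }
    as.integer(f)
  }
  rows <- mapply(parse_row, fields, line_no, SIMPLIFY = FALSE)
  m <- do.call(rbind, rows)
  if (transpose) {
    m <- t(m)
    tmp <- site_lab
    site_lab <- time_lab
    time_lab <- tmp
  }
  as_survey_matrix(m, time_labels = time_lab, site_labels = site_lab)
}

#' Write a survey matrix as delimited text
#'
#' Writes the matrix with a header row of site labels and a first column of
#' time-step labels (defaulting to 1...y and 1...S when the matrix has no
#' dimnames), so that [read_survey_matrix] with default options recovers it
#' exactly.
#'
#' @param m A survey matrix.
#' @param path Output file.
#' @param sep Field delimiter.
#' @param comment Optional character vector of provenance lines written at
#'   the top of the file, each prefixed with `#`.
#' @return `path`, invisibly.
#' @export
write_survey_matrix <- function(m, path, sep = ",", comment = NULL) {
  m <- as_survey_matrix(m)
  tl <- rownames(m)
  if (is.null(tl)) tl <- as.character(seq_len(nrow(m)))
  sl <- colnames(m)
  if (is.null(sl)) sl <- as.character(seq_len(ncol(m)))
  lines <- c(
    if (!is.null(comment)) paste0("# ", comment),
    paste(c("time", sl), collapse = sep),
    vapply(seq_len(nrow(m)), function(i) {
      paste(c(tl[i], m[i, ]), collapse = sep)
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Export a DC decomposition
#'
#' Writes the per-level decomposition and the DC value of a fitted `"dc"`
#' object as CSV (per-level table with the DC in a comment header), JSON
#' (all fields, machine-readable), or a human-readable text report.
#'
#' @param fit A `"dc"` object from [dc].
#' @param path Output file.
#' @param format Output format.
#' @param comment Optional extra provenance lines (CSV/text only).
#' @return `path`, invisibly.
#' @export
write_dc_result <- function(fit, path, format = c("csv", "json", "text"),
                            comment = NULL) {
  stopifnot(inherits(fit, "dc"))
  format <- match.arg(format)
  if (format == "json") {
    obj <- list(
      dc = fit$dc, y = fit$y, n_sites = fit$n_sites, levels = fit$levels,
      M = as.list(fit$M), O = as.list(fit$O), O_adj = as.list(fit$O_adj),
      R = as.list(fit$R), levels_excluded = fit$levels_excluded,
      pop_sizes = fit$pop_sizes
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         na = "null")
  } else if (format == "csv") {
    tab <- summary(fit)$table
    lines <- c(
      if (!is.null(comment)) paste0("# ", comment),
      paste0("# dc,", format(fit$dc, digits = 15)),
      paste(names(tab), collapse = ","),
      vapply(seq_len(nrow(tab)), function(i) {
        paste(unlist(tab[i, ]), collapse = ",")
      }, character(1))
    )
    writeLines(lines, path)
  } else {
    txt <- c(
      if (!is.null(comment)) paste0("# ", comment),
      utils::capture.output(print(summary(fit)))
    )
    writeLines(txt, path)
  }
  invisible(path)
}
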