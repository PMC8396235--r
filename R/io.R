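#' Read a kinetic trace from delimited text
#'
#' Parses a two-column delimited text file (time in seconds, signal) with an
#' optional header line, in comma or tab dialect. Malformed rows are
#' reported with their line numbers.
#'
#' @param path File path.
#' @param kind Signal kind of the trace, `"luminescence"` or `"absorbance"`.
#' @param dialect `"auto"` (default; sniffs the first data line), `"comma"`
#'   or `"tab"`.
#' @param conditions Optional [assay_conditions()] to attach.
#' @return A [kinetic_trace()].
#' @export
read_trace <- function(path, kind = c("luminescence", "absorbance"),
                       dialect = c("auto", "comma", "tab"),
                       conditions = NULL) {
  kind <- match.arg(kind)
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) < 2L) stop("file has fewer than two data lines: ", path,
                              call. = FALSE)
  sep <- switch(dialect,
                comma = ",",
                tab = "\t",
                auto = if (grepl(",", lines[keep[1]], fixed = TRUE)) "," else "\t")

  parse_row <- function(line) {
    fields <- trimws(strsplit(line, sep, fixed = TRUE)[[1]])
    suppressWarnings(as.numeric(fields))
  }
  rows <- lapply(lines[keep], parse_row)

  # optional header: first line whose fields are not all numeric
  start <- 1L
  if (anyNA(rows[[1]])) start <- 2L
  if (length(keep) - start + 1L < 2L)
    stop("file has fewer than two data rows: ", path, call. = FALSE)
  rows <- rows[start:length(rows)]
  lineno <- keep[start:length(keep)]

  bad <- vapply(rows, function(r) length(r) < 2L || anyNA(r[1:2]), logical(1))
  if (any(bad))
    stop("malformed rows (need two numeric columns) at line(s): ",
         paste(lineno[bad], collapse = ", "), call. = FALSE)
  t <- vapply(rows, `[`, numeric(1), 1L)
  y <- vapply(rows, `[`, numeric(1), 2L)
  if (any(diff(t) <= 0))
    stop("time column must be strictly increasing in ", path, call. = FALSE)
  kinetic_trace(t = t, y = y, kind = kind, conditions = conditions)
}

#' Write a kinetic trace to delimited text
#'
#' @param trace A [kinetic_trace()].
#' @param path Output path.
#' @param dialect `"comma"` or `"tab"`.
#' @param header Write a `t,y` header line?
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, dialect = c("comma", "tab"),
                        header = TRUE) {
  stopifnot(inherits(trace, "kinetic_trace"))
  dialect <- match.arg(dialect)
  sep <- if (dialect == "comma") "," else "\t"
  con <- file(path, "w")
  on.exit(close(con))
  if (header) writeLines(paste("t", "y", sep = sep), con)
  writeLines(paste(format(trace$t, digits = 17, trim = TRUE, scientific = FALSE),
                   format(trace$y, digits = 17, trim = TRUE),
                   sep = sep), con)
  invisible(path)
}
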