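#' Signal matrices
#'
#' A signal matrix is a numeric matrix with row identifiers (genes or
#' enhancers), column identifiers (cell types or bins) and a units tag
#' (`"count"`, `"RPM"`, `"RPKM"` or `"zscore"`). It is the common currency
#' between quantification, ROC evaluation and clustering.
#'
#' @param values numeric matrix, no missing values.
#' @param row_ids,col_ids identifier vectors matching the matrix dimensions.
#' @param units one of `"count"`, `"RPM"`, `"RPKM"`, `"zscore"`.
#' @return the matrix with dimnames set and a `units` attribute, classed
#'   `"signal_matrix"`.
#' @export
signal_matrix <- function(values, row_ids = rownames(values),
                          col_ids = colnames(values),
                          units = c("count", "RPM", "RPKM", "zscore")) {
  units <- match.arg(units)
  values <- as.matrix(values)
  if (anyNA(values)) stop("signal matrix must not contain missing values")
  if (length(row_ids) != nrow(values) || length(col_ids) != ncol(values))
    stop("row/col id lengths do not match matrix dimensions")
  dimnames(values) <- list(as.character(row_ids), as.character(col_ids))
  attr(values, "units") <- units
  class(values) <- c("signal_matrix", class(values))
  values
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat(sprintf("<signal_matrix> %d x %d [%s]\n", nrow(x), ncol(x),
              attr(x, "units")))
  y <- x
  attr(y, "units") <- NULL
  class(y) <- "matrix"
  print(utils::head(y, 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

#' Write / read a signal matrix as TSV
#'
#' The file has a header row of column ids (first cell = `id`), one row per
#' row id. Values are written with enough digits that a round-trip is exact
#' to at least 10 significant digits. A `# units:` comment line records the
#' units tag.
#'
#' @param mat a [signal_matrix()] (any numeric matrix with dimnames works).
#' @param path file path.
#' @export
write_matrix <- function(mat, path) {
  units <- attr(mat, "units")
  if (is.null(units)) units <- "count"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: ", units), con)
  writeLines(paste(c("id", colnames(mat)), collapse = "\t"), con)
  if (nrow(mat) > 0) {
    vals <- format(unclass(mat), digits = 15, scientific = FALSE, trim = TRUE)
    lines <- apply(cbind(rownames(mat), vals), 1,
                   paste, collapse = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  lines <- readLines(path)
  units <- "count"
  if (length(lines) && startsWith(lines[1], "# units: ")) {
    units <- sub("^# units: ", "", lines[1])
    lines <- lines[-1]
  }
  if (length(lines) == 0) stop("matrix file has no header row")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  body <- lines[-1]
  ncolumns <- length(header)
  if (length(body) == 0) {
    m <- matrix(numeric(0), nrow = 0, ncol = ncolumns - 1,
                dimnames = list(NULL, header[-1]))
    return(signal_matrix(m, character(0), header[-1], units))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(fields) != ncolumns))
    stop("matrix parse error: ragged row at line ",
         which(lengths(fields) != ncolumns)[1] + 2)
  ids <- vapply(fields, `[[`, "", 1L)
  vals <- matrix(as.numeric(unlist(lapply(fields, `[`, -1L))),
                 nrow = length(body), ncol = ncolumns - 1, byrow = TRUE)
  signal_matrix(vals, ids, header[-1], units)
}
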