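#' Construct a set of genomic intervals
#'
#' Intervals are plain data frames in 0-based half-open coordinates
#' (`start` inclusive, `end` exclusive), the BED convention, with strand
#' `"+"`, `"-"` or `"."` (unstranded). All region types in the package
#' (promoters, NDR windows, enhancers, genome bins) use this representation.
#'
#' @param chrom character vector of chromosome names.
#' @param start integer vector, 0-based inclusive.
#' @param end integer vector, 0-based exclusive; must satisfy `start < end`.
#' @param strand character vector in `c("+", "-", ".")`; recycled.
#' @param ... further equal-length columns (e.g. `name`, `score`) carried
#'   through unchanged.
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `strand`
#'   plus any extra columns.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".", ...) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   strand = rep_len(as.character(strand), length(chrom)),
                   ...,
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  if (any(is.na(df$start)) || any(is.na(df$end)))
    stop("interval coordinates must be non-missing integers")
  bad <- which(df$start < 0 | df$start >= df$end)
  if (length(bad))
    stop("invalid interval(s) at row(s) ", paste(utils::head(bad, 5), collapse = ", "),
         ": need 0 <= start < end")
  if (any(!nzchar(df$chrom))) stop("chromosome names must be non-empty")
  invisible(df)
}

#' Read a BED3/BED6 file
#'
#' Coordinates are BED-native 0-based half-open and are kept as-is. Column 6
#' is used as the strand when present; `track` and `browser` lines are
#' skipped. Malformed records (non-integer coordinates, `start >= end`)
#' raise an error naming the offending line.
#'
#' @param path path to a BED file with >= 3 tab-separated columns.
#' @return interval data frame (see [genomic_intervals()]); BED columns 4-5
#'   become `name` and `score` when present.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser)([ \t]|$)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0)
    return(genomic_intervals(character(), numeric(), numeric()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3))
    stop("BED parse error at line ", lineno[which(nf < 3)[1]],
         ": fewer than 3 tab-separated columns")
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end) | start < 0 | start >= end)
  if (length(bad))
    stop("BED parse error at line ", lineno[bad[1]],
         ": invalid coordinates (need integer 0 <= start < end)")
  strand <- rep(".", length(chrom))
  has6 <- nf >= 6
  strand[has6] <- vapply(fields[has6], `[[`, "", 6L)
  strand[!strand %in% c("+", "-")] <- "."
  df <- data.frame(chrom = chrom, start = start, end = end, strand = strand,
                   stringsAsFactors = FALSE)
  if (any(nf >= 4)) {
    nm <- rep(NA_character_, length(chrom))
    nm[nf >= 4] <- vapply(fields[nf >= 4], `[[`, "", 4L)
    df$name <- nm
  }
  if (any(nf >= 5)) {
    sc <- rep(NA_character_, length(chrom))
    sc[nf >= 5] <- vapply(fields[nf >= 5], `[[`, "", 5L)
    df$score <- sc
  }
  df
}

#' Write intervals as BED
#'
#' @param df interval data frame; optional `name` and `score` columns are
#'   written as BED columns 4-5 (defaulting to `"."` and `0` when a strand
#'   is present).
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  validate_intervals(df)
  cols <- list(df$chrom, format_bp(df$start), format_bp(df$end))
  has_strand <- "strand" %in% names(df) && any(df$strand %in% c("+", "-"))
  if (!is.null(df$name) || !is.null(df$score) || has_strand) {
    cols[[4]] <- if (is.null(df$name)) rep(".", nrow(df)) else as.character(df$name)
    cols[[5]] <- if (is.null(df$score)) rep("0", nrow(df)) else as.character(df$score)
    if (has_strand) cols[[6]] <- df$strand
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

# bp coordinates can exceed .Machine$integer.max in principle; print without
# scientific notation
format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a two-column genome table (chromosome, length in bp)
#'
#' @param path TSV with chromosome name and length columns, no header.
#' @return named numeric vector of chromosome lengths.
#' @export
read_genome_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  if (any(df$length <= 0)) stop("chromosome lengths must be > 0")
  stats::setNames(df$length, df$chrom)
}

#' @rdname read_genome_table
#' @param genome named numeric vector of chromosome lengths.
#' @export
write_genome_table <- function(genome, path) {
  writeLines(paste(names(genome), format_bp(genome), sep = "\t"), path)
  invisible(path)
}

# IRanges conversion: internal 0-based half-open -> 1-based closed
as_iranges0 <- function(start, end) IRanges::IRanges(start = start + 1L, end = end)

#' Merge overlapping or book-ended intervals
#'
#' Computes, per chromosome, the union of intervals, fusing any that overlap
#' or are directly adjacent. Idempotent. Strand and metadata are dropped.
#'
#' @param df interval data frame.
#' @return merged unstranded interval data frame, sorted by chromosome then
#'   start.
#' @export
merge_intervals <- function(df) {
  validate_intervals(df)
  if (nrow(df) == 0) return(genomic_intervals(character(), numeric(), numeric()))
  out <- lapply(split(seq_len(nrow(df)), df$chrom), function(i) {
    r <- IRanges::reduce(as_iranges0(df$start[i], df$end[i]))
    data.frame(chrom = df$chrom[i[1]], start = IRanges::start(r) - 1,
               end = IRanges::end(r), strand = ".", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Overlap hits between two interval frames (>=1 bp). Returns a two-column
# matrix of (query row, subject row) indices.
overlap_hits <- function(query, subject) {
  if (nrow(query) == 0 || nrow(subject) == 0)
    return(cbind(query = integer(), subject = integer()))
  res <- vector("list", 0)
  for (ch in intersect(unique(query$chrom), unique(subject$chrom))) {
    qi <- which(query$chrom == ch)
    si <- which(subject$chrom == ch)
    h <- as.matrix(IRanges::findOverlaps(
      as_iranges0(query$start[qi], query$end[qi]),
      as_iranges0(subject$start[si], subject$end[si])))
    res[[length(res) + 1]] <- cbind(query = qi[h[, 1]], subject = si[h[, 2]])
  }
  if (length(res) == 0) return(cbind(query = integer(), subject = integer()))
  do.call(rbind, res)
}
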