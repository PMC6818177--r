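#' Construct a read track
#'
#' A read track bundles one cell type x one assay's aligned reads (as
#' 0-based half-open intervals) with the library's total mapped read count,
#' the denominator of RPM normalization.
#'
#' @param cell_type cell-type label (e.g. "NSC").
#' @param assay one of `"mnase"`, `"h3k9ac"`, `"h3k27me3"`, `"h3k4me1"`.
#' @param reads interval data frame of aligned reads.
#' @param total_mapped total mapped reads in the library; must be at least
#'   the number of reads carried in the track.
#' @param genome optional named chromosome-length vector; when given, reads
#'   must lie on declared chromosomes.
#' @return object of class `"read_track"`.
#' @export
read_track <- function(cell_type, assay, reads, total_mapped, genome = NULL) {
  assay <- match.arg(assay, c("mnase", "h3k9ac", "h3k27me3", "h3k4me1"))
  validate_intervals(reads)
  if (total_mapped < nrow(reads))
    stop("total_mapped (", total_mapped, ") is smaller than the number of reads (",
         nrow(reads), ")")
  if (!is.null(genome) && nrow(reads) > 0) {
    if (!all(reads$chrom %in% names(genome)))
      stop("track contains reads on chromosomes absent from the genome table")
  }
  structure(list(cell_type = cell_type, assay = assay, reads = reads,
                 total_mapped = total_mapped), class = "read_track")
}

#' @export
print.read_track <- function(x, ...) {
  cat(sprintf("<read_track> %s / %s: %d reads (total_mapped = %s)\n",
              x$cell_type, x$assay, nrow(x$reads),
              format_bp(x$total_mapped)))
  invisible(x)
}

#' Load a read track from a BED file
#'
#' @inheritParams read_track
#' @param path BED file of aligned reads.
#' @param total_mapped library total; defaults to the number of reads in the
#'   file.
#' @export
read_track_bed <- function(path, cell_type, assay, total_mapped = NULL,
                           genome = NULL) {
  reads <- read_bed(path)
  if (is.null(total_mapped)) total_mapped <- nrow(reads)
  read_track(cell_type, assay, reads, total_mapped, genome)
}

read_midpoints <- function(reads) floor((reads$start + reads$end) / 2)

#' Count reads per region
#'
#' `mode = "midpoint"` counts a read in a region iff its midpoint
#' `floor((start + end) / 2)` lies in the half-open region (each read lands
#' in exactly one region of any partition); `mode = "overlap"` counts a read
#' in every region it overlaps by >= 1 bp.
#'
#' @param track a [read_track()].
#' @param regions interval data frame (empty allowed).
#' @param mode `"midpoint"` or `"overlap"`.
#' @return integer vector of counts, one per region row.
#' @export
count_reads <- function(track, regions, mode = c("midpoint", "overlap")) {
  mode <- match.arg(mode)
  validate_intervals(regions)
  n <- nrow(regions)
  if (n == 0) return(integer(0))
  reads <- track$reads
  counts <- integer(n)
  if (nrow(reads) == 0) return(counts)
  if (mode == "midpoint") {
    mid <- read_midpoints(reads)
    qstart <- mid; qend <- mid + 1
  } else {
    qstart <- reads$start; qend <- reads$end
  }
  for (ch in intersect(unique(regions$chrom), unique(reads$chrom))) {
    ri <- which(regions$chrom == ch)
    di <- which(reads$chrom == ch)
    counts[ri] <- IRanges::countOverlaps(
      as_iranges0(regions$start[ri], regions$end[ri]),
      as_iranges0(qstart[di], qend[di]))
  }
  counts
}

#' Reads-per-million normalization
#'
#' `RPM = count * 1e6 / total_mapped`. Linear in the counts for a fixed
#' library size.
#'
#' @param counts numeric vector (or matrix) of read counts.
#' @param total_mapped total mapped reads in the library; must be > 0.
#' @return RPM values with the shape of `counts`.
#' @export
rpm_normalize <- function(counts, total_mapped) {
  if (length(total_mapped) != 1 || is.na(total_mapped) || total_mapped <= 0)
    stop("total_mapped must be a single positive number")
  counts * 1e6 / total_mapped
}

#' Reads-per-kilobase-per-million normalization
#'
#' `RPKM = count * 1e9 / (length_bp * total_mapped)`, i.e. RPM further
#' divided by transcript length in kb.
#'
#' @param count read count(s).
#' @param length_kb transcript length(s) in kilobases; > 0.
#' @param total_mapped library total; > 0.
#' @export
rpkm <- function(count, length_kb, total_mapped) {
  if (any(length_kb <= 0)) stop("length_kb must be > 0")
  if (length(total_mapped) != 1 || total_mapped <= 0)
    stop("total_mapped must be a single positive number")
  count / (length_kb * total_mapped / 1e6)
}
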