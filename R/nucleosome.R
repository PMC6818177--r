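#' TSS-anchored nucleosome occupancy profile
#'
#' Midpoint-counts MNase reads into 200 bins of 10 bp tiling the 2-kb
#' window centered on each gene's TSS, oriented 5'->3': bin 1 starts 1000 bp
#' biologically upstream, bin 200 ends 1000 bp downstream. Minus-strand
#' windows are mirrored. Counts are RPM-normalized by the track total.
#' Genes whose window runs past a chromosome end keep their out-of-bounds
#' bins at zero and are flagged.
#'
#' @param track an MNase [read_track()].
#' @param genes gene-model data frame.
#' @param flank half-window in bp (default 1000).
#' @param bin bin width in bp (default 10).
#' @param genome optional chromosome-length vector used only to flag
#'   truncated windows.
#' @return RPM [signal_matrix()] (genes x bins) with a logical `truncated`
#'   attribute per gene.
#' @export
tss_profile <- function(track, genes, flank = 1000, bin = 10, genome = NULL) {
  if (track$assay != "mnase")
    stop("tss_profile expects an MNase track, got ", track$assay)
  nbin <- as.integer(2 * flank / bin)
  counts <- oriented_window_bins(track$reads, genes, flank, bin)
  truncated <- genes$tss - flank < 0
  if (!is.null(genome))
    truncated <- truncated | (genes$tss + flank > unname(genome[genes$chrom]))
  m <- signal_matrix(rpm_normalize(counts, track$total_mapped),
                     genes$gene_id,
                     paste0("bin", seq_len(nbin)), units = "RPM")
  attr(m, "truncated") <- stats::setNames(truncated, genes$gene_id)
  m
}

# midpoint-count reads into oriented fixed-width bins around each TSS.
# Returns genes x nbin count matrix. Handles overlapping windows (a read can
# serve several genes).
oriented_window_bins <- function(reads, genes, flank, bin) {
  nbin <- as.integer(2 * flank / bin)
  counts <- matrix(0L, nrow(genes), nbin)
  if (nrow(reads) == 0) return(counts)
  mid <- read_midpoints(reads)
  minus_g <- genes$strand == "-"
  # the oriented offset of position p is p - tss on "+" and tss - p on "-";
  # offsets in [-flank, flank) map to the genomic window [tss - flank,
  # tss + flank) on "+" and its exact reflection [tss - flank + 1,
  # tss + flank + 1) on "-"
  wstart <- ifelse(minus_g, genes$tss - flank + 1, genes$tss - flank)
  wend <- wstart + 2 * flank
  for (ch in intersect(unique(genes$chrom), unique(reads$chrom))) {
    gi <- which(genes$chrom == ch)
    di <- which(reads$chrom == ch)
    h <- as.matrix(IRanges::findOverlaps(
      as_iranges0(mid[di], mid[di] + 1),
      as_iranges0(pmax(wstart[gi], 0), wend[gi])))
    if (nrow(h) == 0) next
    g <- gi[h[, 2]]
    m <- mid[di[h[, 1]]]
    o <- ifelse(minus_g[g], genes$tss[g] - m, m - genes$tss[g])
    off <- o + flank
    keep <- off >= 0 & off < 2 * flank
    g <- g[keep]; off <- off[keep]
    idx <- off %/% bin + 1
    tab <- table(factor(g, levels = seq_len(nrow(genes))),
                 factor(idx, levels = seq_len(nbin)))
    counts <- counts + unclass(tab)
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Nucleosome occupancy in nucleosome-depleted regions
#'
#' Quantifies midpoint-counted MNase RPM in the oriented NDR window,
#' by default 150 bp upstream to 50 bp downstream of the TSS:
#' `[tss - 150, tss + 50)` on "+" genes and the strand-mirrored window
#' `[tss - 49, tss + 151)` on "-" genes.
#'
#' @inheritParams tss_profile
#' @param up,down bp upstream/downstream of the TSS (defaults 150 and 50).
#' @return named numeric vector of NDR RPM per gene.
#' @export
ndr_occupancy <- function(track, genes, up = 150, down = 50) {
  if (track$assay != "mnase")
    stop("ndr_occupancy expects an MNase track, got ", track$assay)
  minus <- genes$strand == "-"
  start <- ifelse(minus, genes$tss - down + 1, genes$tss - up)
  end <- ifelse(minus, genes$tss + up + 1, genes$tss + down)
  win <- data.frame(chrom = genes$chrom, start = pmax(start, 0), end = end,
                    strand = ".", stringsAsFactors = FALSE)
  cnt <- count_reads(track, win, mode = "midpoint")
  stats::setNames(rpm_normalize(cnt, track$total_mapped), genes$gene_id)
}

#' NDR occupancy matrix across cell types
#'
#' @param tracks list of MNase [read_track()]s (one per cell type).
#' @inheritParams ndr_occupancy
#' @return RPM [signal_matrix()] genes x cell types.
#' @export
ndr_matrix <- function(tracks, genes, up = 150, down = 50) {
  cols <- lapply(tracks, ndr_occupancy, genes = genes, up = up, down = down)
  m <- do.call(cbind, cols)
  colnames(m) <- vapply(tracks, `[[`, "", "cell_type")
  signal_matrix(m, units = "RPM")
}

#' Order genes ascendingly by NDR occupancy
#'
#' Stable ascending sort with ties broken by lexicographic gene_id.
#'
#' @param ndr named numeric vector from [ndr_occupancy()] (or one column of
#'   [ndr_matrix()]).
#' @return character vector of gene_ids, lowest NDR occupancy first.
#' @export
order_genes_by_ndr <- function(ndr) {
  names(ndr)[order(ndr, names(ndr))]
}
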