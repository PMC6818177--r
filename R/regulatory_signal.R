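hm_assays <- c("h3k9ac", "h3k27me3")

#' Histone-mark RPM signal in promoters
#'
#' Overlap-counts an H3K9ac or H3K27me3 track over promoter intervals and
#' RPM-normalizes by the track total.
#'
#' @param track an HM [read_track()] (`h3k9ac` or `h3k27me3`).
#' @param promoters promoter frame from [promoters_of()] (carries
#'   `gene_id`).
#' @return named numeric vector of promoter RPM per gene.
#' @export
promoter_signal <- function(track, promoters) {
  if (!track$assay %in% hm_assays)
    stop("promoter_signal expects an H3K9ac or H3K27me3 track, got ",
         track$assay)
  cnt <- count_reads(track, promoters, mode = "overlap")
  stats::setNames(rpm_normalize(cnt, track$total_mapped), promoters$gene_id)
}

#' Consensus enhancer universe across cell types
#'
#' Merges the union of per-cell enhancer sets into one non-overlapping
#' universe so that signal columns of different cell types share rows.
#'
#' @param enhancer_sets list of per-cell enhancer frames.
#' @return merged interval frame with an `id` column
#'   (`"chrom:start-end"`).
#' @export
consensus_enhancers <- function(enhancer_sets) {
  all <- do.call(rbind, lapply(enhancer_sets, function(e)
    e[, c("chrom", "start", "end", "strand")]))
  if (is.null(all) || nrow(all) == 0)
    stop("no enhancers in any cell type; cannot build a consensus universe")
  merged <- merge_intervals(all)
  merged$id <- sprintf("%s:%s-%s", merged$chrom, format_bp(merged$start),
                       format_bp(merged$end))
  merged
}

#' Histone-mark RPM signal in consensus enhancers
#'
#' @param track an HM [read_track()].
#' @param enhancers consensus frame from [consensus_enhancers()].
#' @return named numeric vector of enhancer RPM (names = enhancer ids).
#' @export
enhancer_signal <- function(track, enhancers) {
  if (!track$assay %in% hm_assays)
    stop("enhancer_signal expects an H3K9ac or H3K27me3 track, got ",
         track$assay)
  if (nrow(enhancers) == 0) stop("empty consensus enhancer universe")
  cnt <- count_reads(track, enhancers, mode = "overlap")
  stats::setNames(rpm_normalize(cnt, track$total_mapped), enhancers$id)
}

#' Signal matrix over promoters or enhancers for several cell types
#'
#' @param tracks list of HM [read_track()]s, one per cell type, same assay.
#' @param regions promoter frame (with `gene_id`) or consensus enhancer
#'   frame (with `id`).
#' @return RPM [signal_matrix()] regions x cell types.
#' @export
signal_matrix_across_cells <- function(tracks, regions) {
  is_prom <- "gene_id" %in% names(regions)
  cols <- lapply(tracks, function(tr)
    if (is_prom) promoter_signal(tr, regions) else enhancer_signal(tr, regions))
  m <- do.call(cbind, cols)
  colnames(m) <- vapply(tracks, `[[`, "", "cell_type")
  signal_matrix(m, units = "RPM")
}
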