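#' Call enhancers from an H3K4me1 track by Poisson sliding windows
#'
#' Tiles each chromosome with 1-kb windows at 100-bp steps, overlap-counts
#' reads per window, and tests each window's count against a Poisson null
#' with the track's global mean reads-per-window rate (upper tail).
#' P-values are BH-adjusted across all windows; windows with `q < fdr` are
#' merged when overlapping or adjacent. Each merged region is then
#' boundary-refined at half-maximum coverage in 50-bp bins, so reported
#' peaks track the underlying enriched interval rather than the window
#' overhang. Peaks overlapping any promoter by >= 1 bp are discarded.
#'
#' @param track an H3K4me1 [read_track()].
#' @param genome named chromosome-length vector.
#' @param promoters promoter interval frame (from [promoters_of()]).
#' @param window sliding-window width in bp (default 1000).
#' @param step window step in bp (default 100); must not exceed `window`.
#' @param fdr BH threshold (default 0.001).
#' @return interval data frame of class `"enhancer_set"` with columns
#'   `chrom`, `start`, `end`, `count` (reads overlapping the peak), `q`
#'   (minimum q over member windows).
#' @export
call_enhancers <- function(track, genome, promoters, window = 1000,
                           step = 100, fdr = 0.001) {
  if (track$assay != "h3k4me1")
    stop("call_enhancers expects an H3K4me1 track, got ", track$assay)
  if (window <= 0 || step <= 0 || window < step)
    stop("invalid window/step configuration: need 0 < step <= window")
  wins <- sliding_windows(genome, window, step)
  counts <- count_reads(track, wins, mode = "overlap")
  lambda <- mean(counts)  # global mean reads per window
  pv <- stats::ppois(counts - 1, lambda, lower.tail = FALSE)
  qv <- stats::p.adjust(pv, method = "BH")
  sig <- which(qv < fdr)
  if (length(sig) == 0) return(empty_enhancers())
  merged <- merge_intervals(wins[sig, , drop = FALSE])
  # carry min q per merged region
  hits <- overlap_hits(wins[sig, , drop = FALSE], merged)
  minq <- tapply(qv[sig][hits[, "query"]], hits[, "subject"], min)
  merged$q <- as.numeric(minq[as.character(seq_len(nrow(merged)))])
  refined <- refine_peaks(track, merged, lambda / window)
  if (is.null(refined) || nrow(refined) == 0) return(empty_enhancers())
  refined$count <- count_reads(track, refined, mode = "overlap")
  # discard peaks touching promoters
  if (nrow(promoters) > 0) {
    ph <- overlap_hits(refined, promoters)
    if (nrow(ph) > 0)
      refined <- refined[-unique(ph[, "query"]), , drop = FALSE]
  }
  rownames(refined) <- NULL
  class(refined) <- c("enhancer_set", class(refined))
  refined
}

empty_enhancers <- function() {
  df <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                   strand = character(), q = numeric(), count = integer(),
                   stringsAsFactors = FALSE)
  class(df) <- c("enhancer_set", class(df))
  df
}

sliding_windows <- function(genome, window, step) {
  out <- lapply(names(genome), function(ch) {
    len <- genome[[ch]]
    if (len < window)
      return(data.frame(chrom = ch, start = 0, end = len, strand = ".",
                        stringsAsFactors = FALSE))
    start <- seq(0, len - window, by = step)
    data.frame(chrom = ch, start = start, end = start + window, strand = ".",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Boundary refinement of merged significant windows: within each region,
# 50-bp binned coverage is thresholded halfway between the background rate
# and the region's maximum; each maximal run of above-half bins becomes one
# peak. This trims the sliding-window overhang and splits neighbouring
# enriched elements that a shared significant window would otherwise fuse.
refine_peaks <- function(track, regions, bg_per_bp, bin = 50) {
  nreg <- nrow(regions)
  starts_l <- lapply(seq_len(nreg), function(i)
    seq(regions$start[i], regions$end[i] - 1, by = bin))
  nb <- lengths(starts_l)
  all_bins <- data.frame(
    chrom = rep(regions$chrom, nb),
    start = unlist(starts_l),
    end = pmin(unlist(starts_l) + bin, rep(regions$end, nb)),
    strand = ".", stringsAsFactors = FALSE)
  cov_all <- count_reads(track, all_bins, mode = "overlap")
  reg_of <- rep(seq_len(nreg), nb)
  rows <- list()
  for (i in seq_len(nreg)) {
    sel <- which(reg_of == i)
    bins <- all_bins[sel, , drop = FALSE]
    cov <- cov_all[sel]
    # 3-bin moving average damps Poisson dips that would fragment one
    # element; a >= 2-bin run suppresses single-bin specks
    n <- length(cov)
    sm <- if (n >= 3)
      (cov + c(cov[1], cov[-n]) + c(cov[-1], cov[n])) / 3 else cov
    half <- (bg_per_bp * bin + max(sm)) / 2
    above <- sm >= half
    if (!any(above)) {
      rows[[length(rows) + 1]] <- regions[i, , drop = FALSE]
      next
    }
    r <- rle(above)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1
    for (j in which(r$values)) {
      if (r$lengths[j] < 2 && n >= 2) next
      out <- regions[i, , drop = FALSE]
      out$start <- bins$start[starts_i[j]]
      out$end <- bins$end[ends_i[j]]
      rows[[length(rows) + 1]] <- out
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assign each enhancer its nearest-gene target
#'
#' Distance is measured from the proximal enhancer border to the TSS
#' (0 when the TSS lies inside the enhancer); the nearest gene wins, ties
#' broken by the lexicographically smaller gene_id; enhancers with no TSS
#' within `max_dist` (default 10 kb) are flagged unassigned.
#'
#' @param enhancers enhancer interval frame.
#' @param genes gene-model data frame.
#' @param max_dist assignment cutoff in bp (default 10000).
#' @return data frame: `chrom`, `start`, `end`, `target`, `distance`,
#'   `assigned`.
#' @export
assign_targets <- function(enhancers, genes, max_dist = 10000) {
  n <- nrow(enhancers)
  target <- rep(NA_character_, n)
  distance <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    g <- genes[genes$chrom == enhancers$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) next
    tss <- g$tss
    s <- enhancers$start[i]; e <- enhancers$end[i]
    # distance from the proximal border: 0 inside [s, e)
    d <- ifelse(tss >= s & tss < e, 0, pmin(abs(tss - s), abs(tss - e)))
    ord <- order(d, g$gene_id)
    if (d[ord[1]] <= max_dist) {
      target[i] <- g$gene_id[ord[1]]
      distance[i] <- d[ord[1]]
    }
  }
  data.frame(chrom = enhancers$chrom, start = enhancers$start,
             end = enhancers$end, target = target, distance = distance,
             assigned = !is.na(target), stringsAsFactors = FALSE)
}

#' H3K9ac status of enhancers from a chromatin-state map
#'
#' An enhancer is H3K9ac+ in a cell type iff at least one of the 200-bp
#' state bins it overlaps carries the H3K9ac mark (state `H3K9ac+` or
#' `both`).
#'
#' @param enhancers enhancer interval frame.
#' @param map the cell type's [assign_states()] state map.
#' @return logical vector per enhancer.
#' @export
enhancer_h3k9ac_status <- function(enhancers, map) {
  acet <- map$state %in% c("H3K9ac+", "both")
  status <- logical(nrow(enhancers))
  hits <- overlap_hits(enhancers, map$bins[acet, , drop = FALSE])
  status[unique(hits[, "query"])] <- TRUE
  status
}

#' Cell-type-specific H3K9ac+ enhancers
#'
#' Splits the H3K9ac+ enhancers of two cell types into A-specific,
#' B-specific and shared: an H3K9ac+ enhancer of A is shared iff it
#' overlaps (>= 1 bp) any H3K9ac+ enhancer of B, else A-specific.
#'
#' @param enh_a,enh_b enhancer interval frames of the two cell types.
#' @param k9_a,k9_b logical H3K9ac status per enhancer (see
#'   [enhancer_h3k9ac_status()]).
#' @return list: `a_specific`, `b_specific`, `shared_a`, `shared_b`
#'   (interval frames; shared reported from both sides).
#' @export
specific_h3k9ac_enhancers <- function(enh_a, enh_b, k9_a, k9_b) {
  a <- enh_a[k9_a, , drop = FALSE]
  b <- enh_b[k9_b, , drop = FALSE]
  ha <- overlap_hits(a, b)
  shared_a <- unique(ha[, "query"])
  shared_b <- unique(ha[, "subject"])
  list(a_specific = a[setdiff(seq_len(nrow(a)), shared_a), , drop = FALSE],
       b_specific = b[setdiff(seq_len(nrow(b)), shared_b), , drop = FALSE],
       shared_a = a[shared_a, , drop = FALSE],
       shared_b = b[shared_b, , drop = FALSE])
}

#' Read a GMT gene-set file
#'
#' Standard tab format: set name, description, member genes.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3))
    stop("GMT parse error: line with fewer than 3 fields")
  stats::setNames(lapply(fields, function(f) unique(f[-(1:2)])),
                  vapply(fields, `[[`, "", 1L))
}

#' @rdname read_gmt
#' @param sets named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of the overlap between a query gene list
#' and each gene set (sets are intersected with the universe first),
#' BH-adjusted across sets; the five smallest-p sets are flagged.
#'
#' @param query character vector of genes; must be a subset of `universe`.
#' @param sets named list of gene sets (e.g. from [read_gmt()]).
#' @param universe background gene list.
#' @param top_n how many top sets to flag (default 5).
#' @return data frame sorted by p: `set`, `set_size`, `overlap`, `p`, `q`,
#'   `top`.
#' @export
gene_set_enrichment <- function(query, sets, universe, top_n = 5) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  query <- unique(query)
  if (!all(query %in% universe))
    stop("query genes must be contained in the universe")
  n_u <- length(universe); n_q <- length(query)
  res <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    k <- length(intersect(s, query))
    p <- stats::phyper(k - 1, length(s), n_u - length(s), n_q,
                       lower.tail = FALSE)
    data.frame(set = nm, set_size = length(s), overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$q <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$p, res$set), , drop = FALSE]
  res$top <- seq_len(nrow(res)) <= top_n
  rownames(res) <- NULL
  res
}
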