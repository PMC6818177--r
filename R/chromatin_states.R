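CHROMATIN_STATES <- c("H3K9ac+", "H3K27me3+", "both", "unmarked")

#' Genome-tiling bins
#'
#' Tiles each chromosome from 0 in fixed-width steps; the last bin of a
#' chromosome is truncated at the chromosome end.
#'
#' @param genome named chromosome-length vector.
#' @param bin_size bin width in bp (default 200).
#' @return interval data frame of bins in genome-table order.
#' @export
genome_bins <- function(genome, bin_size = 200) {
  out <- lapply(names(genome), function(ch) {
    len <- genome[[ch]]
    start <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = ch, start = start, end = pmin(start + bin_size, len),
               strand = ".", stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Minimal significant count for Poisson-tail binarization
#'
#' The smallest integer `k` whose upper-tail probability
#' `P(X >= k | Poisson(lambda))` is at most `p_threshold`.
#'
#' @param lambda Poisson mean (reads per bin).
#' @param p_threshold tail probability cutoff (default 1e-4).
#' @export
binarization_threshold <- function(lambda, p_threshold = 1e-4) {
  if (lambda <= 0) return(1L)
  # P(X >= k) = ppois(k - 1, lower.tail = FALSE); search upward from the
  # quantile as a lower bound
  k <- stats::qpois(1 - p_threshold, lambda)
  while (k > 0 && stats::ppois(k - 1, lambda, lower.tail = FALSE) <= p_threshold)
    k <- k - 1
  while (stats::ppois(k, lambda, lower.tail = FALSE) > p_threshold)
    k <- k + 1
  as.integer(k + 1)
}

#' Binarize a histone-mark track over genome bins
#'
#' Overlap-counts reads into fixed-width genome bins and marks a bin (1)
#' iff its count `k` has upper-tail Poisson probability
#' `P(X >= k | lambda) <= p_threshold`, where `lambda` is the global mean
#' reads per bin. This is the standard two-state Poisson binarization used
#' ahead of chromatin-state labeling.
#'
#' @param track a ChIP [read_track()].
#' @param genome named chromosome-length vector.
#' @param bin_size bin width in bp (default 200).
#' @param p_threshold Poisson tail cutoff (default 1e-4).
#' @return list: `bins` (interval frame), `marked` (0/1 integer vector),
#'   `lambda`, `k_min` (the minimal significant count).
#' @export
binarize_mark <- function(track, genome, bin_size = 200, p_threshold = 1e-4) {
  bins <- genome_bins(genome, bin_size)
  counts <- count_reads(track, bins, mode = "overlap")
  if (nrow(track$reads) == 0) {
    warning("track has zero reads; all bins unmarked")
    return(list(bins = bins, marked = integer(nrow(bins)), lambda = 0,
                k_min = 1L))
  }
  lambda <- mean(counts)
  k_min <- binarization_threshold(lambda, p_threshold)
  list(bins = bins, marked = as.integer(counts >= k_min), lambda = lambda,
       k_min = k_min)
}

#' Combine two binarized marks into a chromatin-state map
#'
#' Per bin: (H3K9ac, H3K27me3) = (1,0) -> `H3K9ac+`; (0,1) -> `H3K27me3+`;
#' (1,1) -> `both`; (0,0) -> `unmarked`.
#'
#' @param k9ac,k27me3 outputs of [binarize_mark()] on the same bin grid.
#' @param smooth if `TRUE`, apply a 3-bin majority filter to each mark
#'   before combining (off by default).
#' @return list of class `"state_map"`: `bins`, `state` (factor over the
#'   four states).
#' @export
assign_states <- function(k9ac, k27me3, smooth = FALSE) {
  if (nrow(k9ac$bins) != nrow(k27me3$bins) ||
      !all(k9ac$bins$start == k27me3$bins$start) ||
      !all(k9ac$bins$chrom == k27me3$bins$chrom))
    stop("bin grids of the two marks do not match")
  a <- k9ac$marked
  r <- k27me3$marked
  if (smooth) {
    a <- majority3(a, k9ac$bins$chrom)
    r <- majority3(r, k27me3$bins$chrom)
  }
  idx <- 1L + (a == 0) * (r == 1) + (a == 1) * (r == 1) * 2L +
    (a == 0) * (r == 0) * 3L
  # (1,0)->1, (0,1)->2, (1,1)->3, (0,0)->4
  structure(list(bins = k9ac$bins,
                 state = factor(CHROMATIN_STATES[idx],
                                levels = CHROMATIN_STATES)),
            class = "state_map")
}

# 3-bin sliding majority within each chromosome (edges keep their value)
majority3 <- function(x, chrom) {
  out <- x
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    if (length(i) < 3) next
    v <- x[i]
    n <- length(v)
    s <- v[2:(n - 1)] + v[1:(n - 2)] + v[3:n]
    out[i][2:(n - 1)] <- as.integer(s >= 2)
  }
  out
}

#' @export
print.state_map <- function(x, ...) {
  cat("<state_map>", length(x$state), "bins\n")
  print(table(x$state))
  invisible(x)
}

#' Per-state genome fractions
#'
#' @param map a [assign_states()] state map.
#' @return named numeric vector over the four states, summing to 1.
#' @export
state_fractions <- function(map) {
  tab <- table(map$state)
  stats::setNames(as.vector(tab) / length(map$state), names(tab))
}

#' State-transition flow between two cell types
#'
#' The 4x4 contingency of per-bin (source state, target state) on a shared
#' bin grid, plus per-state genome fractions for both cells: the numbers
#' behind an alluvial plot of chromatin-state dynamics.
#'
#' @param map_a,map_b state maps on the same grid (source, target).
#' @return list of class `"state_flow"`: `flow` (4x4 bin-count matrix,
#'   rows = source states), `fractions_a`, `fractions_b`, `n_bins`.
#' @export
state_flow <- function(map_a, map_b) {
  if (length(map_a$state) != length(map_b$state) ||
      !all(map_a$bins$start == map_b$bins$start) ||
      !all(map_a$bins$chrom == map_b$bins$chrom))
    stop("bin grids of the two state maps do not match")
  fl <- table(source = map_a$state, target = map_b$state)
  structure(list(flow = unclass(fl),
                 fractions_a = state_fractions(map_a),
                 fractions_b = state_fractions(map_b),
                 n_bins = length(map_a$state)),
            class = "state_flow")
}

#' @export
print.state_flow <- function(x, ...) {
  cat("<state_flow>", x$n_bins, "bins\n")
  print(x$flow)
  invisible(x)
}

#' Write a state map as BED4
#'
#' @param map state map.
#' @param path output path.
#' @export
write_state_map <- function(map, path) {
  df <- map$bins
  df$name <- as.character(map$state)
  write_bed(df[, c("chrom", "start", "end", "name")], path)
}
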