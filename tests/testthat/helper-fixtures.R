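# shared fixtures, built in code

CELLS <- c("NSC", "GNP", "Glia", "Neuron")

make_reads <- function(chrom, start, end, strand = ".") {
  data.frame(chrom = chrom, start = start, end = end,
             strand = rep_len(strand, length(start)),
             stringsAsFactors = FALSE)
}

make_track <- function(start, end, chrom = "chr1", assay = "mnase",
                       cell = "NSC", total = NULL) {
  reads <- make_reads(rep_len(chrom, length(start)), start, end)
  if (is.null(total)) total <- nrow(reads)
  read_track(cell, assay, reads, total)
}

# one default simulation shared by read-only tests (2 s, built once)
cached_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_dataset(sim_config(seed = 101))
    cache
  }
})

sim_tracks <- function(sim, assay) {
  tr <- lapply(CELLS, function(cl) sim$tracks[[paste(cl, assay, sep = ".")]])
  names(tr) <- CELLS
  tr
}

# brute-force read counting oracle: O(reads x regions) scan
count_reads_oracle <- function(reads, regions, mode) {
  vapply(seq_len(nrow(regions)), function(i) {
    hits <- 0L
    for (j in seq_len(nrow(reads))) {
      if (reads$chrom[j] != regions$chrom[i]) next
      if (mode == "midpoint") {
        m <- floor((reads$start[j] + reads$end[j]) / 2)
        hit <- m >= regions$start[i] && m < regions$end[i]
      } else {
        hit <- reads$start[j] < regions$end[i] &&
          reads$end[j] > regions$start[i]
      }
      hits <- hits + hit
    }
    hits
  }, 0L)
}

# uniform background reads on a 1-chromosome genome
background_track <- function(n_reads, chrom_len, assay = "h3k4me1",
                             chrom = "chrB", read_len = 49) {
  p <- floor(runif(n_reads, 0, chrom_len - read_len))
  make_track(p, p + read_len, chrom = chrom, assay = assay)
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  ov / (pmax(e1, e2) - pmin(s1, s2))
}

no_promoters <- function() data.frame(chrom = character(), start = numeric(),
                                      end = numeric(), strand = character(),
                                      gene_id = character(),
                                      stringsAsFactors = FALSE)
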