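# brute-force oracle: oriented offset of a read midpoint relative to a TSS
oriented_bin_oracle <- function(genes, reads, flank = 1000, bin = 10) {
  nbin <- 2 * flank / bin
  counts <- matrix(0L, nrow(genes), nbin)
  for (j in seq_len(nrow(reads))) {
    m <- floor((reads$start[j] + reads$end[j]) / 2)
    for (i in seq_len(nrow(genes))) {
      if (reads$chrom[j] != genes$chrom[i]) next
      o <- if (genes$strand[i] == "-") genes$tss[i] - m else m - genes$tss[i]
      if (o >= -flank && o < flank)
        counts[i, (o + flank) %/% bin + 1] <- counts[i, (o + flank) %/% bin + 1] + 1L
    }
  }
  counts
}

two_genes <- function() {
  data.frame(gene_id = c("gPlus", "gMinus"), chrom = "chr1",
             start = c(5000, 14000), end = c(6400, 15400),
             strand = c("+", "-"), tss = c(5000, 15399),
             length_kb = 1.4, stringsAsFactors = FALSE)
}

test_that("profile bin indices match the window arithmetic on both strands", {
  genes <- two_genes()
  genes$tss <- c(5000, 5000)
  genes$start <- c(5000, 3601); genes$end <- c(6400, 5001)
  # read midpoints 4101 (plus) and 5899 (minus) both land 899 bp upstream
  tr_p <- make_track(4101 - 24, 4101 + 25, total = 1e6)
  tr_m <- make_track(5899 - 24, 5899 + 25, total = 1e6)
  prof_p <- tss_profile(tr_p, genes)
  prof_m <- tss_profile(tr_m, genes)
  expect_equal(unname(which(prof_p[1, ] > 0)), 11L)  # 0-based bin 10
  expect_equal(unname(which(prof_m[2, ] > 0)), 11L)
  expect_equal(unname(prof_p[1, 11]) * 1e-6 * tr_p$total_mapped, 1)
})

test_that("tss_profile equals the brute-force oracle on random reads", {
  set.seed(31)
  genes <- two_genes()
  pos <- floor(runif(400, 3900, 16500))
  tr <- make_track(pos, pos + 49, total = 1e6)
  prof <- tss_profile(tr, genes)
  oracle <- oriented_bin_oracle(genes, tr$reads)
  expect_equal(unclass(prof) * tr$total_mapped / 1e6,
               oracle, ignore_attr = TRUE)
  expect_equal(ncol(prof), 200)
})

test_that("a trackless profile is all zero and non-MNase tracks are rejected", {
  genes <- two_genes()
  tr <- make_track(numeric(0), numeric(0), total = 10)
  expect_true(all(tss_profile(tr, genes) == 0))
  bad <- make_track(10, 59, assay = "h3k9ac")
  expect_error(tss_profile(bad, genes), "MNase")
  expect_error(ndr_occupancy(bad, genes), "MNase")
})

test_that("NDR windows are [-150,+50) oriented, mirrored exactly on minus", {
  genes <- two_genes()
  # plus gene tss=5000: window [4850, 5050)
  inside_p <- c(4850, 5049); outside_p <- c(4849, 5050)
  # minus gene tss=15399: reflection -> [15350, 15550)
  inside_m <- c(15350, 15549); outside_m <- c(15349, 15550)
  mk <- function(mid) make_track(mid - 24, mid + 25, total = 1e6)
  for (m in inside_p)
    expect_equal(unname(ndr_occupancy(mk(m), genes)["gPlus"]), 1, label = m)
  for (m in outside_p)
    expect_equal(unname(ndr_occupancy(mk(m), genes)["gPlus"]), 0, label = m)
  for (m in inside_m)
    expect_equal(unname(ndr_occupancy(mk(m), genes)["gMinus"]), 1, label = m)
  for (m in outside_m)
    expect_equal(unname(ndr_occupancy(mk(m), genes)["gMinus"]), 0, label = m)
})

test_that("uniform read density puts ~10% of the 2-kb window signal in the NDR", {
  set.seed(32)
  genes <- two_genes()[1, ]
  pos <- floor(runif(60000, 3500, 7500))
  tr <- make_track(pos, pos + 49, total = 1e6)
  ndr <- ndr_occupancy(tr, genes)
  prof <- tss_profile(tr, genes)
  expect_equal(unname(ndr / sum(prof[1, ])), 200 / 2000, tolerance = 0.05)
})

test_that("profile bins partition the 2-kb window (row sum = window RPM)", {
  sim <- cached_sim()
  tr <- sim$tracks[["NSC.mnase"]]
  prof <- tss_profile(tr, sim$genes)
  minus <- sim$genes$strand == "-"
  win <- data.frame(chrom = sim$genes$chrom,
                    start = ifelse(minus, sim$genes$tss - 999,
                                   sim$genes$tss - 1000),
                    end = ifelse(minus, sim$genes$tss + 1001,
                                 sim$genes$tss + 1000))
  rpm <- rpm_normalize(count_reads(tr, win, "midpoint"), tr$total_mapped)
  expect_equal(unname(rowSums(prof)), rpm)
})

test_that("genes are ordered ascendingly by NDR with gene_id tie-breaks", {
  expect_equal(order_genes_by_ndr(c(a = 2, b = 1, c = 3)), c("b", "a", "c"))
  expect_equal(order_genes_by_ndr(c(b = 1, a = 1, c = 1)), c("a", "b", "c"))
  set.seed(33)
  v <- setNames(runif(50), sprintf("g%02d", sample(50)))
  expect_setequal(order_genes_by_ndr(v), names(v))
})

test_that("NDR occupancy anticorrelates with expression under the default coupling", {
  sim <- cached_sim()
  ndr <- ndr_occupancy(sim$tracks[["GNP.mnase"]], sim$genes)
  rho <- cor(unclass(sim$expression$rpkm)[, "GNP"], ndr,
             method = "spearman")
  expect_lt(rho, -0.3)
})

test_that("highly expressed genes show a depleted NDR in the mean profile", {
  sim <- cached_sim()
  prof <- tss_profile(sim$tracks[["NSC.mnase"]], sim$genes)
  expr <- unclass(sim$expression$rpkm)[, "NSC"]
  top <- names(sort(expr, decreasing = TRUE))[1:100]
  avg <- colMeans(unclass(prof)[top, ])
  centers <- seq(-995, 995, by = 10)
  ndr_bins <- centers >= -150 & centers < 50
  expect_lt(min(avg[ndr_bins]), min(avg[!ndr_bins]))
})
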