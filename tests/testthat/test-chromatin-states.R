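# brute-force Poisson upper-tail threshold by term-wise summation
threshold_oracle <- function(lambda, p) {
  k <- 0
  repeat {
    tail <- 1 - sum(dpois(0:(k - 1), lambda))
    if (k == 0) tail <- 1
    if (tail <= p) return(k)
    k <- k + 1
  }
}

test_that("binarization threshold matches the brute-force Poisson tail", {
  for (lambda in c(0.1, 1, 5))
    for (p in c(1e-4, 1e-3))
      expect_equal(binarization_threshold(lambda, p),
                   threshold_oracle(lambda, p),
                   label = paste(lambda, p))
})

test_that("mark combinations map to the four chromatin states", {
  genome <- c(chr1 = 1000)
  bins <- genome_bins(genome)
  mk <- function(marked) list(bins = bins, marked = marked)
  map <- assign_states(mk(c(1L, 0L, 1L, 0L, 1L)),
                       mk(c(0L, 1L, 1L, 0L, 0L)))
  expect_equal(as.character(map$state),
               c("H3K9ac+", "H3K27me3+", "both", "unmarked", "H3K9ac+"))
  expect_equal(sum(table(map$state)), length(map$state))
  zero <- assign_states(mk(rep(0L, 5)), mk(rep(0L, 5)))
  expect_true(all(zero$state == "unmarked"))
  other <- list(bins = genome_bins(c(chr2 = 1000)), marked = rep(0L, 5))
  expect_error(assign_states(mk(rep(0L, 5)), other), "grids")
})

test_that("genome bins tile from zero with a truncated last bin", {
  bins <- genome_bins(c(chrA = 950, chrB = 400), 200)
  expect_equal(bins$start[1], 0)
  expect_equal(max(bins$end[bins$chrom == "chrA"]), 950)
  expect_equal(bins$end[bins$chrom == "chrA"][5], 950)  # truncated
  expect_equal(sum(bins$chrom == "chrB"), 2)
})

test_that("adding reads to a bin never unmarks it", {
  set.seed(41)
  genome <- c(chr1 = 2e5)
  pos <- floor(runif(3000, 0, genome - 49))
  extra <- floor(runif(200, 10000, 10200 - 49))  # pile onto one bin
  tr1 <- make_track(pos, pos + 49, assay = "h3k9ac")
  tr2 <- make_track(c(pos, extra), c(pos, extra) + 49, assay = "h3k9ac")
  b1 <- binarize_mark(tr1, genome)
  b2 <- binarize_mark(tr2, genome)
  expect_true(all(b2$marked >= b1$marked))
})

test_that("pure background marks almost nothing at the default threshold", {
  frac <- vapply(1:20, function(s) {
    set.seed(500 + s)
    genome <- c(chr1 = 1e6)
    pos <- floor(runif(30000, 0, genome - 49))
    tr <- make_track(pos, pos + 49, assay = "h3k27me3")
    mean(binarize_mark(tr, genome)$marked)
  }, 0)
  expect_lte(mean(frac), 1e-4 * 10)
})

test_that("a zero-read track warns and leaves all bins unmarked", {
  tr <- make_track(numeric(0), numeric(0), assay = "h3k9ac", total = 1)
  expect_warning(b <- binarize_mark(tr, c(chr1 = 10000)), "zero")
  expect_true(all(b$marked == 0))
})

test_that("state flows conserve bins and detect identity", {
  genome <- c(chr1 = 2000)
  bins <- genome_bins(genome)
  mk <- function(a, r) assign_states(list(bins = bins, marked = a),
                                     list(bins = bins, marked = r))
  mapA <- mk(c(1L, 1L, 0L, 0L, 1L, 0L, 1L, 1L, 0L, 0L),
             c(0L, 1L, 1L, 0L, 0L, 0L, 1L, 0L, 1L, 0L))
  fl <- state_flow(mapA, mapA)
  expect_equal(sum(fl$flow), 10)
  expect_true(all(fl$flow[row(fl$flow) != col(fl$flow)] == 0))
  expect_equal(sum(fl$fractions_a), 1)
  expect_equal(sum(fl$fractions_b), 1)
  mapB <- mk(rep(0L, 10), rep(1L, 10))
  fl2 <- state_flow(mapA, mapB)
  expect_equal(sum(fl2$flow), 10)
  expect_equal(unname(rowSums(fl2$flow)),
               unname(as.vector(table(mapA$state))))
})

test_that("a planted 30% H3K9ac+ -> unmarked transition is recovered within 3 points", {
  est <- vapply(1:3, function(s) {
    set.seed(600 + s)
    genome <- c(chr1 = 2e6)
    n_marked <- 1500
    bins <- genome_bins(genome)
    marked_idx <- sample(nrow(bins), n_marked)
    lost <- sample(marked_idx, round(0.3 * n_marked))
    mk_track <- function(active_idx) {
      # background 1 read/bin plus 15x pile-up in active bins
      bg <- floor(runif(10000, 0, genome - 49))
      act <- rep(bins$start[active_idx], each = 15) +
        floor(runif(15 * length(active_idx)) * 150)
      make_track(c(bg, act), c(bg, act) + 49, assay = "h3k9ac")
    }
    qpos <- floor(runif(10000, 0, genome - 49))
    quiet <- make_track(qpos, qpos + 49, assay = "h3k27me3")
    mapA <- assign_states(binarize_mark(mk_track(marked_idx), genome),
                          binarize_mark(quiet, genome))
    mapB <- assign_states(binarize_mark(mk_track(setdiff(marked_idx, lost)),
                                        genome),
                          binarize_mark(quiet, genome))
    fl <- state_flow(mapA, mapB)
    fl$flow["H3K9ac+", "unmarked"] / sum(fl$flow["H3K9ac+", ])
  }, 0)
  expect_lt(abs(mean(est) - 0.30), 0.03)
})

test_that("the optional 3-bin majority filter smooths isolated flips", {
  genome <- c(chr1 = 2000)
  bins <- genome_bins(genome)
  a <- c(1L, 1L, 0L, 1L, 1L, 0L, 0L, 0L, 1L, 0L)
  sm <- assign_states(list(bins = bins, marked = a),
                      list(bins = bins, marked = rep(0L, 10)),
                      smooth = TRUE)
  expect_equal(as.character(sm$state[3]), "H3K9ac+")  # hole filled
  expect_equal(as.character(sm$state[9]), "unmarked") # speck removed
})
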