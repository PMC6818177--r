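test_that("window/step configuration is validated", {
  tr <- make_track(10, 59, assay = "h3k4me1")
  expect_error(call_enhancers(tr, c(chr1 = 1e5), no_promoters(),
                              window = 500, step = 600), "step")
  expect_error(call_enhancers(tr, c(chr1 = 1e5), no_promoters(),
                              window = 0), "window")
  bad <- make_track(10, 59, assay = "mnase")
  expect_error(call_enhancers(bad, c(chr1 = 1e5), no_promoters()),
               "H3K4me1")
})

test_that("pure background yields at most ~1 spurious peak per 6 Mb", {
  n_peaks <- vapply(1:20, function(s) {
    set.seed(700 + s)
    tr <- background_track(180000, 6e6)
    nrow(call_enhancers(tr, c(chrB = 6e6), no_promoters()))
  }, 0)
  expect_lte(mean(n_peaks), 1)
})

test_that("planted 10-fold enhancers are recovered with >= 50% reciprocal overlap", {
  sim <- cached_sim()
  prom <- promoters_of(sim$genes, genome = sim$genome)
  truth <- sim$truth$enhancers
  for (cell in c("NSC", "Neuron")) {
    called <- call_enhancers(sim$tracks[[paste0(cell, ".h3k4me1")]],
                             sim$genome, prom)
    act <- truth[sim$truth$enhancer_active[, cell], ]
    rec <- vapply(seq_len(nrow(act)), function(i) {
      cand <- which(called$start < act$end[i] & called$end > act$start[i])
      if (!length(cand)) return(0)
      max(reciprocal_overlap(act$start[i], act$end[i],
                             called$start[cand], called$end[cand]))
    }, 0)
    expect_gte(mean(rec >= 0.5), 0.9)
    # and no called peak touches a promoter
    expect_equal(nrow(epilineage:::overlap_hits(called, prom)), 0)
  }
})

test_that("an enriched region inside a promoter is discarded", {
  set.seed(44)
  genome <- c(chr1 = 2e5)
  bg <- floor(runif(6000, 0, genome - 49))
  peak <- rep(50500, 500) + floor(runif(500) * 900)  # inside promoter below
  tr <- make_track(c(bg, peak), c(bg, peak) + 49, assay = "h3k4me1")
  prom <- data.frame(chrom = "chr1", start = 50000, end = 52000,
                     strand = ".", gene_id = "g1", stringsAsFactors = FALSE)
  called <- call_enhancers(tr, genome, prom)
  expect_equal(nrow(epilineage:::overlap_hits(called, prom)), 0)
  # without the promoter the same region is called
  called2 <- call_enhancers(tr, genome, no_promoters())
  expect_gte(nrow(epilineage:::overlap_hits(
    called2, data.frame(chrom = "chr1", start = 50500, end = 51400))), 1)
})

test_that("target assignment follows proximal-border distance with ties and cutoff", {
  enh <- data.frame(chrom = "chr1", start = 5000, end = 6000)
  genes <- data.frame(gene_id = c("gA", "gB"), chrom = "chr1",
                      start = c(6500, 20000), end = c(7500, 21000),
                      strand = "+", tss = c(6500, 20000), length_kb = 1,
                      stringsAsFactors = FALSE)
  t1 <- assign_targets(enh, genes)
  expect_equal(t1$target, "gA")
  expect_equal(t1$distance, 500)
  genes$tss[1] <- 5500  # inside the enhancer
  expect_equal(assign_targets(enh, genes)$distance[1], 0)
  genes$tss <- c(16001, 16001); genes$gene_id <- c("gB", "gA")
  t3 <- assign_targets(enh, genes)
  expect_false(t3$assigned)  # 10,001 bp from the proximal border
  genes$tss <- c(16000, 16000)
  t4 <- assign_targets(enh, genes)
  expect_true(t4$assigned)
  expect_equal(t4$target, "gA")  # tie broken by smaller gene_id
  expect_true(all(t4$distance[t4$assigned] <= 10000))
})

test_that("H3K9ac+ enhancer sets split into specific and shared", {
  e1 <- data.frame(chrom = "chr1", start = c(100, 5000), end = c(600, 5500),
                   strand = ".", stringsAsFactors = FALSE)
  res_id <- specific_h3k9ac_enhancers(e1, e1, c(TRUE, TRUE), c(TRUE, TRUE))
  expect_equal(nrow(res_id$a_specific), 0)
  expect_equal(nrow(res_id$shared_a), 2)
  e2 <- data.frame(chrom = "chr1", start = 9000, end = 9500, strand = ".",
                   stringsAsFactors = FALSE)
  res_dis <- specific_h3k9ac_enhancers(e1, e2, c(TRUE, TRUE), TRUE)
  expect_equal(nrow(res_dis$shared_a), 0)
  expect_equal(nrow(res_dis$a_specific), 2)
  expect_equal(nrow(res_dis$b_specific), 1)
})

test_that("planted neuron-/glia-specific acetylated enhancers classify correctly", {
  sim <- cached_sim()
  prom <- promoters_of(sim$genes, genome = sim$genome)
  truth <- sim$truth$enhancers
  called <- list(); status <- list()
  for (cell in c("Neuron", "Glia")) {
    called[[cell]] <- call_enhancers(sim$tracks[[paste0(cell, ".h3k4me1")]],
                                     sim$genome, prom)
    map <- assign_states(
      binarize_mark(sim$tracks[[paste0(cell, ".h3k9ac")]], sim$genome),
      binarize_mark(sim$tracks[[paste0(cell, ".h3k27me3")]], sim$genome))
    status[[cell]] <- enhancer_h3k9ac_status(called[[cell]], map)
  }
  res <- specific_h3k9ac_enhancers(called$Neuron, called$Glia,
                                   status$Neuron, status$Glia)
  hits_class <- function(set, cls) {
    tr <- truth[truth$class == cls, ]
    nrow(epilineage:::overlap_hits(set, tr))
  }
  # neuron-specific calls should be planted neuron-class enhancers
  expect_gte(hits_class(res$a_specific, "neuron") /
               max(nrow(res$a_specific), 1), 0.9)
  expect_gte(hits_class(res$b_specific, "glia") /
               max(nrow(res$b_specific), 1), 0.9)
  # and recover >= 90% of the planted specific classes
  expect_gte(hits_class(res$a_specific, "neuron") / sum(truth$class == "neuron"),
             0.9)
  expect_gte(hits_class(res$b_specific, "glia") / sum(truth$class == "glia"),
             0.9)
})

test_that("hypergeometric enrichment matches the combinatorial oracle", {
  universe <- sprintf("u%02d", 1:20)
  sets <- list(hit = universe[1:5], miss = universe[16:20])
  res <- gene_set_enrichment(universe[1:5], sets, universe)
  expect_equal(res$p[res$set == "hit"], 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$p[res$set == "miss"], 1)
  sat <- gene_set_enrichment(universe, sets, universe)
  expect_true(all(sat$p == 1))
  expect_error(gene_set_enrichment("x", sets, character()), "universe")
  expect_error(gene_set_enrichment("zz", sets, universe), "contained")
})

test_that("GMT files round-trip and the generator's sets match the blocks", {
  sim <- cached_sim()
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sim$truth$gene_sets, path)
  back <- read_gmt(path)
  expect_identical(back, sim$truth$gene_sets)
  # enrichment of neuron-specific enhancer targets in the neuron set
  tgt <- sim$truth$enhancers
  q <- unique(tgt$target[tgt$class == "neuron"])
  res <- gene_set_enrichment(q, back, sim$genes$gene_id)
  expect_equal(res$set[1], "neuron_specific")
  expect_lt(res$p[1], 1e-10)
  expect_equal(sum(res$top), 4)  # only 4 sets exist
})
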