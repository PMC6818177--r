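test_that("BED parsing keeps half-open coordinates and strand column", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=x",
               "chr1\t100\t200",
               "chr1\t100\t200\tx\t0\t-",
               "chr2\t5\t6\ty\t1\t+"), path)
  df <- read_bed(path)
  expect_equal(nrow(df), 3)
  expect_equal(df$start, c(100, 100, 5))
  expect_equal(df$end, c(200, 200, 6))
  expect_equal(df$strand, c(".", "-", "+"))
})

test_that("malformed BED records raise errors naming the line", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t200\t100"), path)
  expect_error(read_bed(path), "line 2")
  writeLines(c("chr1\tx\t200"), path)
  expect_error(read_bed(path), "line 1")
  writeLines("chr1\t100", path)
  expect_error(read_bed(path), "fewer than 3")
})

test_that("BED round-trip is the identity on valid records", {
  df <- genomic_intervals(c("chr1", "chr2"), c(0, 50), c(10, 99),
                          c("+", "-"))
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(df, path)
  back <- read_bed(path)
  expect_equal(back$start, df$start)
  expect_equal(back$end, df$end)
  expect_equal(back$strand, df$strand)
})

test_that("GTF coordinates convert to 0-based half-open and TSS follows strand", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\ttranscript\t1001\t2000\t.\t+\t.\tgene_id "gA"; transcript_id "gA.1";',
    'chr1\tsrc\texon\t1001\t2000\t.\t+\t.\tgene_id "gA"; transcript_id "gA.1";',
    'chr1\tsrc\ttranscript\t5001\t6000\t.\t-\t.\tgene_id "gB"; transcript_id "gB.1";',
    'chr1\tsrc\texon\t5001\t6000\t.\t-\t.\tgene_id "gB"; transcript_id "gB.1";'),
    path)
  g <- read_gtf_genes(path)
  a <- g[g$gene_id == "gA", ]
  b <- g[g$gene_id == "gB", ]
  expect_equal(c(a$start, a$end, a$tss), c(1000, 2000, 1000))
  expect_equal(b$tss, 5999)
  expect_equal(a$length_kb, 1)
})

test_that("multi-transcript genes collapse to the longest exonic transcript", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\ts\ttranscript\t1001\t2200\t.\t+\t.\tgene_id "g"; transcript_id "t1";',
    'chr1\ts\texon\t1001\t1600\t.\t+\t.\tgene_id "g"; transcript_id "t1";',
    'chr1\ts\texon\t1601\t2200\t.\t+\t.\tgene_id "g"; transcript_id "t1";',
    'chr1\ts\ttranscript\t1001\t1800\t.\t+\t.\tgene_id "g"; transcript_id "t2";',
    'chr1\ts\texon\t1001\t1800\t.\t+\t.\tgene_id "g"; transcript_id "t2";'),
    path)
  g <- read_gtf_genes(path)
  expect_equal(nrow(g), 1)
  expect_equal(g$length_kb, 1.2)  # 0.6 + 0.6 beats 0.8
  expect_equal(c(g$start, g$end), c(1000, 2200))
})

test_that("GTF errors: missing gene_id, conflicting strand", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines('chr1\ts\ttranscript\t1\t10\t.\t+\t.\tfoo "bar";', path)
  expect_error(read_gtf_genes(path), "gene_id")
  writeLines(c(
    'chr1\ts\ttranscript\t1\t10\t.\t+\t.\tgene_id "g"; transcript_id "t1";',
    'chr1\ts\ttranscript\t21\t30\t.\t-\t.\tgene_id "g"; transcript_id "t2";'),
    path)
  expect_error(read_gtf_genes(path), "strand")
})

test_that("gene models survive a GTF write/read round trip", {
  sim <- cached_sim()
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf_genes(sim$genes, path)
  back <- read_gtf_genes(path)
  back <- back[match(sim$genes$gene_id, back$gene_id), ]
  expect_equal(back$start, sim$genes$start)
  expect_equal(back$end, sim$genes$end)
  expect_equal(back$tss, sim$genes$tss)
  expect_equal(back$length_kb, sim$genes$length_kb)
})

test_that("midpoint and overlap counting follow their definitions", {
  tr <- make_track(95, 105)
  expect_equal(count_reads(tr, genomic_intervals("chr1", 100, 110)),
               1L)  # midpoint 100 in [100,110)
  expect_equal(count_reads(tr, genomic_intervals("chr1", 100, 110),
                           mode = "overlap"), 1L)
  expect_equal(count_reads(tr, genomic_intervals("chr1", 110, 120),
                           mode = "overlap"), 0L)
  expect_equal(count_reads(tr, genomic_intervals("chr1", 101, 110)),
               0L)  # midpoint 100 excluded
  expect_equal(count_reads(tr, data.frame(chrom = character(),
                                          start = numeric(),
                                          end = numeric())), integer(0))
})

test_that("midpoint counting over a partition conserves reads", {
  set.seed(11)
  starts <- floor(runif(1000, 0, 990))
  tr <- make_track(starts, starts + sample(1:10, 1000, TRUE))
  bins <- genomic_intervals("chr1", seq(0, 900, 100), seq(100, 1000, 100))
  cnt <- count_reads(tr, bins, mode = "midpoint")
  expect_equal(sum(cnt), 1000)
  expect_equal(cnt, count_reads_oracle(tr$reads, bins, "midpoint"))
})

test_that("both counting modes match the brute-force scan on random cases", {
  set.seed(12)
  for (rep in 1:5) {
    rs <- floor(runif(100, 0, 5000))
    tr <- make_track(rs, rs + sample(20:80, 100, TRUE))
    qs <- floor(runif(15, 0, 5000))
    regions <- genomic_intervals("chr1", qs, qs + sample(50:800, 15, TRUE))
    for (mode in c("midpoint", "overlap"))
      expect_equal(count_reads(tr, regions, mode = mode),
                   count_reads_oracle(tr$reads, regions, mode))
  }
})

test_that("RPM and RPKM implement their formulas and scaling laws", {
  expect_equal(rpm_normalize(50, 1e7), 5)
  expect_equal(rpm_normalize(0, 1e7), 0)
  expect_equal(rpm_normalize(c(1, 2, 3), 1e6), c(1, 2, 3))
  expect_error(rpm_normalize(1, 0), "positive")
  a <- rpm_normalize(3, 5e6); b <- rpm_normalize(4, 5e6)
  expect_equal(rpm_normalize(7, 5e6), a + b)  # linearity
  expect_equal(rpkm(200, 2, 1e7), 10)
  expect_equal(rpkm(0, 2, 1e7), 0)
  expect_equal(rpkm(200, 2, 2e7), 5)  # doubling total halves RPKM
  expect_error(rpkm(1, 0, 1e6), "length_kb")
})

test_that("signal matrices round-trip through TSV at full precision", {
  m <- signal_matrix(matrix(c(1 / 3, pi, -2.5, 0, 1e-8, 123456.789,
                              1, 2, 3, 4, 5, 6), nrow = 3),
                     paste0("r", 1:3), paste0("c", 1:4), units = "RPM")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(m, path)
  back <- read_matrix(path)
  expect_equal(rownames(back), rownames(m))
  expect_equal(colnames(back), colnames(m))
  expect_lt(max(abs(back - m)), 1e-10)
  expect_equal(attr(back, "units"), "RPM")

  empty <- signal_matrix(matrix(numeric(0), 0, 2), character(0),
                         c("a", "b"))
  write_matrix(empty, path)
  back <- read_matrix(path)
  expect_equal(dim(back), c(0L, 2L))

  writeLines(c("id\ta\tb", "r1\t1\t2", "r2\t3"), path)
  expect_error(read_matrix(path), "ragged")
})

test_that("merge_intervals fuses overlapping/adjacent intervals and is idempotent", {
  df <- genomic_intervals(rep("chr1", 3), c(0, 50, 200), c(60, 100, 300))
  m <- merge_intervals(df)
  expect_equal(m$start, c(0, 200))
  expect_equal(m$end, c(100, 300))
  expect_identical(merge_intervals(m)[, c("start", "end")],
                   m[, c("start", "end")])
  adj <- genomic_intervals(c("chr1", "chr1"), c(0, 100), c(100, 200))
  expect_equal(nrow(merge_intervals(adj)), 1)
})
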