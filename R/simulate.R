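SIM_CELLS <- c("NSC", "GNP", "Glia", "Neuron")
SIM_ASSAYS <- c("mnase", "h3k9ac", "h3k27me3", "h3k4me1")

#' Simulation configuration
#'
#' Defaults define the study conditions the package's tests and acceptance
#' checks run under: four cell types on the lineage NSC -> GNP -> glia with
#' neurons branching directly from NSCs, a 6-Mb single-chromosome genome
#' with 1000 genes and 300 planted enhancers, and per-track declared
#' library sizes of 2 million reads of which roughly half a million fall in
#' modeled regions.
#'
#' @param seed integer RNG seed; fixed seed gives byte-identical outputs.
#' @param n_genes number of genes tiled along the chromosome.
#' @param n_enhancers number of planted enhancers (each 1-8 kb from its
#'   target TSS, outside every promoter).
#' @param chrom_length chromosome length in bp; must allow >= 6 kb per
#'   gene.
#' @param reads_per_track declared total mapped reads per track (the RPM
#'   denominator).
#' @param expression_blocks fractions of genes that are progenitor-high,
#'   differentiated-high, neuron-specific and glia-specific; remaining
#'   genes have no block effect.
#' @param h3k27me3_edge_scales per-edge Gaussian drift standard deviations
#'   (log2 signal) along NSC->GNP, GNP->Glia, NSC->Neuron.
#' @param ndr_depth_coupling strength of the expression -> NDR-depletion
#'   coupling (0 disables it).
#' @param enhancer_fold H3K4me1 enrichment of an active enhancer over
#'   background.
#' @param background_rate genome-wide background, reads per bp.
#' @param block_effect log2 effect size of an expression block.
#' @param expr_mu_mean,expr_mu_sd mean/sd of per-gene baseline log2
#'   expression.
#' @param expr_noise_sd per-gene-per-cell log2 expression noise.
#' @param expr_lib_size expected expression library size per cell type.
#' @param k9ac_coupling,k27me3_coupling log2-scale coupling of promoter
#'   H3K9ac (positive) and H3K27me3 (negative) to expression.
#' @param hm_noise_sd log2 noise on histone-mark latents.
#' @param promoter_reads,enhancer_reads expected modeled ChIP reads per
#'   track in promoters / enhancers.
#' @param mnase_reads_per_gene expected MNase array reads per gene window.
#' @param enhancer_width planted enhancer width in bp.
#' @param gene_length gene (transcript) length in bp.
#' @param read_length emitted read length in bp.
#' @param chrom_name chromosome name.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1,
                       n_genes = 1000,
                       n_enhancers = 300,
                       chrom_length = 6e6,
                       reads_per_track = 2e6,
                       expression_blocks = c(progenitor = 0.15,
                                             differentiated = 0.15,
                                             neuron = 0.10, glia = 0.10),
                       h3k27me3_edge_scales = c(nsc_gnp = 0.3,
                                                gnp_glia = 0.6,
                                                nsc_neuron = 1.0),
                       ndr_depth_coupling = 0.8,
                       enhancer_fold = 10,
                       background_rate = 0.03,
                       block_effect = 1.5,
                       expr_mu_mean = 3, expr_mu_sd = 2,
                       expr_noise_sd = 0.25,
                       expr_lib_size = 2e6,
                       k9ac_coupling = 0.8, k27me3_coupling = 0.9,
                       hm_noise_sd = 0.2,
                       promoter_reads = 2.5e5, enhancer_reads = 5e4,
                       mnase_reads_per_gene = 300,
                       enhancer_width = 900,
                       gene_length = 1400,
                       read_length = 49,
                       chrom_name = "chrS") {
  cfg <- as.list(environment())
  stopifnot(n_genes > 0, n_enhancers > 0, chrom_length > 0,
            reads_per_track > 0, enhancer_fold > 0, background_rate > 0)
  if (any(expression_blocks < 0) || sum(expression_blocks) > 1)
    stop("expression_blocks must be non-negative fractions summing to <= 1")
  if (any(h3k27me3_edge_scales <= 0)) stop("edge scales must be > 0")
  class(cfg) <- "sim_config"
  cfg
}

# per-slot geometry (bp offsets within each gene's slot); requires
# slot >= 6000 so that promoters stay inside the slot and enhancer gaps
# keep the intended target the nearest TSS
SLOT_GENE_START <- 2300
SLOT_ENH_LEFT <- 350
SLOT_ENH_RIGHT <- 4750

sim_seed <- function(seed, stage) as.integer((seed + 99991 * stage) %% 2147483629)

#' Simulate the full synthetic dataset
#'
#' Generates the toy genome, gene models, per-cell-type expression counts
#' and read tracks, plus the planted ground truth (latent matrices,
#' enhancer intervals with targets and classes, lineage tree). Latent
#' structure: promoter and enhancer log2 H3K27me3 drifts along the lineage
#' tree with the configured per-edge scales; expression and H3K9ac carry a
#' progenitor/differentiated two-block structure with neuron- and
#' glia-specific sub-blocks; expression couples positively to H3K9ac,
#' negatively to H3K27me3 and to NDR nucleosome occupancy; H3K4me1 is
#' enriched `enhancer_fold`-fold in active planted enhancers. All read
#' counts are Poisson draws from the expected densities; reads are emitted
#' as 49-bp intervals.
#'
#' @param config a [sim_config()].
#' @param assays which read tracks to generate (default all four); the
#'   latent phase is identical regardless, so any subset is consistent
#'   with the full run.
#' @param dir optional output directory; when given, all files (genome.tsv,
#'   genes.gtf, reads/*.bed, expression_counts.tsv, truth/*) are written.
#' @return list of class `"sim_data"`: `config`, `genome`, `genes`,
#'   `expression` (an [expression_table()]), `tracks` (named
#'   `"<cell>.<assay>"`), `truth`.
#' @export
simulate_dataset <- function(config = sim_config(),
                             assays = SIM_ASSAYS, dir = NULL) {
  assays <- match.arg(assays, SIM_ASSAYS, several.ok = TRUE)
  slot <- floor(config$chrom_length / config$n_genes)
  if (slot < 6000)
    stop("genome too short: ", format_bp(config$chrom_length), " bp for ",
         config$n_genes, " genes needs >= 6 kb per gene")
  genome <- stats::setNames(config$chrom_length, config$chrom_name)

  truth <- simulate_latents(config, slot)
  genes <- truth$genes

  tracks <- list()
  for (ci in seq_along(SIM_CELLS)) {
    for (ai in seq_along(SIM_ASSAYS)) {
      assay <- SIM_ASSAYS[ai]
      if (!assay %in% assays) next
      set.seed(sim_seed(config$seed, 10 + ci * 10 + ai))
      reads <- switch(assay,
        mnase = sim_mnase_reads(config, truth, ci),
        h3k9ac = sim_hm_reads(config, truth, ci, "k9"),
        h3k27me3 = sim_hm_reads(config, truth, ci, "k27"),
        h3k4me1 = sim_h3k4me1_reads(config, truth, ci))
      tracks[[paste(SIM_CELLS[ci], assay, sep = ".")]] <-
        read_track(SIM_CELLS[ci], assay, reads, config$reads_per_track,
                   genome)
    }
  }

  expr <- expression_table(truth$counts, genes)
  sim <- structure(list(config = config, genome = genome, genes = genes,
                        expression = expr, tracks = tracks, truth = truth),
                   class = "sim_data")
  if (!is.null(dir)) write_simulation(sim, dir)
  sim
}

#' @export
print.sim_data <- function(x, ...) {
  cat(sprintf("<sim_data> %d genes, %d enhancers, %s bp genome, %d tracks\n",
              nrow(x$genes), nrow(x$truth$enhancers),
              format_bp(x$genome[[1]]), length(x$tracks)))
  invisible(x)
}

# latent phase: layout, blocks, latent matrices, expression counts.
# Uses its own sub-seed so the result is independent of which assays are
# requested downstream.
simulate_latents <- function(config, slot) {
  set.seed(sim_seed(config$seed, 1))
  n <- config$n_genes
  cells <- SIM_CELLS
  ids <- sprintf("g%04d", seq_len(n))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  gstart <- (seq_len(n) - 1) * slot + SLOT_GENE_START
  gend <- gstart + config$gene_length
  tss <- ifelse(strand == "+", gstart, gend - 1)
  genes <- data.frame(gene_id = ids, chrom = config$chrom_name,
                      start = gstart, end = gend, strand = strand, tss = tss,
                      length_kb = config$gene_length / 1000,
                      stringsAsFactors = FALSE)

  # expression blocks
  fr <- config$expression_blocks
  sizes <- round(fr * n)
  pool <- sample.int(n)
  block <- rep("none", n)
  off <- 0
  for (b in names(sizes)) {
    if (sizes[[b]] > 0)
      block[pool[(off + 1):(off + sizes[[b]])]] <- b
    off <- off + sizes[[b]]
  }
  # block indicator per cell: which cells a block elevates
  elev <- list(progenitor = c("NSC", "GNP"),
               differentiated = c("Glia", "Neuron"),
               neuron = "Neuron", glia = "Glia", none = character())
  B <- sapply(cells, function(cl)
    config$block_effect * vapply(block, function(b) cl %in% elev[[b]], TRUE))

  mu <- stats::rnorm(n, config$expr_mu_mean, config$expr_mu_sd)
  E <- mu + B + matrix(stats::rnorm(n * 4, 0, config$expr_noise_sd), n, 4)
  dimnames(E) <- list(ids, cells)

  # lineage drift (log2), NSC at the root state
  s <- config$h3k27me3_edge_scales
  D <- matrix(0, n, 4, dimnames = list(ids, cells))
  D[, "GNP"] <- stats::rnorm(n, 0, s[["nsc_gnp"]])
  D[, "Glia"] <- D[, "GNP"] + stats::rnorm(n, 0, s[["gnp_glia"]])
  D[, "Neuron"] <- stats::rnorm(n, 0, s[["nsc_neuron"]])

  Ec <- E - mean(E)
  A9 <- config$k9ac_coupling * Ec +
    matrix(stats::rnorm(n * 4, 0, config$hm_noise_sd), n, 4)
  L27 <- -config$k27me3_coupling * Ec + D +
    matrix(stats::rnorm(n * 4, 0, config$hm_noise_sd), n, 4)
  dimnames(A9) <- dimnames(L27) <- list(ids, cells)

  # planted enhancers: neuron-/glia-specific classes target the matching
  # gene blocks; shared enhancers target other genes and are active (and
  # acetylated) in the progenitors
  ne <- config$n_enhancers
  n_spec <- min(round(0.2 * ne), sum(block == "neuron"), sum(block == "glia"))
  n_shared <- ne - 2 * n_spec
  tgt_neu <- sample(which(block == "neuron"), n_spec)
  tgt_glia <- sample(which(block == "glia"), n_spec)
  rest <- setdiff(seq_len(n), c(tgt_neu, tgt_glia))
  tgt_shared <- sample(rest, n_shared)
  tgt <- c(tgt_neu, tgt_glia, tgt_shared)
  eclass <- c(rep("neuron", n_spec), rep("glia", n_spec),
              rep("shared", n_shared))
  side <- sample(c("left", "right"), ne, replace = TRUE)
  slot0 <- (tgt - 1) * slot
  estart <- ifelse(side == "left", slot0 + SLOT_ENH_LEFT,
                   slot0 + SLOT_ENH_RIGHT)
  enh <- data.frame(chrom = config$chrom_name, start = estart,
                    end = estart + config$enhancer_width, strand = ".",
                    target = ids[tgt], class = eclass,
                    stringsAsFactors = FALSE)
  ord <- order(enh$start)
  enh <- enh[ord, , drop = FALSE]
  rownames(enh) <- NULL
  eclass <- enh$class

  # enhancer activity (H3K4me1) and acetylation (H3K9ac) per cell
  act <- sapply(cells, function(cl) switch(cl,
    NSC = , GNP = eclass == "shared",
    Neuron = eclass == "neuron",
    Glia = eclass == "glia"))
  if (ne == 1) act <- matrix(act, nrow = 1, dimnames = list(NULL, cells))

  etss <- stats::setNames(genes$tss, genes$gene_id)[enh$target]
  Ae9 <- 1.5 * act + matrix(stats::rnorm(ne * 4, 0, 0.3), ne, 4)
  De <- matrix(0, ne, 4)
  De[, 2] <- stats::rnorm(ne, 0, s[["nsc_gnp"]])
  De[, 3] <- De[, 2] + stats::rnorm(ne, 0, s[["gnp_glia"]])
  De[, 4] <- stats::rnorm(ne, 0, s[["nsc_neuron"]])
  Le27 <- -config$k27me3_coupling * (E[enh$target, ] - mean(E)) + De +
    matrix(stats::rnorm(ne * 4, 0, config$hm_noise_sd), ne, 4)
  colnames(Ae9) <- colnames(De) <- colnames(Le27) <- cells
  eid <- sprintf("%s:%s-%s", enh$chrom, format_bp(enh$start),
                 format_bp(enh$end))
  rownames(Ae9) <- rownames(De) <- rownames(Le27) <- eid

  # expression counts, Poisson per gene x cell, library-calibrated
  scale_e <- config$expr_lib_size / mean(colSums(2^E))
  counts <- matrix(stats::rpois(n * 4, 2^E * scale_e), n, 4,
                   dimnames = list(ids, cells))

  list(genes = genes, block = stats::setNames(block, ids),
       E = E, D = D, A9 = A9, L27 = L27,
       enhancers = enh, enhancer_active = act, Ae9 = Ae9, Le27 = Le27,
       counts = counts,
       tree = reference_lineage(config$h3k27me3_edge_scales),
       gene_sets = list(
         neuron_specific = ids[block == "neuron"],
         glia_specific = ids[block == "glia"],
         progenitor_high = ids[block == "progenitor"],
         differentiated_high = ids[block == "differentiated"]))
}

# uniform background reads over the whole chromosome, optionally excluding
# intervals already modeled (mask as [start,end) columns)
sim_background_reads <- function(config, n_expected, mask = NULL) {
  n <- stats::rpois(1, n_expected)
  p <- floor(stats::runif(n, 0, config$chrom_length))
  if (!is.null(mask) && length(p)) {
    inside <- rep(FALSE, length(p))
    idx <- findInterval(p, mask$start)
    hit <- idx >= 1
    inside[hit] <- p[hit] < mask$end[idx[hit]]
    p <- p[!inside]
  }
  p
}

reads_from_midpoints <- function(config, p) {
  half <- (config$read_length - 1) / 2
  p <- pmin(pmax(p, ceiling(half)), config$chrom_length - ceiling(half) - 1)
  data.frame(chrom = config$chrom_name, start = floor(p - half),
             end = floor(p - half) + config$read_length, strand = ".",
             stringsAsFactors = FALSE)
}

# MNase: phased nucleosome arrays around each TSS with an
# expression-coupled NDR, plus genome-wide uniform background
sim_mnase_reads <- function(config, truth, ci) {
  genes <- truth$genes
  n <- nrow(genes)
  flank <- 1000; cw <- 10
  centers <- seq(-flank + cw / 2, flank - cw / 2, by = cw)
  peaks <- c(-180, 120, 295, 470)
  phi <- rowSums(sapply(peaks, function(m) exp(-(centers - m)^2 / (2 * 40^2))))
  bgcell <- config$background_rate * cw
  base <- config$mnase_reads_per_gene * phi / sum(phi) + bgcell
  ndr <- centers >= -150 & centers < 50
  z <- as.vector(scale(truth$E[, ci]))
  lam <- matrix(base, n, length(centers), byrow = TRUE)
  lam[, ndr] <- lam[, ndr] * exp(-config$ndr_depth_coupling * z)
  cnt <- matrix(stats::rpois(length(lam), lam), n, ncol(lam))
  gi <- rep(seq_len(n), times = rowSums(cnt))
  cellof <- rep(rep(seq_along(centers), n),
                times = as.vector(t(cnt)))
  o <- centers[cellof] - cw / 2 + floor(stats::runif(length(cellof)) * cw)
  p <- ifelse(genes$strand[gi] == "+", genes$tss[gi] + o, genes$tss[gi] - o)
  # background outside the modeled TSS windows (the in-window uniform term
  # is part of the array density above)
  minus <- genes$strand == "-"
  mask <- data.frame(start = ifelse(minus, genes$tss - flank + 1,
                                    genes$tss - flank))
  mask$end <- mask$start + 2 * flank
  bg <- sim_background_reads(
    config, config$background_rate * config$chrom_length, mask)
  reads_from_midpoints(config, c(p, bg))
}

# promoter + enhancer histone-mark reads from 2^latent weights, plus
# genome-wide background
sim_hm_reads <- function(config, truth, ci, which_mark) {
  genes <- truth$genes
  if (which_mark == "k9") {
    wp <- 2^truth$A9[, ci]; we <- 2^truth$Ae9[, ci]
  } else {
    wp <- 2^truth$L27[, ci]; we <- 2^truth$Le27[, ci]
  }
  scale_p <- config$promoter_reads / mean(colSums(
    if (which_mark == "k9") 2^truth$A9 else 2^truth$L27))
  scale_e <- config$enhancer_reads / mean(colSums(
    if (which_mark == "k9") 2^truth$Ae9 else 2^truth$Le27))
  np <- stats::rpois(length(wp), wp * scale_p)
  pstart <- pmax(genes$tss - 1000, 0)
  pend <- pmin(genes$tss + 1000, config$chrom_length)
  p1 <- rep(pstart, np) + floor(stats::runif(sum(np)) *
                                  rep(pend - pstart, np))
  enh <- truth$enhancers
  ne <- stats::rpois(length(we), we * scale_e)
  p2 <- rep(enh$start, ne) + floor(stats::runif(sum(ne)) *
                                     config$enhancer_width)
  bg <- sim_background_reads(config,
                             config$background_rate * config$chrom_length)
  reads_from_midpoints(config, c(p1, p2, bg))
}

# H3K4me1: background everywhere plus enhancer_fold x background within
# active enhancers
sim_h3k4me1_reads <- function(config, truth, ci) {
  enh <- truth$enhancers
  active <- truth$enhancer_active[, ci]
  extra <- (config$enhancer_fold - 1) * config$background_rate *
    config$enhancer_width
  ne <- stats::rpois(nrow(enh), ifelse(active, extra, 0))
  p1 <- rep(enh$start, ne) + floor(stats::runif(sum(ne)) *
                                     config$enhancer_width)
  bg <- sim_background_reads(config,
                             config$background_rate * config$chrom_length)
  reads_from_midpoints(config, c(p1, bg))
}

#' Permute the gene-to-expression assignment (negative control)
#'
#' Uniformly permutes which gene carries which expression value(s); the
#' multiset of values is unchanged. Used as the label-shuffle null for ROC
#' evaluation.
#'
#' @param x named numeric vector or matrix with gene rownames.
#' @param seed RNG seed.
#' @return object of the same shape with names/rownames fixed and values
#'   permuted.
#' @export
shuffle_labels <- function(x, seed) {
  set.seed(as.integer(seed %% 2147483629))
  if (is.matrix(x)) {
    if (nrow(x) == 0) stop("empty table")
    perm <- sample.int(nrow(x))
    y <- x[perm, , drop = FALSE]
    rownames(y) <- rownames(x)
  } else {
    if (length(x) == 0) stop("empty table")
    perm <- sample.int(length(x))
    y <- stats::setNames(x[perm], names(x))
  }
  y
}

#' Expected chromatin-state map planted by the generator
#'
#' Computes, per 200-bp bin, the generator's expected H3K9ac and H3K27me3
#' read rates (promoter + enhancer + background components) and marks a
#' bin for a mark when its expected rate exceeds `fold_cut` times
#' background; the two binary vectors combine as in [assign_states()].
#'
#' @param sim a [simulate_dataset()] result.
#' @param cell_type one of the four cell types.
#' @param bin_size state bin width (default 200).
#' @param fold_cut enrichment multiple defining a planted mark (default 3).
#' @return a `state_map` (see [assign_states()]).
#' @export
planted_state_map <- function(sim, cell_type, bin_size = 200, fold_cut = 3) {
  config <- sim$config
  truth <- sim$truth
  ci <- match(cell_type, SIM_CELLS)
  if (is.na(ci)) stop("unknown cell type: ", cell_type)
  bins <- genome_bins(sim$genome, bin_size)
  bg <- config$background_rate * bin_size
  rate_for <- function(w, scale, regions, width) {
    r <- numeric(nrow(bins))
    h <- overlap_hits(bins, regions)
    if (nrow(h)) {
      ov <- pmin(bins$end[h[, "query"]], regions$end[h[, "subject"]]) -
        pmax(bins$start[h[, "query"]], regions$start[h[, "subject"]])
      dens <- (w * scale / width)[h[, "subject"]]
      r0 <- tapply(ov * dens, h[, "query"], sum)
      r[as.integer(names(r0))] <- r0
    }
    r
  }
  prom <- promoters_of(truth$genes, genome = sim$genome)
  enh <- truth$enhancers
  scale_p9 <- config$promoter_reads / mean(colSums(2^truth$A9))
  scale_p27 <- config$promoter_reads / mean(colSums(2^truth$L27))
  scale_e9 <- config$enhancer_reads / mean(colSums(2^truth$Ae9))
  scale_e27 <- config$enhancer_reads / mean(colSums(2^truth$Le27))
  r9 <- bg + rate_for(2^truth$A9[, ci], scale_p9, prom, 2000) +
    rate_for(2^truth$Ae9[, ci], scale_e9, enh, config$enhancer_width)
  r27 <- bg + rate_for(2^truth$L27[, ci], scale_p27, prom, 2000) +
    rate_for(2^truth$Le27[, ci], scale_e27, enh, config$enhancer_width)
  mk <- function(r) list(bins = bins, marked = as.integer(r >= fold_cut * bg))
  assign_states(mk(r9), mk(r27))
}

#' Write a simulated dataset to disk
#'
#' Emits genome.tsv, genes.gtf, reads/<cell>_<assay>.bed,
#' expression_counts.tsv and a truth/ directory (latent matrices, planted
#' enhancers BED with target and class, lineage tree Newick, gene-set
#' GMT). Deterministic for a fixed-config simulation.
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(file.path(dir, "reads"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  write_genome_table(sim$genome, file.path(dir, "genome.tsv"))
  write_gtf_genes(sim$genes, file.path(dir, "genes.gtf"))
  write_expression_counts(sim$expression,
                          file.path(dir, "expression_counts.tsv"))
  for (nm in names(sim$tracks)) {
    tr <- sim$tracks[[nm]]
    write_bed(tr$reads[, c("chrom", "start", "end")],
              file.path(dir, "reads",
                        paste0(tr$cell_type, "_", tr$assay, ".bed")))
  }
  tr <- sim$truth
  for (mat in c("E", "D", "A9", "L27", "Ae9", "Le27"))
    write_matrix(signal_matrix(tr[[mat]], units = "count"),
                 file.path(dir, "truth", paste0("latent_", mat, ".tsv")))
  enh <- tr$enhancers
  enh$name <- paste(enh$target, enh$class, sep = ";")
  write_bed(enh[, c("chrom", "start", "end", "name")],
            file.path(dir, "truth", "enhancers.bed"))
  writeLines(tr$tree$newick, file.path(dir, "truth", "tree.nwk"))
  write_gmt(tr$gene_sets, file.path(dir, "truth", "gene_sets.gmt"))
  invisible(dir)
}
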