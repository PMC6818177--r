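PIPELINE_STAGES <- c("simulate", "expression", "nucleosome", "states",
                     "enhancers", "signal", "roc", "clustering", "report")

# stage -> stages whose outputs it needs
STAGE_DEPS <- list(
  expression = character(),
  nucleosome = character(),
  states = character(),
  enhancers = character(),
  signal = "enhancers",
  roc = "signal",
  clustering = c("expression", "nucleosome", "signal"),
  report = character())

#' Default pipeline configuration
#'
#' All analysis parameters with their standard values: 10-bp profile bins,
#' +/- 1 kb promoters, the [-150, +50) NDR window, 200-bp state bins with
#' Poisson binarization at p = 1e-4, 1-kb enhancer windows at 100-bp steps
#' with FDR 0.001, 10-kb target assignment, top/bottom-1500 ROC positive
#' sets, DEG FDR 0.05, complete-linkage clustering.
#'
#' @return nested list of defaults (`simulate` block plus `params`).
#' @export
pipeline_defaults <- function() {
  list(
    seed = 1,
    outdir = "epilineage_out",
    stages = PIPELINE_STAGES,
    simulate = list(),      # sim_config() overrides; NULL disables
    inputs = NULL,          # alternatively: genome, gtf, expression, reads dir
    params = list(
      profile_bin = 10,
      profile_flank = 1000,
      promoter_up = 1000, promoter_down = 1000,
      ndr_up = 150, ndr_down = 50,
      state_bin = 200, binarize_p = 1e-4,
      enhancer_window = 1000, enhancer_step = 100, enhancer_fdr = 0.001,
      target_max_dist = 10000,
      roc_k = 1500,
      deg_fdr = 0.05, deg_pseudo = 1,
      linkage = "complete"))
}

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML configuration, rejects unknown keys, fills defaults and
#' checks ranges; every violation is collected and reported in one error.
#'
#' @param path YAML file path (an empty file yields all defaults), or a
#'   list to validate directly.
#' @return normalized configuration list of class `"pipeline_config"`.
#' @export
validate_config <- function(path) {
  if (is.character(path)) {
    if (grepl("\\.toml$", path))
      stop("unsupported config format '.toml'; use YAML")
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg)) cfg <- list()
  } else cfg <- path
  def <- pipeline_defaults()
  errs <- character()
  unknown <- setdiff(names(cfg), names(def))
  if (length(unknown))
    errs <- c(errs, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  if (!is.null(cfg$params)) {
    unknown_p <- setdiff(names(cfg$params), names(def$params))
    if (length(unknown_p))
      errs <- c(errs, paste0("unknown params key(s): ",
                             paste(unknown_p, collapse = ", ")))
  }
  merged <- utils::modifyList(def, cfg[intersect(names(cfg), names(def))])
  p <- merged$params
  num_pos <- c("profile_bin", "profile_flank", "promoter_up", "promoter_down",
               "ndr_up", "ndr_down", "state_bin", "enhancer_window",
               "enhancer_step", "target_max_dist", "roc_k", "deg_pseudo")
  for (k in num_pos)
    if (!is.numeric(p[[k]]) || p[[k]] <= 0)
      errs <- c(errs, paste0("params$", k, " must be a positive number"))
  for (k in c("binarize_p", "enhancer_fdr", "deg_fdr"))
    if (!is.numeric(p[[k]]) || p[[k]] <= 0 || p[[k]] >= 1)
      errs <- c(errs, paste0("params$", k, " must be in (0, 1)"))
  if (is.numeric(p$enhancer_window) && is.numeric(p$enhancer_step) &&
      p$enhancer_window < p$enhancer_step)
    errs <- c(errs, "params$enhancer_window must be >= params$enhancer_step")
  if (!is.character(p$linkage) ||
      !p$linkage %in% c("complete", "average", "ward"))
    errs <- c(errs, "params$linkage must be complete, average or ward")
  bad_stage <- setdiff(merged$stages, PIPELINE_STAGES)
  if (length(bad_stage))
    errs <- c(errs, paste0("unknown stage(s): ",
                           paste(bad_stage, collapse = ", ")))
  if (length(errs))
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  class(merged) <- "pipeline_config"
  merged
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in dependency order on either a simulated
#' dataset (the `simulate` config block) or user-supplied inputs, writes
#' per-stage TSV/BED outputs under `outdir`, and returns a run report with
#' parameter echo, per-file checksums, stage counts, the AUC table,
#' dendrogram Newick strings and topology-match verdicts. Fixed seed and
#' config give identical report checksums.
#'
#' @param config a [validate_config()] result, a path to a YAML config, or
#'   a list of overrides.
#' @return list of class `"run_report"`.
#' @export
run_pipeline <- function(config = list()) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  p <- config$params
  stages <- config$stages
  need <- function(stage, what, value) {
    if (is.null(value))
      stop("stage '", stage, "' requires outputs of stage '", what,
           "'; add it to `stages`")
    value
  }
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(parameters = p, seed = config$seed, stages = stages,
                 counts = list())
  res <- new.env()

  # --- inputs ---------------------------------------------------------
  if ("simulate" %in% stages || is.null(config$inputs)) {
    scfg <- do.call(sim_config, c(list(seed = config$seed), config$simulate))
    sim <- simulate_dataset(scfg,
                            dir = if ("simulate" %in% stages)
                              file.path(outdir, "simulated") else NULL)
    res$genome <- sim$genome
    res$genes <- sim$genes
    res$expr <- sim$expression
    res$tracks <- sim$tracks
    res$sim <- sim
  } else {
    inp <- config$inputs
    res$genome <- read_genome_table(inp$genome)
    res$genes <- read_gtf_genes(inp$gtf)
    res$expr <- read_expression_counts(inp$expression, res$genes)
    res$tracks <- list()
    for (spec in inp$reads) {
      res$tracks[[paste(spec$cell_type, spec$assay, sep = ".")]] <-
        read_track_bed(spec$path, spec$cell_type, spec$assay,
                       spec$total_mapped, res$genome)
    }
  }
  cells <- unique(vapply(res$tracks, `[[`, "", "cell_type"))
  if (length(cells) == 0) cells <- colnames(res$expr$counts)
  track_of <- function(cell, assay) res$tracks[[paste(cell, assay, sep = ".")]]
  promoters <- promoters_of(res$genes, p$promoter_up, p$promoter_down,
                            res$genome)
  report$counts$genes <- nrow(res$genes)

  # --- expression -----------------------------------------------------
  if ("expression" %in% stages) {
    res$degs <- call_degs_all_pairs(res$expr, fdr = p$deg_fdr,
                                    pseudo = p$deg_pseudo)
    res$deg_matrix <- deg_union_matrix(res$expr, res$degs)
    report$counts$degs_union <- nrow(res$deg_matrix)
    utils::write.table(res$degs, file.path(outdir, "deg_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_matrix(res$deg_matrix, file.path(outdir, "deg_rpkm.tsv"))
  }

  # --- nucleosome -----------------------------------------------------
  if ("nucleosome" %in% stages) {
    mnase <- lapply(cells, track_of, assay = "mnase")
    names(mnase) <- cells
    res$ndr <- ndr_matrix(mnase, res$genes, p$ndr_up, p$ndr_down)
    write_matrix(res$ndr, file.path(outdir, "ndr_rpm.tsv"))
    for (cell in cells) {
      prof <- tss_profile(mnase[[cell]], res$genes, p$profile_flank,
                          p$profile_bin, res$genome)
      write_matrix(prof, file.path(outdir,
                                   paste0("tss_profile_", cell, ".tsv")))
    }
    ord <- order_genes_by_ndr(res$ndr[, cells[1]])
    writeLines(ord, file.path(outdir, "genes_by_ndr.txt"))
  }

  # --- chromatin states -----------------------------------------------
  if ("states" %in% stages) {
    res$state_maps <- lapply(cells, function(cell) {
      b9 <- binarize_mark(track_of(cell, "h3k9ac"), res$genome,
                          p$state_bin, p$binarize_p)
      b27 <- binarize_mark(track_of(cell, "h3k27me3"), res$genome,
                           p$state_bin, p$binarize_p)
      assign_states(b9, b27)
    })
    names(res$state_maps) <- cells
    for (cell in cells)
      write_state_map(res$state_maps[[cell]],
                      file.path(outdir, paste0("states_", cell, ".bed")))
    fr <- t(sapply(res$state_maps, state_fractions))
    utils::write.table(fr, file.path(outdir, "state_fractions.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    report$counts$state_fractions <- as.list(as.data.frame(t(fr)))
    if (length(cells) >= 2) {
      for (i in seq_len(length(cells) - 1)) {
        fl <- state_flow(res$state_maps[[cells[i]]],
                         res$state_maps[[cells[i + 1]]])
        utils::write.table(fl$flow,
                           file.path(outdir, paste0("state_flow_", cells[i],
                                                    "_", cells[i + 1], ".tsv")),
                           sep = "\t", quote = FALSE, col.names = NA)
      }
    }
  }

  # --- enhancers ------------------------------------------------------
  if ("enhancers" %in% stages) {
    res$enhancers <- lapply(cells, function(cell)
      call_enhancers(track_of(cell, "h3k4me1"), res$genome, promoters,
                     p$enhancer_window, p$enhancer_step, p$enhancer_fdr))
    names(res$enhancers) <- cells
    report$counts$enhancers <- lapply(res$enhancers, nrow)
    for (cell in cells) {
      e <- res$enhancers[[cell]]
      e$name <- "enh"
      e$score <- round(-log10(pmax(e$q, 1e-300)), 2)
      write_bed(e, file.path(outdir, paste0("enhancers_", cell, ".bed")))
    }
  }

  # --- regulatory signal ----------------------------------------------
  if ("signal" %in% stages) {
    enh_sets <- need("signal", "enhancers", res$enhancers)
    res$consensus <- consensus_enhancers(enh_sets)
    res$targets <- assign_targets(res$consensus, res$genes,
                                  p$target_max_dist)
    report$counts$consensus_enhancers <- nrow(res$consensus)
    res$signal <- list()
    for (mark in c("h3k9ac", "h3k27me3")) {
      tr <- lapply(cells, track_of, assay = mark)
      res$signal[[paste0(mark, "_promoter")]] <-
        signal_matrix_across_cells(tr, promoters)
      res$signal[[paste0(mark, "_enhancer")]] <-
        signal_matrix_across_cells(tr, res$consensus)
    }
    for (nm in names(res$signal))
      write_matrix(res$signal[[nm]],
                   file.path(outdir, paste0("signal_", nm, ".tsv")))
    utils::write.table(res$targets, file.path(outdir, "enhancer_targets.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- ROC ------------------------------------------------------------
  if ("roc" %in% stages) {
    sig <- need("roc", "signal", res$signal)
    res$roc <- roc_suite(sig, unclass(res$expr$rpkm), res$targets,
                         k = p$roc_k)
    utils::write.table(res$roc, file.path(outdir, "roc_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$auc <- res$roc
  }

  # --- clustering -----------------------------------------------------
  if ("clustering" %in% stages) {
    mats <- list(expression_deg = need("clustering", "expression",
                                       res$deg_matrix),
                 ndr = need("clustering", "nucleosome", res$ndr))
    sig <- need("clustering", "signal", res$signal)
    mats <- c(mats, sig)
    res$clustering <- lapply(mats, function(m)
      cluster_and_compare(m, linkage = p$linkage))
    report$dendrograms <- lapply(res$clustering,
                                 function(cc) dendrogram_newick(cc$hc))
    report$topology <- lapply(res$clustering, function(cc)
      list(bipartition_match = cc$bipartition_match,
           order_match = cc$order_match, unresolved = cc$unresolved))
    writeLines(unlist(report$dendrograms),
               file.path(outdir, "dendrograms.nwk"))
  }

  # --- report ---------------------------------------------------------
  files <- sort(setdiff(list.files(outdir, recursive = TRUE,
                                   full.names = TRUE),
                        file.path(outdir, "report.json")))
  sums <- tools::md5sum(files)
  names(sums) <- substring(names(sums), nchar(outdir) + 2)
  report$checksums <- as.list(sums)
  class(report) <- "run_report"
  if ("report" %in% stages)
    jsonlite::write_json(unclass(report), file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> stages:", paste(x$stages, collapse = ", "), "\n")
  cat(" counts:", paste(names(x$counts), unlist(lapply(x$counts, function(v)
    if (is.list(v)) paste(unlist(v), collapse = "/") else v)),
    sep = "=", collapse = ", "), "\n")
  if (!is.null(x$auc)) {
    cat(" AUC table:\n")
    print(x$auc)
  }
  if (!is.null(x$topology)) {
    cat(" topology:\n")
    for (nm in names(x$topology))
      cat(sprintf("  %-20s bipartition=%s order=%s\n", nm,
                  x$topology[[nm]]$bipartition_match,
                  x$topology[[nm]]$order_match))
  }
  invisible(x)
}
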