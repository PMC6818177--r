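#' Build an expression table from counts and gene models
#'
#' @param counts matrix of raw read counts, genes x cell types.
#' @param genes gene-model data frame supplying `length_kb` per gene
#'   (rownames of `counts` must be gene_ids present in `genes`).
#' @param totals optional named vector of library totals per cell type;
#'   defaults to column sums of `counts`.
#' @return list of class `"expression_table"` with elements `counts`,
#'   `rpkm` (both signal matrices), `totals`, `length_kb`.
#' @export
expression_table <- function(counts, genes, totals = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be >= 0")
  if (is.null(totals)) totals <- colSums(counts)
  totals <- totals[colnames(counts)]
  if (any(totals <= 0)) stop("library totals must be > 0")
  len <- stats::setNames(genes$length_kb, genes$gene_id)[rownames(counts)]
  if (anyNA(len)) stop("counts contain gene_ids absent from the annotation")
  rk <- sweep(counts / len, 2, totals / 1e6, "/")
  structure(list(counts = signal_matrix(counts, units = "count"),
                 rpkm = signal_matrix(rk, units = "RPKM"),
                 totals = totals, length_kb = len),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("<expression_table> %d genes x %d cell types (totals: %s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(format_bp(x$totals), collapse = ", ")))
  invisible(x)
}

#' Read an expression counts TSV (gene_id + one column per cell type)
#'
#' @param path TSV with header; first column `gene_id`.
#' @param genes gene-model data frame (for RPKM lengths).
#' @export
read_expression_counts <- function(path, genes) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expression_table(m, genes)
}

#' @rdname read_expression_counts
#' @param tab an `expression_table`.
#' @export
write_expression_counts <- function(tab, path) {
  m <- unclass(tab$counts)
  lines <- c(paste(c("gene_id", colnames(m)), collapse = "\t"),
             apply(cbind(rownames(m), format_bp(m)), 1, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

# doubled-tail two-sided exact binomial p-value, vectorized over x, n
binom_two_sided <- function(x, n, p) {
  lower <- stats::pbinom(x, n, p)
  upper <- stats::pbinom(x - 1, n, p, lower.tail = FALSE)
  pv <- 2 * pmin(lower, upper)
  pv[n == 0] <- 1
  pmin(pv, 1)
}

#' Call differentially expressed genes between two cell types
#'
#' Per gene, a conditional binomial rate test: given the gene's combined
#' count `cA + cB`, the count in A is Binomial with success probability
#' `NA / (NA + NB)` under the null of equal per-million rates (`NA`, `NB`
#' the library totals). Two-sided p-values (doubled smaller tail) are
#' BH-adjusted across genes. Genes with zero counts in both libraries get
#' p = 1 and remain in the BH family. The pseudocount only stabilizes the
#' reported fold change; it never enters the test.
#'
#' @param tab an [expression_table()].
#' @param pair character vector of two cell-type labels `c(A, B)`.
#' @param fdr BH threshold for the `is_deg` flag (default 0.05).
#' @param pseudo pseudocount for the fold change, applied on the per-million
#'   rate scale as `pseudo / min(NA, NB)` (default 1).
#' @return data frame: `gene_id`, `cell_a`, `cell_b`, `log2fc`, `p`, `q`,
#'   `is_deg`.
#' @export
call_degs <- function(tab, pair, fdr = 0.05, pseudo = 1) {
  stopifnot(length(pair) == 2)
  cnt <- unclass(tab$counts)
  if (!all(pair %in% colnames(cnt)))
    stop("cell type(s) not present: ",
         paste(setdiff(pair, colnames(cnt)), collapse = ", "))
  ca <- cnt[, pair[1]]; cb <- cnt[, pair[2]]
  na_ <- tab$totals[[pair[1]]]; nb_ <- tab$totals[[pair[2]]]
  p0 <- pseudo / min(na_, nb_)
  pv <- binom_two_sided(ca, ca + cb, na_ / (na_ + nb_))
  qv <- stats::p.adjust(pv, method = "BH")
  lfc <- log2((ca / na_ + p0) / (cb / nb_ + p0))
  data.frame(gene_id = rownames(cnt), cell_a = pair[1], cell_b = pair[2],
             log2fc = lfc, p = pv, q = qv, is_deg = qv < fdr,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' DEG calls for every pair of cell types
#'
#' @inheritParams call_degs
#' @return data frame of stacked [call_degs()] results over all unordered
#'   pairs.
#' @export
call_degs_all_pairs <- function(tab, fdr = 0.05, pseudo = 1) {
  cells <- colnames(tab$counts)
  if (length(cells) < 2) stop("need >= 2 cell types")
  pairs <- utils::combn(cells, 2, simplify = FALSE)
  do.call(rbind, lapply(pairs, function(p) call_degs(tab, p, fdr, pseudo)))
}

#' RPKM matrix restricted to the union of DEGs over all pairs
#'
#' @param tab an [expression_table()].
#' @param degs stacked DEG results from [call_degs_all_pairs()].
#' @param log2_transform if `TRUE`, return `log2(RPKM + 1)` instead of raw
#'   RPKM (the downstream row Z-score makes this a per-gene monotone
#'   rescaling; off by default).
#' @return RPKM [signal_matrix()] over the DEG union.
#' @export
deg_union_matrix <- function(tab, degs, log2_transform = FALSE) {
  keep <- unique(degs$gene_id[degs$is_deg])
  if (length(keep) == 0)
    stop("no gene is differentially expressed in any pair; ",
         "consider raising the FDR threshold or sequencing depth")
  m <- unclass(tab$rpkm)[rownames(tab$rpkm) %in% keep, , drop = FALSE]
  if (log2_transform) m <- log2(m + 1)
  signal_matrix(m, units = "RPKM")
}
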