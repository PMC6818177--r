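#' Label genes as actual positives/negatives by expression rank
#'
#' `top_k`: the k highest-expression genes are positives (ties at the
#' boundary broken by lexicographic gene_id so exactly k are chosen);
#' `bottom_k`: the k lowest-expression genes.
#'
#' @param expr named numeric vector of expression values (names = gene
#'   ids).
#' @param convention `"top_k"` or `"bottom_k"`.
#' @param k number of positives (default 1500); must be < number of genes
#'   and >= 1.
#' @return named logical vector (TRUE = positive) in the input gene order.
#' @export
label_genes <- function(expr, convention = c("top_k", "bottom_k"), k = 1500) {
  convention <- match.arg(convention)
  n <- length(expr)
  if (k > n) stop("k (", k, ") exceeds the number of genes (", n, ")")
  if (k < 1) stop("k must be >= 1")
  ord <- if (convention == "top_k") order(-expr, names(expr))
         else order(expr, names(expr))
  lab <- stats::setNames(logical(n), names(expr))
  lab[ord[seq_len(k)]] <- TRUE
  if (all(lab) || !any(lab))
    stop("degenerate labels: one class is empty")
  lab
}

#' ROC curve of a signal column against binary labels
#'
#' Thresholds are the distinct signal values in descending order; at
#' threshold t a gene is predicted positive iff `signal >= t`. The curve is
#' the (FPR, TPR) polyline including endpoints (0,0) and (1,1); AUC is the
#' trapezoid area, which equals the pairwise statistic
#' `P(sig_pos > sig_neg) + 0.5 P(tie)`.
#'
#' @param signal named numeric vector.
#' @param labels logical vector (TRUE = actual positive), aligned with
#'   `signal` by name when both are named.
#' @return list of class `"roc_curve"`: `thresholds`, `tpr`, `fpr`, `auc`.
#' @export
roc_curve <- function(signal, labels) {
  if (!is.null(names(signal)) && !is.null(names(labels)))
    labels <- labels[names(signal)]
  if (!any(labels) || all(labels))
    stop("ROC needs both classes non-empty")
  thr <- sort(unique(signal), decreasing = TRUE)
  pos <- sum(labels); neg <- sum(!labels)
  # cumulative counts over descending thresholds
  ord <- order(-signal)
  s <- signal[ord]; l <- labels[ord]
  grp <- match(s, thr)  # every threshold occurs at least once
  tp <- cumsum(rowsum(as.integer(l), grp)[, 1])
  fp <- cumsum(rowsum(as.integer(!l), grp)[, 1])
  tpr <- c(0, unname(tp) / pos, 1)
  fpr <- c(0, unname(fp) / neg, 1)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d thresholds, AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' Pairwise-comparison AUC (independent of the trapezoid path)
#'
#' `P(sig_pos > sig_neg) + 0.5 P(sig_pos == sig_neg)` over all
#' positive-negative pairs, computed from rank sums.
#'
#' @inheritParams roc_curve
#' @export
auc_pairwise <- function(signal, labels) {
  if (!is.null(names(signal)) && !is.null(names(labels)))
    labels <- labels[names(signal)]
  pos <- signal[labels]; neg <- signal[!labels]
  if (length(pos) == 0 || length(neg) == 0)
    stop("ROC needs both classes non-empty")
  r <- rank(c(pos, neg))  # midranks handle ties as half-wins
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' ROC suite over promoter and enhancer matrices
#'
#' Evaluates each histone mark's signal as a predictor of gene activity
#' with the mark's convention: H3K9ac against the top-k most expressed
#' genes as positives, H3K27me3 against the bottom-k least expressed.
#' Enhancer signal is mapped to genes through target assignment (max over a
#' gene's enhancers); genes without an assigned enhancer are excluded from
#' that evaluation. k is capped at half the scored genes so the convention
#' stays applicable to small universes.
#'
#' @param signal_mats named list of RPM signal matrices; names of the form
#'   `"<mark>_promoter"` / `"<mark>_enhancer"` with mark `h3k9ac` or
#'   `h3k27me3`. Promoter matrices have gene rows; enhancer matrices have
#'   consensus-enhancer rows.
#' @param expr_mat expression matrix (genes x cells), e.g. RPKM.
#' @param targets optional [assign_targets()] frame mapping consensus
#'   enhancers (rows named `chrom:start-end`) to genes; required for
#'   enhancer matrices.
#' @param k positive-set size (default 1500, capped per evaluation).
#' @return data frame: `mark`, `element`, `cell`, `convention`, `k`,
#'   `n_genes`, `auc`; the ROC objects in `attr(, "curves")`.
#' @export
roc_suite <- function(signal_mats, expr_mat, targets = NULL, k = 1500) {
  res <- list(); curves <- list()
  for (nm in names(signal_mats)) {
    parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
    mark <- parts[1]; element <- parts[2]
    convention <- if (mark == "h3k27me3") "bottom_k" else "top_k"
    mat <- signal_mats[[nm]]
    for (cell in colnames(mat)) {
      sig <- mat[, cell]
      if (element == "enhancer") {
        if (is.null(targets)) stop("enhancer ROC requires target assignment")
        sig <- enhancer_signal_per_gene(sig, targets)
      }
      genes <- intersect(names(sig), rownames(expr_mat))
      sig <- sig[genes]
      expr <- expr_mat[genes, cell]
      k_eff <- min(k, floor(length(genes) / 2))
      lab <- label_genes(expr, convention, k_eff)
      rc <- roc_curve(sig, lab)
      res[[length(res) + 1]] <- data.frame(
        mark = mark, element = element, cell = cell,
        convention = convention, k = k_eff, n_genes = length(genes),
        auc = rc$auc, stringsAsFactors = FALSE)
      curves[[paste(nm, cell, sep = ".")]] <- rc
    }
  }
  out <- do.call(rbind, res)
  attr(out, "curves") <- curves
  out
}

# map per-enhancer signal to genes: max over the gene's assigned enhancers
enhancer_signal_per_gene <- function(sig, targets) {
  ids <- sprintf("%s:%s-%s", targets$chrom, format_bp(targets$start),
                 format_bp(targets$end))
  keep <- targets$assigned & ids %in% names(sig)
  if (!any(keep)) stop("no assigned enhancer matches the signal rows")
  v <- tapply(sig[ids[keep]], targets$target[keep], max)
  stats::setNames(as.numeric(v), names(v))
}
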