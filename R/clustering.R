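#' Z-score matrix rows
#'
#' Per row, subtracts the row mean and divides by the population standard
#' deviation (divisor n). Zero-variance rows carry no clustering
#' information and are dropped (a count is attached as an attribute).
#'
#' @param mat numeric matrix (rows = genes/enhancers, columns = cell
#'   types); >= 2 columns required.
#' @return [signal_matrix()] with `units = "zscore"` and an `n_dropped`
#'   attribute.
#' @export
zscore_rows <- function(mat) {
  if (ncol(mat) < 2) stop("zscore_rows needs >= 2 columns")
  m <- unclass(mat)
  attr(m, "units") <- NULL
  mu <- rowMeans(m)
  sd_pop <- sqrt(rowMeans((m - mu)^2))
  keep <- sd_pop > 0
  if (!any(keep)) stop("all rows have zero variance")
  z <- (m[keep, , drop = FALSE] - mu[keep]) / sd_pop[keep]
  out <- signal_matrix(z, units = "zscore")
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Hierarchical clustering of cell types (matrix columns)
#'
#' Euclidean distances between columns, agglomerated with the chosen
#' linkage (default complete). `hclust`'s merge order is deterministic for
#' a given distance matrix; the input columns are taken in lexicographic
#' label order so label permutations cannot change tie resolution.
#'
#' @param mat signal matrix, typically Z-scored; >= 3 columns.
#' @param linkage `"complete"`, `"average"` or `"ward"` (ward.D2).
#' @return an object of class `"hclust"` with an `unresolved` attribute
#'   (TRUE when all merge heights are equal within 1e-9).
#' @export
hcluster_cells <- function(mat, linkage = c("complete", "average", "ward")) {
  linkage <- match.arg(linkage)
  if (ncol(mat) < 3) stop("need >= 3 columns to cluster")
  m <- unclass(mat)[, order(colnames(mat), method = "radix"), drop = FALSE]
  method <- if (linkage == "ward") "ward.D2" else linkage
  hc <- stats::hclust(stats::dist(t(m)), method = method)
  attr(hc, "unresolved") <- diff(range(hc$height)) <= 1e-9
  hc
}

#' Export a dendrogram as Newick
#'
#' Branch lengths derive from merge heights (via [ape::as.phylo()]).
#'
#' @param hc an `hclust` object.
#' @return Newick string.
#' @export
dendrogram_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

#' Reference lineage tree of the four neural cell types
#'
#' NSC and GNP are sibling progenitors, glia branch from the GNP side and
#' neurons split first: the caterpillar (((NSC,GNP),Glia),Neuron).
#'
#' @param edge_scales named per-edge drift standard deviations (defaults
#'   match the synthetic generator).
#' @return list of class `"lineage_tree"`: `leaves`, `newick`,
#'   `merge_order` (list of leaf sets in merge sequence), `bipartition`
#'   (the non-trivial split), `edge_scales`.
#' @export
reference_lineage <- function(edge_scales = c(nsc_gnp = 0.3, gnp_glia = 0.6,
                                              nsc_neuron = 1.0)) {
  structure(list(
    leaves = c("NSC", "GNP", "Glia", "Neuron"),
    newick = "(((NSC,GNP),Glia),Neuron);",
    merge_order = list(c("GNP", "NSC"), c("GNP", "Glia", "NSC"),
                       c("GNP", "Glia", "NSC", "Neuron")),
    bipartition = list(sort(c("NSC", "GNP"), method = "radix"),
                       sort(c("Glia", "Neuron"), method = "radix")),
    edge_scales = edge_scales), class = "lineage_tree")
}

# leaf sets formed at each merge of an hclust, in merge order
merge_leaf_sets <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", n - 1)
  for (i in seq_len(n - 1)) {
    members <- unlist(lapply(hc$merge[i, ], function(j)
      if (j < 0) hc$labels[-j] else sets[[j]]))
    sets[[i]] <- sort(members, method = "radix")
  }
  sets
}

# non-trivial unrooted bipartitions (as sorted smaller-side leaf sets)
dendrogram_bipartitions <- function(hc) {
  leaves <- sort(hc$labels, method = "radix")
  sets <- merge_leaf_sets(hc)
  out <- list()
  for (s in sets) {
    comp <- setdiff(leaves, s)
    if (length(s) < 2 || length(comp) < 2) next
    side <- if (length(s) < length(comp) ||
                (length(s) == length(comp) &&
                 paste(s, collapse = "") <= paste(comp, collapse = ""))) s else comp
    out[[paste(side, collapse = "|")]] <- side
  }
  out
}

#' Compare a dendrogram's topology with the reference lineage
#'
#' Checks (i) whether the dendrogram contains the reference's non-trivial
#' bipartition ({NSC,GNP} vs {Glia,Neuron}) and (ii) whether the full
#' nested merge order matches the lineage: first {NSC,GNP}, then Glia
#' joins, then Neuron. Dendrograms whose merge heights are all equal
#' (within 1e-9) are flagged unresolved and fail both checks.
#'
#' @param hc an `hclust` over the reference's leaves.
#' @param reference a [reference_lineage()].
#' @return list of class `"topology_comparison"`: `bipartition_match`,
#'   `order_match`, `exact_match`, `unresolved`, `merge_order` (observed).
#' @export
compare_topology <- function(hc, reference = reference_lineage()) {
  if (!setequal(hc$labels, reference$leaves))
    stop("leaf sets differ: dendrogram has {",
         paste(sort(hc$labels, method = "radix"), collapse = ","), "}, reference {",
         paste(sort(reference$leaves, method = "radix"), collapse = ","), "}")
  unresolved <- isTRUE(attr(hc, "unresolved"))
  sets <- merge_leaf_sets(hc)
  order_match <- !unresolved &&
    all(mapply(identical, sets, reference$merge_order))
  bip <- dendrogram_bipartitions(hc)
  ref_side <- reference$bipartition[[1]]
  bipartition_match <- !unresolved &&
    any(vapply(bip, function(s) identical(s, ref_side) ||
                 identical(s, reference$bipartition[[2]]), TRUE))
  structure(list(bipartition_match = bipartition_match,
                 order_match = order_match,
                 exact_match = order_match,
                 unresolved = unresolved,
                 merge_order = sets), class = "topology_comparison")
}

#' @export
print.topology_comparison <- function(x, ...) {
  cat("<topology_comparison>\n",
      " bipartition {NSC,GNP}|{Glia,Neuron}:", x$bipartition_match, "\n",
      " nested merge order:", x$order_match, "\n",
      " unresolved:", x$unresolved, "\n")
  invisible(x)
}

#' Cluster a signal matrix and compare with the reference lineage
#'
#' Convenience wrapper: Z-score rows, cluster columns, compare topology.
#'
#' @param mat raw signal matrix (genes/enhancers x cell types).
#' @inheritParams hcluster_cells
#' @param reference a [reference_lineage()].
#' @return [compare_topology()] result with the `hclust` in `$hc`.
#' @export
cluster_and_compare <- function(mat, linkage = "complete",
                                reference = reference_lineage()) {
  hc <- hcluster_cells(zscore_rows(mat), linkage = linkage)
  cmp <- compare_topology(hc, reference)
  cmp$hc <- hc
  cmp
}
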