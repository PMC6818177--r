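#' Read gene models from a GTF file
#'
#' GTF 1-based closed coordinates are converted to the package's 0-based
#' half-open convention at the boundary. One gene model is produced per
#' `gene_id`: when several transcripts share a gene_id, the transcript with
#' the largest summed exon length wins (ties broken by transcript_id), its
#' genomic span becomes the gene interval and its exonic length (in kb) is
#' used for RPKM. The TSS is the 5' end of the oriented interval:
#' `start` on "+", `end - 1` on "-".
#'
#' @param path GTF file with `gene_id` attributes on gene/transcript
#'   features (exon features, when present, define transcript lengths).
#' @return a `data.frame` with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`, `length_kb`.
#' @export
read_gtf_genes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stop("GTF contains no feature lines")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9))
    stop("GTF parse error at line ", lineno[which(nf < 9)[1]],
         ": fewer than 9 tab-separated columns")
  feat <- vapply(fields, `[[`, "", 3L)
  use <- feat %in% c("gene", "transcript", "mRNA", "exon")
  if (!any(use)) stop("GTF has no gene/transcript/exon features")
  fields <- fields[use]; feat <- feat[use]; lineno <- lineno[use]
  chrom <- vapply(fields, `[[`, "", 1L)
  start1 <- as.numeric(vapply(fields, `[[`, "", 4L))
  end1 <- as.numeric(vapply(fields, `[[`, "", 5L))
  strand <- vapply(fields, `[[`, "", 7L)
  attrs <- vapply(fields, `[[`, "", 9L)
  gene_id <- gtf_attr(attrs, "gene_id")
  tx_id <- gtf_attr(attrs, "transcript_id")
  if (anyNA(gene_id))
    stop("GTF parse error at line ", lineno[which(is.na(gene_id))[1]],
         ": missing gene_id attribute")
  # 1-based closed -> 0-based half-open
  start0 <- start1 - 1
  end0 <- end1

  df <- data.frame(feat = feat, chrom = chrom, start = start0, end = end0,
                   strand = strand, gene_id = gene_id, tx_id = tx_id,
                   stringsAsFactors = FALSE)
  out <- lapply(split(df, df$gene_id), collapse_gene)
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$chrom, out$start, out$gene_id), , drop = FALSE]
}

gtf_attr <- function(attrs, key) {
  pat <- paste0('(^|;)\\s*', key, '\\s+"([^"]*)"')
  m <- regexec(pat, attrs)
  vapply(regmatches(attrs, m), function(g) if (length(g) >= 3) g[3] else NA_character_, "")
}

collapse_gene <- function(g) {
  if (length(unique(g$strand)) > 1)
    stop("gene_id ", g$gene_id[1], " has conflicting strands")
  if (length(unique(g$chrom)) > 1)
    stop("gene_id ", g$gene_id[1], " spans multiple chromosomes")
  ex <- g[g$feat == "exon" & !is.na(g$tx_id), , drop = FALSE]
  tx <- g[g$feat %in% c("transcript", "mRNA") & !is.na(g$tx_id), , drop = FALSE]
  if (nrow(ex) > 0 && nrow(tx) > 0) {
    exlen <- tapply(ex$end - ex$start, ex$tx_id, sum)
    # longest exonic length wins; ties by transcript_id
    best <- names(exlen)[order(-exlen, names(exlen))][1]
    b <- tx[tx$tx_id == best, , drop = FALSE]
    if (nrow(b) == 0) {
      bex <- ex[ex$tx_id == best, , drop = FALSE]
      b <- data.frame(start = min(bex$start), end = max(bex$end))
    }
    span <- c(min(b$start), max(b$end))
    len_kb <- unname(exlen[best]) / 1000
  } else if (nrow(tx) > 0) {
    w <- tx$end - tx$start
    best <- order(-w, tx$tx_id)[1]
    span <- c(tx$start[best], tx$end[best])
    len_kb <- w[best] / 1000
  } else {
    span <- c(min(g$start), max(g$end))
    len_kb <- (span[2] - span[1]) / 1000
  }
  strand <- g$strand[1]
  tss <- if (strand == "-") span[2] - 1 else span[1]
  data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
             start = span[1], end = span[2], strand = strand,
             tss = tss, length_kb = len_kb, stringsAsFactors = FALSE)
}

#' Write gene models as GTF (transcript + exon lines)
#'
#' Inverse of [read_gtf_genes()] for single-transcript genes: emits one
#' transcript and one exon feature per gene in 1-based closed coordinates.
#'
#' @param genes gene-model data frame from [read_gtf_genes()] or the
#'   simulator.
#' @param path output path.
#' @export
write_gtf_genes <- function(genes, path) {
  attr9 <- sprintf('gene_id "%s"; transcript_id "%s.t1";',
                   genes$gene_id, genes$gene_id)
  row <- function(feat) paste(genes$chrom, "epilineage", feat,
                              format_bp(genes$start + 1), format_bp(genes$end),
                              ".", genes$strand, ".", attr9, sep = "\t")
  lines <- as.vector(rbind(row("transcript"), row("exon")))
  writeLines(lines, path)
  invisible(path)
}

#' Promoter intervals for a set of genes
#'
#' Promoters are the strand-symmetric windows `[tss - up, tss + down)`
#' (defaults +/- 1 kb), clipped to chromosome bounds when a genome table is
#' supplied.
#'
#' @param genes gene-model data frame.
#' @param up,down bp upstream/downstream of the TSS (symmetric default 1000).
#' @param genome optional named vector of chromosome lengths for clipping.
#' @return interval data frame with a `gene_id` column.
#' @export
promoters_of <- function(genes, up = 1000, down = 1000, genome = NULL) {
  start <- pmax(genes$tss - up, 0)
  end <- genes$tss + down
  if (!is.null(genome)) end <- pmin(end, unname(genome[genes$chrom]))
  data.frame(chrom = genes$chrom, start = start, end = end, strand = ".",
             gene_id = genes$gene_id, stringsAsFactors = FALSE)
}
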