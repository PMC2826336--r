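#' Co-localize gene intervals with QTL intervals
#'
#' A gene is associated with a QTL when their intervals share at least one
#' base pair on the same chromosome; a gene spanning several QTL yields one
#' association record per QTL.
#'
#' @param genes data.frame with `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @param qtl data.frame with `trait`, `chrom`, `start`, `end`.
#' @return list with `associations` (gene_id, trait, qtl row index) and
#'   `per_trait` (trait, n_genes). Genes on chromosomes absent from the QTL
#'   table simply have no associations; genes with chromosomes absent from
#'   the gene table trigger per-record warnings upstream.
#' @export
colocalize_genes <- function(genes, qtl) {
  gr_genes <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end))
  if (nrow(qtl) == 0L) {
    return(list(associations = data.frame(gene_id = character(0),
                                          trait = character(0),
                                          qtl = integer(0)),
                per_trait = data.frame(trait = character(0),
                                       n_genes = integer(0))))
  }
  gr_qtl <- GenomicRanges::GRanges(
    seqnames = qtl$chrom,
    ranges = IRanges::IRanges(start = qtl$start, end = qtl$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_genes, gr_qtl))
  assoc <- data.frame(
    gene_id = genes$gene_id[S4Vectors::queryHits(hits)],
    trait = qtl$trait[S4Vectors::subjectHits(hits)],
    qtl = S4Vectors::subjectHits(hits),
    stringsAsFactors = FALSE)
  per_trait <- stats::aggregate(gene_id ~ trait, data = assoc,
                                FUN = function(x) length(unique(x)))
  names(per_trait)[2] <- "n_genes"
  list(associations = assoc, per_trait = per_trait)
}

#' One-sided Fisher exact enrichment of QTL-associated genes in a subset
#'
#' Tests whether the ratio of QTL-associated genes is higher in a gene
#' subset (e.g. upregulated transcription factors) than in the rest of the
#' universe, via the one-sided ("greater") Fisher exact test, i.e. the
#' hypergeometric tail on the 2x2 table. Enrichment requires both a higher
#' subset ratio and p below `alpha` (default 0.25).
#'
#' @param subset character vector of gene ids (must be a subset of
#'   `universe`).
#' @param universe character vector of all gene ids considered.
#' @param associated character vector of QTL-associated gene ids.
#' @param alpha significance level (default 0.25).
#' @return object of class `fisher_result`: list with `table` (2x2 counts),
#'   `subset_ratio`, `genome_ratio`, `p_value`, `enriched`.
#' @export
fisher_enrichment <- function(subset, universe, associated, alpha = 0.25) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("universe is empty")
  subset <- unique(subset)
  if (!all(subset %in% universe)) stop("subset must be contained in universe")
  associated <- intersect(unique(associated), universe)
  a <- sum(subset %in% associated)
  b <- length(subset) - a
  rest <- setdiff(universe, subset)
  c_ <- sum(rest %in% associated)
  d <- length(rest) - c_
  res <- fisher_greater(a, b, c_, d)
  subset_ratio <- if (length(subset)) a / length(subset) else 0
  genome_ratio <- length(associated) / length(universe)
  structure(list(
    table = matrix(c(a, b, c_, d), 2L, 2L, byrow = TRUE,
                   dimnames = list(c("subset", "rest"),
                                   c("qtl", "non_qtl"))),
    subset_ratio = subset_ratio, genome_ratio = genome_ratio,
    p_value = res, alpha = alpha,
    enriched = (subset_ratio > genome_ratio) && (res < alpha)
  ), class = "fisher_result")
}

#' One-sided (greater) Fisher exact p-value of a 2x2 table
#'
#' The hypergeometric tail probability of observing `a` or more
#' QTL-associated genes in the subset, conditional on all margins.
#'
#' @param a,b,c,d the 2x2 cell counts: subset associated / subset not /
#'   rest associated / rest not.
#' @return the one-sided p-value.
#' @export
fisher_greater <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("counts must be non-negative")
  # P(X >= a), X ~ Hypergeometric(m = a+c successes, n = b+d, k = a+b draws)
  stats::phyper(a - 1L, m = a + c, n = b + d, k = a + b, lower.tail = FALSE)
}

#' @export
print.fisher_result <- function(x, ...) {
  cat("fisher_result: subset ratio", sprintf("%.3f", x$subset_ratio),
      "vs genome ratio", sprintf("%.3f", x$genome_ratio),
      "| one-sided p =", signif(x$p_value, 4),
      "| enriched:", x$enriched, "\n")
  invisible(x)
}
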