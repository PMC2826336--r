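#' Match a motif consensus to a known cis-element class
#'
#' Slides the IUPAC consensus (both orientations) against every catalog
#' pattern at all ungapped offsets; a position is compatible when the two
#' IUPAC base sets intersect, and the compatibility fraction is taken over
#' the shorter of the two lengths. The best-scoring class at or above
#' `min_similarity` wins; ties break by higher similarity, then catalog
#' order. Classes other than the winner that also reach the threshold are
#' dual-reported (this captures the known W-box / as1-like ambiguity).
#'
#' @param consensus IUPAC consensus string, or a `motif_model`.
#' @param catalog an element catalog from [load_element_catalog()].
#' @param min_similarity minimum compatibility fraction (default 0.75).
#' @return one-row data.frame: `element_class` (or "unassigned"),
#'   `broad_category`, `tf_family`, `similarity`, `also_matches`
#'   (comma-joined other classes reaching the threshold).
#' @export
match_element_class <- function(consensus, catalog = load_element_catalog(),
                                min_similarity = 0.75) {
  if (inherits(consensus, "motif_model")) consensus <- consensus$consensus
  if (nrow(catalog) == 0L) stop("catalog is empty")
  sims <- vapply(catalog$iupac_pattern, function(p) {
    iupac_similarity(consensus, p)
  }, numeric(1))
  hits <- which(sims >= min_similarity)
  if (length(hits) == 0L) {
    return(data.frame(element_class = "unassigned",
                      broad_category = "unassigned",
                      tf_family = NA_character_, similarity = max(sims),
                      also_matches = "", stringsAsFactors = FALSE))
  }
  best <- hits[order(-sims[hits], hits)][1L]
  others <- setdiff(hits, best)
  data.frame(element_class = catalog$class[best],
             broad_category = catalog$broad_category[best],
             tf_family = catalog$tf_family[best],
             similarity = sims[best],
             also_matches = paste(catalog$class[others], collapse = ","),
             stringsAsFactors = FALSE)
}

# Best ungapped compatibility fraction between two IUPAC strings over all
# offsets and both orientations of `a`, normalized by the shorter length.
iupac_similarity <- function(a, b) {
  best <- 0
  for (aa in c(a, iupac_revcomp(a))) {
    sa <- iupac_sets(aa)
    sb <- iupac_sets(b)
    la <- length(sa)
    lb <- length(sb)
    shorter <- min(la, lb)
    for (shift in (-(la - 1L)):(lb - 1L)) {
      ia <- seq_len(la)
      ib <- ia + shift
      keep <- ib >= 1L & ib <= lb
      if (!any(keep)) next
      compat <- mapply(function(x, y) length(intersect(x, y)) > 0,
                       sa[ia[keep]], sb[ib[keep]])
      best <- max(best, sum(compat) / shorter)
    }
  }
  best
}

#' Total enrichment scores per cluster and broad element category
#'
#' For each cluster and broad category, the total enrichment score is the
#' sum of occurrence percentages of all motif species in that category that
#' occur in at least `min_occurrence` percent of the cluster's promoters.
#' Categories with no qualifying motif are omitted; output is sorted by
#' total score, descending, within cluster.
#'
#' @param motif_table data.frame with columns `cluster`, `motif` (consensus),
#'   `broad_category`, `occurrence_pct` (and optionally `n` extras).
#' @param min_occurrence qualifying occurrence threshold in percent
#'   (default 50).
#' @return data.frame: `cluster`, `broad_category`, `total_score`,
#'   `n_motif_species`, `motifs` (comma-joined consensi).
#' @export
class_scores <- function(motif_table, min_occurrence = 50) {
  required <- c("cluster", "motif", "broad_category", "occurrence_pct")
  missing <- setdiff(required, names(motif_table))
  if (length(missing) > 0) stop("missing column(s): ", paste(missing, collapse = ", "))
  keep <- motif_table$occurrence_pct >= min_occurrence &
    !motif_table$broad_category %in% c("unassigned")
  tab <- motif_table[keep, , drop = FALSE]
  if (nrow(tab) == 0L) {
    return(data.frame(cluster = character(0), broad_category = character(0),
                      total_score = numeric(0), n_motif_species = integer(0),
                      motifs = character(0), stringsAsFactors = FALSE))
  }
  key <- interaction(tab$cluster, tab$broad_category, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(tab)), key), function(idx) {
    data.frame(cluster = tab$cluster[idx[1]],
               broad_category = tab$broad_category[idx[1]],
               total_score = sum(tab$occurrence_pct[idx]),
               n_motif_species = length(idx),
               motifs = paste(tab$motif[idx], collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$cluster, -out$total_score, out$broad_category), , drop = FALSE]
}

#' Top-ranked element categories of a cluster
#'
#' Ranks a cluster's class enrichments by total score (descending), with
#' ties broken by the number of motif species (descending) and then by
#' category name; returns the top `n`.
#'
#' @param enrichments rows of a [class_scores()] result for one cluster.
#' @param n how many categories to return (default 3).
#' @return character vector of broad categories, best first.
#' @export
dominant_classes <- function(enrichments, n = 3L) {
  if (nrow(enrichments) == 0L) return(character(0))
  ord <- order(-enrichments$total_score, -enrichments$n_motif_species,
               enrichments$broad_category)
  utils::head(enrichments$broad_category[ord], n)
}
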