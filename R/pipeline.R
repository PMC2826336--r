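#' Run the full inference pipeline on a study bundle
#'
#' Executes the stages in order: induction/repression calling on the
#' chilling series, oxidative-mimic responsiveness calling, chilling vs
#' H2O2 overlap, k-means clustering of upregulated non-TF genes, per-cluster
#' de novo motif discovery with background subtraction, cis-element class
#' enrichment scoring, regulatory edge inference with mediation labels,
#' and QTL co-localization enrichment of the upregulated TFs. Deterministic
#' for a fixed seed: every stochastic stage derives its seed from `seed`.
#'
#' @param bundle a `study_bundle` (from [generate_study()] or
#'   [read_study_bundle()]).
#' @param call_cfg a [call_config()] for the chilling series.
#' @param k number of co-expression clusters.
#' @param discovery a [discovery_config()]; its seed is re-derived per
#'   cluster from `seed`.
#' @param min_occurrence occurrence threshold (percent) for a motif to
#'   enter class scoring (default 50).
#' @param alpha_e e-value cutoff of the background filter.
#' @param n_background number of non-responsive promoters used as the
#'   background set.
#' @param max_cluster_promoters cap on promoters per cluster fed to the EM
#'   (larger clusters are subsampled deterministically).
#' @param mediation_thresholds passed to [infer_edges()].
#' @param qtl_alpha Fisher significance level (default 0.25).
#' @param seed global pipeline seed.
#' @return a `pipeline_result` list with elements `up_calls`, `down_calls`,
#'   `h2o2_set`, `overlap`, `clusters`, `motif_table`, `motifs`,
#'   `enrichments`, `edges`, `tf_calls`, `qtl` (pooled `fisher_result` plus
#'   per-trait results and the association table), and `seed`.
#' @export
run_pipeline <- function(bundle, call_cfg = call_config(), k = 18L,
                         discovery = discovery_config(),
                         min_occurrence = 50, alpha_e = 1e-3,
                         n_background = 100L,
                         max_cluster_promoters = Inf,
                         mediation_thresholds = c(0.50, 0.25),
                         qtl_alpha = 0.25, seed = 1L) {
  validate_bundle(bundle)
  universe <- bundle$universe
  up <- call_upregulated(bundle$chilling, call_cfg)
  down <- call_downregulated(bundle$chilling, call_cfg)
  h2o2_set <- call_h2o2_responsive(bundle$h2o2, call_cfg)
  ovl <- overlap_sets(up$gene_id, h2o2_set)

  is_tf <- universe$is_tf[match(up$gene_id, universe$gene_id)]
  up_ntf <- up$gene_id[!is_tf]
  if (length(up_ntf) < k) {
    stop("stage clustering: fewer upregulated non-TF genes (", length(up_ntf),
         ") than clusters (", k, ")")
  }
  profiles <- bundle$chilling$ratio[up_ntf, , drop = FALSE]
  clus <- kmeans_cluster(profiles, k = k, seed = seed,
                         timepoints = bundle$chilling$timepoints,
                         up_threshold = call_cfg$up_threshold,
                         config = call_cfg)
  clus$clusters$h2o2_fraction <- vapply(clus$clusters$members, h2o2_fraction,
                                        numeric(1), h2o2_set = h2o2_set)

  responsive <- union(up$gene_id, down$gene_id)
  bg_pool <- setdiff(names(bundle$promoters), responsive)
  bg_idx <- with_seed(seed + 1000L, {
    sample(bg_pool, min(n_background, length(bg_pool)))
  })
  bg_seqs <- as.character(bundle$promoters[bg_idx])

  motif_rows <- list()
  motif_models <- list()
  for (j in seq_len(nrow(clus$clusters))) {
    cl <- clus$clusters$cluster[j]
    members <- intersect(clus$clusters$members[[j]], names(bundle$promoters))
    if (length(members) > max_cluster_promoters) {
      members <- with_seed(seed + 2000L + j, {
        sample(members, max_cluster_promoters)
      })
    }
    if (length(members) < 5L) next
    fg <- as.character(bundle$promoters[members])
    dcfg <- discovery
    dcfg$seed <- seed + 3000L + j
    found <- discover_motifs(fg, dcfg)
    kept <- background_filter(found, fg, bg_seqs, alpha_e = alpha_e,
                              n_tests = max(length(found), 1L))
    motif_models[[cl]] <- kept
    if (length(kept) == 0L) next
    rows <- lapply(kept, function(m) {
      cls <- match_element_class(m, bundle$catalog)
      data.frame(cluster = cl, motif = m$consensus,
                 element_class = cls$element_class,
                 broad_category = cls$broad_category,
                 tf_family = cls$tf_family,
                 also_matches = cls$also_matches,
                 occurrence_pct = m$occurrence_pct, tic = m$tic,
                 e_value = m$e_value, stringsAsFactors = FALSE)
    })
    motif_rows[[cl]] <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  motif_table <- if (length(motif_rows)) {
    do.call(rbind, c(motif_rows, list(make.row.names = FALSE)))
  } else {
    data.frame(cluster = character(0), motif = character(0),
               element_class = character(0), broad_category = character(0),
               tf_family = character(0), also_matches = character(0),
               occurrence_pct = numeric(0), tic = numeric(0),
               e_value = numeric(0))
  }
  enr <- class_scores(motif_table, min_occurrence = min_occurrence)

  up_tf <- up$gene_id[is_tf]
  tf_calls <- data.frame(
    gene_id = up_tf,
    tf_family = universe$tf_family[match(up_tf, universe$gene_id)],
    phase = up$phase[match(up_tf, up$gene_id)],
    h2o2 = up_tf %in% h2o2_set, stringsAsFactors = FALSE)
  edges <- infer_edges(clus$clusters, enr, tf_calls, bundle$catalog,
                       mediation_thresholds)

  coloc <- colocalize_genes(universe, bundle$qtl)
  associated <- unique(coloc$associations$gene_id)
  pooled <- fisher_enrichment(up_tf, universe$gene_id, associated, qtl_alpha)
  per_trait <- lapply(split(coloc$associations, coloc$associations$trait),
                      function(a) {
                        fisher_enrichment(up_tf, universe$gene_id,
                                          unique(a$gene_id), qtl_alpha)
                      })
  structure(list(
    up_calls = up, down_calls = down, h2o2_set = h2o2_set, overlap = ovl,
    clusters = clus, motif_table = motif_table, motifs = motif_models,
    enrichments = enr, tf_calls = tf_calls, edges = edges,
    qtl = list(pooled = pooled, per_trait = per_trait,
               associations = coloc$associations),
    seed = seed), class = "pipeline_result")
}

validate_bundle <- function(bundle) {
  needed <- c("universe", "chilling", "h2o2", "promoters", "catalog", "qtl")
  missing <- setdiff(needed, names(bundle))
  if (length(missing) > 0) {
    stop("bundle validation: missing component(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(bundle$chilling$ratio) == 0L) {
    stop("bundle validation: chilling expression matrix is empty")
  }
  ids <- bundle$universe$gene_id
  expr_ids <- rownames(bundle$chilling$ratio)
  if (!all(expr_ids %in% ids)) {
    stop("bundle validation: expression gene ids absent from gene annotation")
  }
  invisible(TRUE)
}

#' Write the pipeline report files
#'
#' Emits per-cluster motif statistics laid out like a published
#' cluster/motif/element table (`cluster`, `motif`, `element`,
#' `tf_family`, `pct_tic` formatted "occ (TIC)", `e_value`), the
#' per-cluster class-score summary, the network edge list (TSV and JSON),
#' the QTL enrichment table, the regulation calls, and cluster membership
#' and summary tables, plus a checksummed manifest.
#'
#' @param results a `pipeline_result`.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
write_report <- function(results, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop("cannot create report directory: ", dir)
  mt <- results$motif_table
  motif_report <- data.frame(
    cluster = mt$cluster, motif = mt$motif, element = mt$element_class,
    tf_family = mt$tf_family,
    pct_tic = sprintf("%.0f (%.2f)", mt$occurrence_pct, mt$tic),
    e_value = formatC(mt$e_value, format = "e", digits = 0),
    stringsAsFactors = FALSE)
  paths <- c(
    motifs = file.path(dir, "cluster_motifs.tsv"),
    scores = file.path(dir, "class_scores.tsv"),
    edges = file.path(dir, "network_edges.tsv"),
    network = file.path(dir, "network.json"),
    qtl = file.path(dir, "qtl_enrichment.tsv"),
    calls = file.path(dir, "regulation_calls.tsv"),
    membership = file.path(dir, "cluster_membership.tsv"),
    summary = file.path(dir, "cluster_summary.tsv"))
  utils::write.table(motif_report, paths[["motifs"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(results$enrichments, paths[["scores"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(results$edges, paths[["edges"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  export_network(results$edges, paths[["network"]], "json")
  qtl_rows <- lapply(names(results$qtl$per_trait), function(tr) {
    f <- results$qtl$per_trait[[tr]]
    data.frame(trait = tr, subset_qtl = f$table[1, 1],
               subset_non = f$table[1, 2], rest_qtl = f$table[2, 1],
               rest_non = f$table[2, 2],
               subset_ratio = f$subset_ratio, genome_ratio = f$genome_ratio,
               p_value = f$p_value, enriched = f$enriched,
               stringsAsFactors = FALSE)
  })
  pooled <- results$qtl$pooled
  qtl_rows <- c(list(data.frame(
    trait = "pooled", subset_qtl = pooled$table[1, 1],
    subset_non = pooled$table[1, 2], rest_qtl = pooled$table[2, 1],
    rest_non = pooled$table[2, 2], subset_ratio = pooled$subset_ratio,
    genome_ratio = pooled$genome_ratio, p_value = pooled$p_value,
    enriched = pooled$enriched, stringsAsFactors = FALSE)), qtl_rows)
  utils::write.table(do.call(rbind, qtl_rows), paths[["qtl"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  calls <- rbind(
    results$up_calls[, c("gene_id", "status", "phase", "waves")],
    results$down_calls[, c("gene_id", "status", "phase", "waves")])
  utils::write.table(calls, paths[["calls"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  membership <- data.frame(
    gene_id = names(results$clusters$assignment),
    cluster = cluster_labels(results$clusters$k)[results$clusters$assignment],
    stringsAsFactors = FALSE)
  utils::write.table(membership, paths[["membership"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summ <- results$clusters$clusters
  summ$h2o2_pct <- round(100 * summ$h2o2_fraction, 1)
  utils::write.table(
    summ[, c("cluster", "size", "phase", "h2o2_pct", "consensus")],
    paths[["summary"]], sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- data.frame(file = basename(unname(paths)),
                         md5 = unname(tools::md5sum(unname(paths))),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(dir)
}

#' Compare a pipeline run against the generator's ground truth
#'
#' Convenience scorer used in validation: fraction of true upregulated
#' genes recovered, precision of the up call, adjusted agreement of the
#' cluster partition with truth (label-permutation-invariant exact check),
#' and the fraction of non-degenerate clusters whose primary edge matches
#' the cluster's planted regulator category (a cluster's planted category
#' is taken as the majority planted category of its members).
#'
#' @param results a `pipeline_result`.
#' @param truth the bundle's `ground_truth`.
#' @return list of scores.
#' @export
score_against_truth <- function(results, truth) {
  up_called <- results$up_calls$gene_id
  up_true <- truth$up
  recall <- mean(up_true %in% up_called)
  precision <- if (length(up_called)) mean(up_called %in% up_true) else NA

  cl <- results$clusters
  member_truth <- truth$genes$cluster[match(names(cl$assignment),
                                            truth$genes$gene_id)]
  # planted category per discovered cluster = majority truth cluster's class
  planted_broad <- vapply(seq_len(cl$k), function(j) {
    mt <- member_truth[cl$assignment == j]
    mt <- mt[!is.na(mt)]
    if (length(mt) == 0L) return(NA_character_)
    maj <- names(sort(table(mt), decreasing = TRUE))[1L]
    truth$clusters$regulator_broad[truth$clusters$cluster == maj]
  }, character(1))
  prim <- results$edges[results$edges$rank %in% "primary", , drop = FALSE]
  prim_broad <- prim$source_class[match(cluster_labels(cl$k),
                                        prim$target_cluster)]
  usable <- !is.na(planted_broad)
  hit <- !is.na(prim_broad) & prim_broad == planted_broad
  primary_recovery <- if (any(usable)) mean(hit[usable]) else 0
  list(up_recall = recall, up_precision = precision,
       primary_edge_recovery = primary_recovery)
}
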