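#' Write a time-course matrix as TSV
#'
#' Dialect: column 1 is `gene_id`, followed by `ratio_<hour>` and
#' `p_<hour>` column pairs in time order. Missing values are forbidden.
#'
#' @param matrix a [time_course_matrix()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_expression_tsv <- function(matrix, path) {
  tp <- matrix$timepoints
  out <- data.frame(gene_id = rownames(matrix$ratio), stringsAsFactors = FALSE)
  for (i in seq_along(tp)) {
    out[[sprintf("ratio_%g", tp[i])]] <- matrix$ratio[, i]
    out[[sprintf("p_%g", tp[i])]] <- matrix$p[, i]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a time-course matrix from TSV
#' @param path TSV in the [write_expression_tsv()] dialect.
#' @return a [time_course_matrix()].
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("expression file is empty: ", path)
  ratio_cols <- grep("^ratio_", names(df), value = TRUE)
  tp <- as.numeric(sub("^ratio_", "", ratio_cols))
  ord <- order(tp)
  ratio <- as.matrix(df[, ratio_cols[ord], drop = FALSE])
  p <- as.matrix(df[, sub("^ratio_", "p_", ratio_cols[ord]), drop = FALSE])
  rownames(ratio) <- df$gene_id
  time_course_matrix(ratio, p, tp[ord])
}

#' Write gene intervals as BED (0-based half-open)
#' @param universe gene table with `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive), `strand`.
#' @param path output path.
#' @export
write_genes_bed <- function(universe, path) {
  bed <- data.frame(universe$chrom, universe$start - 1L, universe$end,
                    universe$gene_id, 0L, universe$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene intervals from BED into the 1-based gene-table layout
#' @param path BED path.
#' @export
read_genes_bed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  data.frame(gene_id = bed[[4]], chrom = bed[[1]],
             start = bed[[2]] + 1L, end = bed[[3]], strand = bed[[6]],
             stringsAsFactors = FALSE)
}

#' Write gene models as GFF3 (1-based inclusive)
#' @inheritParams write_genes_bed
#' @export
write_genes_gff3 <- function(universe, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  lines <- sprintf("%s\tchillregnet\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                   universe$chrom, universe$start, universe$end,
                   universe$strand, universe$gene_id)
  writeLines(lines, con)
  invisible(path)
}

#' Write the QTL table as a BED-like TSV with a trait column
#' @param qtl data.frame `trait`, `chrom`, `start`, `end`.
#' @param path output path.
#' @export
write_qtl_tsv <- function(qtl, path) {
  utils::write.table(qtl[, c("trait", "chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a QTL TSV written by [write_qtl_tsv()]
#' @param path TSV path.
#' @export
read_qtl_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write promoter sequences as FASTA (80-column wrap)
#' @param sequences a named `DNAStringSet` or character vector.
#' @param path output path.
#' @export
write_promoters_fasta <- function(sequences, path) {
  if (!inherits(sequences, "DNAStringSet")) {
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  Biostrings::writeXStringSet(sequences, path, width = 80L)
  invisible(path)
}

#' Write discovered motifs in MEME minimal motif format
#'
#' @param motifs list of `motif_model`s.
#' @param path output path.
#' @export
write_meme <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (i in seq_along(motifs)) {
    m <- motifs[[i]]
    writeLines(sprintf("MOTIF %s M%02d", m$consensus, i), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= %s",
      m$width, max(nrow(m$sites), 1L),
      if (is.null(m$e_value)) "0" else format(m$e_value)), con)
    writeLines(apply(m$pwm, 2L, function(p) {
      paste(sprintf("%.6f", p), collapse = " ")
    }), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Write a study bundle to a directory with a checksummed manifest
#'
#' Artifacts: chilling and H2O2 expression TSVs, promoters FASTA, genes
#' BED and GFF3, QTL TSV, ground-truth JSON, generator config YAML, and a
#' `manifest.json` listing each file with its md5 checksum.
#'
#' @param bundle a `study_bundle` from [generate_study()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_study_bundle <- function(bundle, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stop("cannot create output directory: ", dir)
  paths <- c(
    chilling = file.path(dir, "chilling_expression.tsv"),
    h2o2 = file.path(dir, "h2o2_expression.tsv"),
    promoters = file.path(dir, "promoters.fasta"),
    genes_bed = file.path(dir, "genes.bed"),
    genes_gff3 = file.path(dir, "genes.gff3"),
    qtl = file.path(dir, "qtl.tsv"),
    truth = file.path(dir, "truth.json"),
    config = file.path(dir, "config.yaml"),
    universe = file.path(dir, "universe.tsv")
  )
  write_expression_tsv(bundle$chilling, paths[["chilling"]])
  write_expression_tsv(bundle$h2o2, paths[["h2o2"]])
  write_promoters_fasta(bundle$promoters, paths[["promoters"]])
  write_genes_bed(bundle$universe, paths[["genes_bed"]])
  write_genes_gff3(bundle$universe, paths[["genes_gff3"]])
  write_qtl_tsv(bundle$qtl, paths[["qtl"]])
  truth <- bundle$truth
  jsonlite::write_json(unclass(truth), paths[["truth"]], dataframe = "columns",
                       na = "null", digits = NA, auto_unbox = FALSE)
  cfg <- unclass(bundle$config)
  cfg$planted_motifs <- NULL
  # yaml drops names on atomic vectors; serialize named vectors as maps
  for (f in c("chrom_lengths", "base_comp", "per_cluster_h2o2_fraction")) {
    cfg[[f]] <- as.list(cfg[[f]])
  }
  yaml::write_yaml(cfg, paths[["config"]])
  utils::write.table(bundle$universe, paths[["universe"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- data.frame(file = basename(unname(paths)),
                         md5 = unname(tools::md5sum(unname(paths))),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       dataframe = "rows", pretty = TRUE)
  invisible(dir)
}

#' Read a study bundle back from a directory
#'
#' Inverse of [write_study_bundle()]; the round trip is loss-free for
#' every component the pipeline consumes.
#'
#' @param dir bundle directory.
#' @return a `study_bundle` list.
#' @export
read_study_bundle <- function(dir) {
  tj <- jsonlite::fromJSON(file.path(dir, "truth.json"))
  truth <- structure(list(
    genes = as.data.frame(tj$genes, stringsAsFactors = FALSE),
    clusters = as.data.frame(tj$clusters, stringsAsFactors = FALSE),
    up = unlist(tj$up), down = unlist(tj$down), h2o2 = unlist(tj$h2o2),
    qtl_associations = as.data.frame(tj$qtl_associations,
                                     stringsAsFactors = FALSE)),
    class = "ground_truth")
  cfg_list <- yaml::read_yaml(file.path(dir, "config.yaml"))
  cfg_list$chrom_lengths <- unlist(cfg_list$chrom_lengths)
  cfg_list$base_comp <- unlist(cfg_list$base_comp)
  cfg_list$per_cluster_h2o2_fraction <- unlist(cfg_list$per_cluster_h2o2_fraction)
  cfg <- do.call(simulation_config, cfg_list)
  prom <- Biostrings::readDNAStringSet(file.path(dir, "promoters.fasta"))
  names(prom) <- sub("\\s.*$", "", names(prom))
  structure(list(
    universe = utils::read.delim(file.path(dir, "universe.tsv"),
                                 stringsAsFactors = FALSE),
    chilling = read_expression_tsv(file.path(dir, "chilling_expression.tsv")),
    h2o2 = read_expression_tsv(file.path(dir, "h2o2_expression.tsv")),
    promoters = prom,
    catalog = load_element_catalog(),
    qtl = read_qtl_tsv(file.path(dir, "qtl.tsv")),
    truth = truth, config = cfg), class = "study_bundle")
}
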