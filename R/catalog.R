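#' Load the cis-element class catalog
#'
#' The packaged catalog maps fine cis-element classes (as1/ocs/TGA-like,
#' ABRE-like, DRE/CRT-like, rav1-like, GCC-box-like, JAre-like,
#' MYB2-box-like, GARE-like, pyrimidine-box-like, W-box-like, MYC2-box-like)
#' to an IUPAC core pattern, a broad scoring category, and the
#' transcription-factor family known to bind that class. Fine classes carry
#' the literature labels; broad categories pool sub-classes the way
#' enrichment is scored and graphed (e.g. DRE/CRT-like and rav1-like pool
#' into "DRE/CRT/rav1-like").
#'
#' @param path path to a catalog TSV with columns `class`, `broad_category`,
#'   `iupac_pattern`, `tf_family`, `source`. Defaults to the packaged
#'   catalog.
#' @return data.frame with one row per fine element class.
#' @export
load_element_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cis_element_catalog.tsv",
                        package = "chillregnet", mustWork = TRUE)
  }
  cat <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("class", "broad_category", "iupac_pattern", "tf_family")
  missing <- setdiff(required, names(cat))
  if (length(missing) > 0) {
    stop("catalog is missing column(s): ", paste(missing, collapse = ", "))
  }
  for (p in cat$iupac_pattern) validate_iupac(p)
  fam_per_class <- tapply(cat$tf_family, cat$class, function(x) length(unique(x)))
  if (any(fam_per_class > 1)) {
    stop("each element class must map to exactly one TF family")
  }
  cat
}

# Printed element labels (as they appear in published motif tables) pooled
# into the broad categories used for total enrichment scoring. Labels not
# listed here score under "other".
PRINTED_LABEL_POOLING <- c(
  "as1/ocs/TGA-like"         = "as1/ocs/TGA-like",
  "ABRE-like"                = "ABRE-like",
  "CAMTA3/ABRE-like"         = "ABRE-like",
  "DRE/CRT-like"             = "DRE/CRT/rav1-like",
  "rav1b element-like"       = "DRE/CRT/rav1-like",
  "GCC-box-like"             = "GCC-box/JAre-like",
  "JA response element-like" = "GCC-box/JAre-like",
  "MYB2-box-like"            = "MYB2-box-like",
  "MYB1-box-like"            = "MYB2-box-like",
  "GA response element-like" = "GARE/pyrimidine-box-like",
  "Pyrimidine box-like"      = "GARE/pyrimidine-box-like",
  "W-box-like"               = "W-box-like",
  "MYC2-box-like"            = "MYC2-box-like"
)

#' Map printed element labels to broad scoring categories
#'
#' @param labels character vector of element labels as printed in a motif
#'   table (e.g. "GA response element-like").
#' @return character vector of broad categories; unrecognized labels map to
#'   `"other"`.
#' @export
pool_element_labels <- function(labels) {
  out <- unname(PRINTED_LABEL_POOLING[labels])
  out[is.na(out)] <- "other"
  out
}

#' Read a table of published per-cluster motif statistics
#'
#' Reads a TSV with columns `cluster`, `motif`, `element`, `occurrence`,
#' `tic`, `e_value` (plus any extras), the layout used for per-cluster
#' promoter-motif reports. The packaged copy transcribes the printed
#' per-cluster bZIP/ERF/MYB motif statistics used as a format fixture and as
#' input to the class-score checks.
#'
#' @param path TSV path; defaults to the packaged table.
#' @return data.frame of motif rows.
#' @export
read_printed_motif_tables <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "printed_motif_tables.tsv",
                        package = "chillregnet", mustWork = TRUE)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("cluster", "motif", "element", "occurrence")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("motif table is missing column(s): ", paste(missing, collapse = ", "))
  }
  tab
}

# Broad category -> TF family, derived from the catalog.
#' @keywords internal
broad_category_families <- function(catalog = load_element_catalog()) {
  fam <- tapply(catalog$tf_family, catalog$broad_category,
                function(x) unique(x)[1])
  as.list(fam)
}
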