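# IUPAC nucleotide codes used throughout motif matching and simulation.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Split an IUPAC pattern into per-position base sets
#'
#' @param pattern character scalar of IUPAC nucleotide codes.
#' @return list of character vectors, one per position.
#' @keywords internal
iupac_sets <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_SETS))
  if (length(bad) > 0) {
    stop("invalid IUPAC code(s) in pattern '", pattern, "': ",
         paste(unique(bad), collapse = ", "))
  }
  IUPAC_SETS[chars]
}

#' Validate an IUPAC pattern, returning TRUE or signalling an error
#' @keywords internal
validate_iupac <- function(pattern) {
  iupac_sets(pattern)
  invisible(TRUE)
}

#' Reverse complement of an IUPAC pattern
#' @keywords internal
iupac_revcomp <- function(pattern) {
  chars <- rev(strsplit(toupper(pattern), "")[[1]])
  paste(unname(IUPAC_COMPLEMENT[chars]), collapse = "")
}

#' Draw a concrete DNA realization of an IUPAC pattern
#'
#' Each degenerate position is sampled uniformly from its base set.
#' @keywords internal
iupac_realize <- function(pattern) {
  sets <- iupac_sets(pattern)
  paste(vapply(sets, function(s) s[sample.int(length(s), 1L)], character(1)),
        collapse = "")
}

#' Per-position compatibility between two equal-length IUPAC strings
#'
#' Two positions are compatible when their base sets intersect.
#' @keywords internal
iupac_compatible_positions <- function(a, b) {
  sa <- iupac_sets(a)
  sb <- iupac_sets(b)
  stopifnot(length(sa) == length(sb))
  mapply(function(x, y) length(intersect(x, y)) > 0, sa, sb)
}

#' IUPAC consensus letter for a set of bases
#' @keywords internal
bases_to_iupac <- function(bases) {
  bases <- sort(unique(bases))
  for (code in names(IUPAC_SETS)) {
    if (identical(sort(IUPAC_SETS[[code]]), bases)) return(code)
  }
  "N"
}
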