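# Independent oracles used across the suite. These deliberately re-derive
# results by direct loops/enumeration, not by calling the implementation.

# Brute-force induction-rule scanner: direct per-gene loop over windows.
brute_force_up <- function(ratio, p, up = 1.8, down = -1.8, alpha = 0.05,
                           min_consec = 2, never_down = TRUE) {
  hits <- character(0)
  for (g in rownames(ratio)) {
    ind <- ratio[g, ] >= up & p[g, ] < alpha
    ok <- FALSE
    if (min_consec <= length(ind)) {
      for (s in seq_len(length(ind) - min_consec + 1)) {
        if (all(ind[s:(s + min_consec - 1)])) ok <- TRUE
      }
    }
    if (ok && never_down) {
      if (any(ratio[g, ] <= down & p[g, ] < alpha)) ok <- FALSE
    }
    if (ok) hits <- c(hits, g)
  }
  hits
}

brute_force_down <- function(ratio, p, up = 1.8, down = -1.8, alpha = 0.05) {
  hits <- character(0)
  for (g in rownames(ratio)) {
    has_down <- any(ratio[g, ] <= down & p[g, ] < alpha)
    never_up <- !any(ratio[g, ] >= up)
    if (has_down && never_up) hits <- c(hits, g)
  }
  hits
}

# Exhaustive hypergeometric enumeration of the one-sided (greater) Fisher
# p-value: sum table probabilities over all tables with the same margins
# and a first cell at least as large as observed.
enumerate_fisher_greater <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, xs) + lchoose(r2, c1 - xs) - lchoose(n, c1)
  sum(exp(logp[xs >= a]))
}

# Random time-course matrix with mixed significant/non-significant cells.
random_tcm <- function(n, timepoints = c(0.5, 2, 4, 6, 12, 18, 24, 36, 48, 96)) {
  ratio <- matrix(stats::rnorm(n * length(timepoints), 0, 2), n,
                  dimnames = list(sprintf("g%04d", seq_len(n)), NULL))
  p <- matrix(stats::runif(n * length(timepoints)), n)
  rownames(p) <- rownames(ratio)
  time_course_matrix(ratio, p, timepoints)
}

# Uniform random promoter set with a pattern planted in a chosen subset.
planted_promoters <- function(n, L, pattern, carriers) {
  seqs <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- sprintf("p%04d", seq_len(n))
  w <- nchar(pattern)
  for (i in carriers) {
    pos <- sample.int(L - w + 1, 1)
    substr(seqs[i], pos, pos + w - 1) <- pattern
  }
  seqs
}

# Character-level Hamming distance between equal-length strings.
str_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Has any discovered motif recovered `pattern` (either orientation,
# Hamming <= ham) at or above `min_occ` percent occurrence?
recovered_pattern <- function(motifs, pattern, ham = 1, min_occ = 60) {
  rc <- chillregnet:::iupac_revcomp(pattern)
  any(vapply(motifs, function(m) {
    if (nchar(m$consensus) != nchar(pattern)) return(FALSE)
    d <- min(str_hamming(m$consensus, pattern), str_hamming(m$consensus, rc))
    d <= ham && m$occurrence_pct >= min_occ
  }, logical(1)))
}

# Small study bundle used by several tests.
small_bundle <- function(seed = 5L, n_genes = 600L, n_clusters = 6L, ...) {
  generate_study(simulation_config(n_genes = n_genes, n_clusters = n_clusters,
                                   seed = seed, ...))
}
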