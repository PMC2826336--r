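#' Motif discovery configuration
#'
#' Controls the per-cluster de novo promoter motif search: number of motif
#' slots extracted per run, candidate widths, the site-calling threshold
#' (fraction of the maximal PWM log-odds score a window must reach to be
#' called a site), EM limits, and strand handling.
#'
#' @param n_motifs motif slots per run (default 30).
#' @param widths candidate motif widths in nt (default 8:10).
#' @param site_threshold fraction of the maximal achievable PWM log-odds
#'   score required to call a site (default 0.875).
#' @param max_iter maximum EM iterations per seed (default 50).
#' @param tol EM convergence tolerance on the log likelihood.
#' @param strand `"both"` (default; cis-elements are orientation-ambiguous)
#'   or `"forward"`.
#' @param n_seeds enumerated frequent w-mers tried as EM starting points
#'   per slot and width.
#' @param tic_floor minimum total information content (bits) for a motif to
#'   be reported.
#' @param pseudocount added per base per PWM column (default 0.25).
#' @param seed integer seed (the procedure is deterministic given it).
#' @return object of class `discovery_config`.
#' @export
discovery_config <- function(n_motifs = 30L, widths = 8:10,
                             site_threshold = 0.875, max_iter = 50L,
                             tol = 1e-4, strand = c("both", "forward"),
                             n_seeds = 3L, tic_floor = 6,
                             pseudocount = 0.25, seed = 1L) {
  strand <- match.arg(strand)
  if (!(site_threshold > 0 && site_threshold <= 1)) {
    stop("site_threshold must lie in (0, 1]")
  }
  if (any(widths < 2)) stop("motif widths must be >= 2")
  structure(list(n_motifs = as.integer(n_motifs), widths = as.integer(widths),
                 site_threshold = site_threshold, max_iter = as.integer(max_iter),
                 tol = tol, strand = strand, n_seeds = as.integer(n_seeds),
                 tic_floor = tic_floor, pseudocount = pseudocount,
                 seed = as.integer(seed)),
            class = "discovery_config")
}

BASES <- c("A", "C", "G", "T")

# Encode sequences (character or DNAStringSet) as integer vectors:
# A=1, C=2, G=3, T=4, anything else (N, masked) = 0.
encode_seqs <- function(seqs) {
  if (inherits(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%03d", seq_along(seqs))
  lapply(seqs, function(s) {
    m <- match(strsplit(toupper(s), "")[[1]], BASES)
    m[is.na(m)] <- 0L
    as.integer(m)
  })
}

revcomp_int <- function(x) {
  y <- rev(x)
  ifelse(y == 0L, 0L, 5L - y)
}

# Window table over a set of integer-coded sequences: for each strand, a
# sparse indicator matrix M (4w x n_windows) with a 1 at row
# 4*(position-1) + base for every window position, the owning sequence,
# the 1-based offset on the scanned strand, a validity mask (windows
# containing masked/N bases), and a base-4 hash of each window for w-mer
# seeding. Built once per (slot, width); PWM scoring and weighted base
# counting each reduce to one sparse matrix product.
window_table <- function(ints, w, strand) {
  seq_lens <- lengths(ints)
  usable <- which(seq_lens >= w)
  blocks <- list()
  pow <- 4^(seq_len(w) - 1L)
  for (st in if (strand == "both") c("+", "-") else "+") {
    xs <- if (st == "+") ints[usable] else lapply(ints[usable], revcomp_int)
    lens <- lengths(xs)
    starts <- c(0L, cumsum(lens + w))[seq_along(xs)]
    offs <- lapply(lens, function(L) seq_len(L - w + 1L))
    nwin_each <- lengths(offs)
    concat <- unlist(lapply(xs, function(v) c(v, integer(w))),
                     use.names = FALSE)
    gstart <- unlist(offs, use.names = FALSE) + rep(starts, nwin_each)
    nwin <- length(gstart)
    B <- matrix(0L, nwin, w)
    for (j in seq_len(w)) B[, j] <- concat[gstart + j - 1L]
    valid <- rowSums(B == 0L) == 0L
    Bsafe <- pmax(B, 1L)
    M <- Matrix::sparseMatrix(
      i = as.vector(Bsafe + matrix(4L * (seq_len(w) - 1L), nwin, w,
                                   byrow = TRUE)),
      j = rep(seq_len(nwin), times = w), x = 1,
      dims = c(4L * w, nwin))
    seq_idx <- rep(usable, nwin_each)
    S <- Matrix::sparseMatrix(i = seq_idx, j = seq_len(nwin), x = 1,
                              dims = c(length(ints), nwin))
    blocks[[st]] <- list(
      M = M, S = S, valid = valid,
      hash = as.numeric((Bsafe - 1L) %*% pow),
      seq_idx = seq_idx,
      offset = unlist(offs, use.names = FALSE),
      strand = st
    )
  }
  blocks
}

# Score every window of one strand block against a (4 x w) score matrix.
# Windows containing a masked/N base score -Inf.
score_windows <- function(block, scores, w) {
  s <- as.numeric(Matrix::crossprod(block$M, as.vector(scores)))
  s[!block$valid] <- -Inf
  s
}

# Weighted base counts of windows (responsibilities z), returned as 4 x w.
weighted_counts <- function(block, z, w) {
  matrix(as.numeric(block$M %*% (z * block$valid)), 4L, w)
}

#' Total information content of a position weight matrix
#'
#' Sum over columns of 2 minus the column's Shannon entropy (bits), i.e.
#' against a uniform background; bounded by `[0, 2w]`.
#'
#' @param pwm numeric matrix, 4 rows (A, C, G, T) x width columns, each
#'   column summing to 1.
#' @return bits, a single number.
#' @export
compute_tic <- function(pwm) {
  if (nrow(pwm) != 4L) stop("PWM must have 4 rows (A, C, G, T)")
  if (any(abs(colSums(pwm) - 1) > 1e-9)) stop("PWM columns must sum to 1")
  ent <- apply(pwm, 2L, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  sum(2 - ent)
}

#' IUPAC consensus string of a PWM
#'
#' A position's consensus letter covers every base with probability at
#' least 0.30 (falling back to the most probable base).
#' @keywords internal
pwm_consensus <- function(pwm, min_prob = 0.30) {
  paste(apply(pwm, 2L, function(p) {
    b <- BASES[p >= min_prob]
    if (length(b) == 0L) b <- BASES[which.max(p)]
    bases_to_iupac(b)
  }), collapse = "")
}

pwm_logodds <- function(pwm, bg) log2(pwm / bg)

pwm_max_score <- function(logodds) sum(apply(logodds, 2L, max))

#' Scan sequences for sites of a motif model
#'
#' A site is called wherever the PWM log-odds score reaches
#' `site_threshold` times the maximal achievable score, scanning the
#' strands given by the motif's strand mode.
#'
#' @param motif a `motif_model` (as returned by [discover_motifs()]).
#' @param seqs named character vector or `DNAStringSet` of promoter
#'   sequences.
#' @param site_threshold overrides the motif's stored threshold if given.
#' @return data.frame of sites: `gene`, `offset` (1-based on the scanned
#'   strand), `strand`, `score`.
#' @export
scan_sites <- function(motif, seqs, site_threshold = NULL) {
  if (is.null(site_threshold)) site_threshold <- motif$site_threshold
  ints <- encode_seqs(seqs)
  w <- ncol(motif$pwm)
  lo <- pwm_logodds(motif$pwm, motif$background)
  cutoff <- site_threshold * pwm_max_score(lo)
  blocks <- window_table(ints, w, motif$strand_mode)
  call_sites_blocks(blocks, lo, cutoff, names(ints), w)
}

# Site calls from prebuilt window blocks (shared by scan_sites and the
# discovery loop, which reuses the blocks of the winning width).
call_sites_blocks <- function(blocks, lo, cutoff, seq_names, w) {
  out <- list()
  for (block in blocks) {
    s <- score_windows(block, lo, w)
    hit <- which(s >= cutoff)
    if (length(hit) > 0L) {
      out[[block$strand]] <- data.frame(
        gene = seq_names[block$seq_idx[hit]],
        offset = block$offset[hit], strand = block$strand,
        score = s[hit], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(gene = character(0), offset = integer(0),
                      strand = character(0), score = numeric(0)))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Percent of promoters carrying at least one motif site
#'
#' @inheritParams scan_sites
#' @return occurrence percentage in `[0, 100]`.
#' @export
score_occurrence <- function(motif, seqs, site_threshold = NULL) {
  if (inherits(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%03d", seq_along(seqs))
  sites <- scan_sites(motif, seqs, site_threshold)
  100 * length(unique(sites$gene)) / length(seqs)
}

# One ZOOPS EM run from a seed PWM. Returns the fitted model and the final
# log-likelihood ratio against the pure-background model.
zoops_em <- function(blocks, seed_pwm, bg, n_seq, w, max_iter, tol, pseudo) {
  theta <- seed_pwm
  gamma <- 0.5
  m_i <- numeric(n_seq)
  for (block in blocks) m_i <- m_i + tabulate(block$seq_idx, nbins = n_seq)
  m_i <- pmax(m_i, 1)
  prev_ll <- -Inf
  ll <- prev_ll
  for (it in seq_len(max_iter)) {
    lr_scores <- log(theta / bg)
    # likelihood ratio of each window under the motif vs background
    persum <- numeric(n_seq)
    zs <- list()
    for (bn in names(blocks)) {
      lr <- exp(score_windows(blocks[[bn]], lr_scores, w))
      zs[[bn]] <- lr
      persum <- persum + as.numeric(blocks[[bn]]$S %*% lr)
    }
    denom_i <- (1 - gamma) + gamma * persum / m_i
    ll <- sum(log(pmax(denom_i, .Machine$double.xmin)))
    counts <- matrix(0, 4L, w)
    zsum_i <- numeric(n_seq)
    for (bn in names(blocks)) {
      idx <- blocks[[bn]]$seq_idx
      z <- (gamma / m_i[idx]) * zs[[bn]] / denom_i[idx]
      counts <- counts + weighted_counts(blocks[[bn]], z, w)
      zsum_i <- zsum_i + as.numeric(blocks[[bn]]$S %*% z)
    }
    gamma <- min(max(mean(pmin(zsum_i, 1)), 0.01), 0.99)
    theta <- sweep(counts + pseudo, 2L, colSums(counts) + 4 * pseudo, "/")
    if (is.finite(prev_ll) && abs(ll - prev_ll) < tol * (abs(ll) + 1)) break
    prev_ll <- ll
  }
  list(pwm = theta, gamma = gamma, loglik = ll)
}

# Top seed w-mers by count among currently unmasked windows, via base-4
# hashing of the windows.
seed_kmers <- function(blocks, w, n_seeds) {
  hashes <- numeric(0)
  for (block in blocks) {
    hashes <- c(hashes, block$hash[block$valid])
  }
  if (length(hashes) == 0L) return(list())
  counts <- tabulate(hashes + 1, nbins = 4^w)
  nz <- which(counts > 0L)
  top <- nz[order(counts[nz], decreasing = TRUE)[
    seq_len(min(n_seeds, length(nz)))]] - 1
  lapply(top, function(h) {
    v <- integer(w)
    for (j in seq_len(w)) {
      v[j] <- (h %% 4) + 1
      h <- h %/% 4
    }
    as.integer(v)
  })
}

seed_pwm_from_kmer <- function(kmer, match_prob = 0.7) {
  w <- length(kmer)
  pwm <- matrix((1 - match_prob) / 3, 4L, w)
  pwm[cbind(kmer, seq_len(w))] <- match_prob
  pwm
}

#' De novo promoter motif discovery by iterative ZOOPS EM
#'
#' Extracts `n_motifs` motif slots from a set of promoter sequences. For
#' each slot, frequent w-mers among the unmasked windows seed a
#' zero-or-one-site-per-sequence EM against the sequence-set base
#' composition; candidate widths are fitted independently and the slot
#' keeps the width with the best EM objective. Sites scoring at least
#' `site_threshold` of the maximal PWM log-odds score are called, the
#' motif is recorded (unless its total information content falls below
#' `tic_floor`), and its sites are masked before the next slot.
#' Deterministic for a fixed config seed.
#'
#' @param seqs named character vector or `DNAStringSet` of promoter
#'   sequences (at least 5).
#' @param config a [discovery_config()].
#' @return list of `motif_model` objects, each with elements `pwm`,
#'   `consensus`, `width`, `tic`, `occurrence_pct`, `sites`, `gamma`,
#'   `loglik`, `background`, `site_threshold`, `strand_mode`.
#' @export
discover_motifs <- function(seqs, config = discovery_config()) {
  if (inherits(seqs, "DNAStringSet")) seqs <- as.character(seqs)
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq%03d", seq_along(seqs))
  if (length(seqs) < 5L) stop("need at least 5 sequences")
  ints <- encode_seqs(seqs)
  if (all(unlist(ints) == 0L)) stop("sequences contain no unambiguous bases")
  if (max(config$widths) > max(lengths(ints))) {
    stop("motif width exceeds sequence length")
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(config$seed)
  n_seq <- length(ints)
  base_tab <- tabulate(unlist(ints)[unlist(ints) > 0L], nbins = 4L)
  bg <- (base_tab + 1) / sum(base_tab + 1)
  motifs <- list()
  work <- ints
  for (slot in seq_len(config$n_motifs)) {
    best <- NULL
    best_blocks <- NULL
    for (w in config$widths) {
      if (w > max(lengths(work))) next
      blocks <- window_table(work, w, config$strand)
      if (sum(vapply(blocks, function(b) sum(b$valid), integer(1))) == 0L) next
      seeds <- seed_kmers(blocks, w, config$n_seeds)
      if (length(seeds) == 0L) next
      # screen seeds with a short EM, then refine only the best one
      short <- lapply(seeds, function(kmer) {
        zoops_em(blocks, seed_pwm_from_kmer(kmer), bg, n_seq, w,
                 min(3L, config$max_iter), config$tol, config$pseudocount)
      })
      top <- which.max(vapply(short, `[[`, numeric(1), "loglik"))
      fit <- zoops_em(blocks, short[[top]]$pwm, bg, n_seq, w,
                      config$max_iter, config$tol, config$pseudocount)
      if (is.null(best) || fit$loglik > best$loglik) {
        best <- c(fit, list(width = w))
        best_blocks <- blocks
      }
    }
    if (is.null(best)) break
    motif <- structure(list(
      pwm = best$pwm, width = best$width,
      consensus = pwm_consensus(best$pwm),
      background = bg, gamma = best$gamma, loglik = best$loglik,
      site_threshold = config$site_threshold, strand_mode = config$strand
    ), class = "motif_model")
    lo <- pwm_logodds(motif$pwm, motif$background)
    cutoff <- motif$site_threshold * pwm_max_score(lo)
    sites <- call_sites_blocks(best_blocks, lo, cutoff, names(work),
                               best$width)
    motif$sites <- sites
    motif$tic <- compute_tic(best$pwm)
    motif$occurrence_pct <- 100 * length(unique(sites$gene)) / n_seq
    work <- mask_sites(work, sites, best$width)
    if (nrow(sites) == 0L) {
      # nothing callable: stop extracting further slots
      if (motif$tic >= config$tic_floor) motifs[[length(motifs) + 1L]] <- motif
      break
    }
    if (motif$tic >= config$tic_floor) motifs[[length(motifs) + 1L]] <- motif
  }
  motifs
}

ints_to_char <- function(x) {
  paste(c("N", BASES)[x + 1L], collapse = "")
}

mask_sites <- function(ints, sites, w) {
  if (nrow(sites) == 0L) return(ints)
  for (r in seq_len(nrow(sites))) {
    g <- sites$gene[r]
    x <- ints[[g]]
    L <- length(x)
    if (sites$strand[r] == "+") {
      pos <- sites$offset[r]:(sites$offset[r] + w - 1L)
    } else {
      # offset is on the reverse strand; map back to forward coordinates
      pos <- (L - sites$offset[r] - w + 2L):(L - sites$offset[r] + 1L)
    }
    x[pos[pos >= 1L & pos <= L]] <- 0L
    ints[[g]] <- x
  }
  ints
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("motif_model %s  width=%d  TIC=%.2f bits  occurrence=%.0f%%%s\n",
              x$consensus, x$width, x$tic, x$occurrence_pct,
              if (!is.null(x$e_value)) sprintf("  e=%.1e", x$e_value) else ""))
  invisible(x)
}

#' Background subtraction of random motif occurrence
#'
#' Compares each motif's foreground occurrence against promoters of genes
#' not involved in the response (the background set). The e-value is a
#' Bonferroni-scaled one-sided binomial tail probability of the foreground
#' site-carrying count given the background per-sequence site probability;
#' motifs with e-value above `alpha_e` are removed.
#'
#' @param motifs list of `motif_model`s with `sites` over the foreground
#'   set of `n_fg` sequences.
#' @param fg_seqs foreground promoter sequences the motifs came from.
#' @param bg_seqs background promoter sequences (non-responsive genes).
#' @param alpha_e e-value cutoff (default 1e-3).
#' @param n_tests Bonferroni factor; defaults to the number of motifs
#'   tested.
#' @return the retained motifs, each annotated with `e_value` and
#'   `bg_occurrence_pct`.
#' @export
background_filter <- function(motifs, fg_seqs, bg_seqs, alpha_e = 1e-3,
                              n_tests = length(motifs)) {
  if (length(bg_seqs) == 0L) stop("background promoter set is empty")
  if (inherits(fg_seqs, "DNAStringSet")) fg_seqs <- as.character(fg_seqs)
  if (inherits(bg_seqs, "DNAStringSet")) bg_seqs <- as.character(bg_seqs)
  n_fg <- length(fg_seqs)
  n_bg <- length(bg_seqs)
  if (is.null(names(bg_seqs))) {
    names(bg_seqs) <- sprintf("bg%04d", seq_along(bg_seqs))
  }
  bg_ints <- encode_seqs(bg_seqs)
  bg_blocks <- list()  # window tables cached per (width, strand mode)
  kept <- list()
  for (m in motifs) {
    key <- paste(m$width, m$strand_mode)
    if (is.null(bg_blocks[[key]])) {
      bg_blocks[[key]] <- window_table(bg_ints, m$width, m$strand_mode)
    }
    lo <- pwm_logodds(m$pwm, m$background)
    cutoff <- m$site_threshold * pwm_max_score(lo)
    bg_sites <- call_sites_blocks(bg_blocks[[key]], lo, cutoff,
                                  names(bg_ints), m$width)
    bg_occ <- length(unique(bg_sites$gene)) / n_bg
    q <- if (bg_occ == 0) 0.5 / (n_bg + 1) else bg_occ
    x <- round(m$occurrence_pct / 100 * n_fg)
    e <- max(n_tests, 1L) *
      stats::pbinom(x - 1L, size = n_fg, prob = q, lower.tail = FALSE)
    m$e_value <- e
    m$bg_occurrence_pct <- 100 * bg_occ
    if (e <= alpha_e) kept[[length(kept) + 1L]] <- m
  }
  kept
}
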