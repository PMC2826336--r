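test_that("promoter windows are cut, clipped and strand-flipped correctly", {
  set.seed(8)
  chr <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
               collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = chr))
  tss <- data.frame(gene_id = c("gA", "gB", "gC", "gD"),
                    chrom = "chr1", strand = c("+", "+", "-", "+"),
                    tss = c(1500, 400, 5000, 20000))
  pr <- extract_promoters(genome, tss)
  # plus strand: [TSS-1000, TSS+200) covers 1-based 500..1699, 1200 nt
  expect_equal(pr$table$start[pr$table$gene_id == "gA"], 500)
  expect_equal(pr$table$end[pr$table$gene_id == "gA"], 1699)
  expect_equal(pr$table$width[pr$table$gene_id == "gA"], 1200)
  expect_false(pr$table$truncated[pr$table$gene_id == "gA"])
  # near the contig start the window is clipped and flagged
  expect_true(pr$table$truncated[pr$table$gene_id == "gB"])
  expect_lt(pr$table$width[pr$table$gene_id == "gB"], 1200)
  # minus strand: reverse complement of the opposite-side slice
  slice <- Biostrings::subseq(genome[["chr1"]], 5000 - 199, 5000 + 1000)
  expect_equal(as.character(pr$sequences[["gC"]]),
               as.character(Biostrings::reverseComplement(slice)))
  # off-contig TSS becomes an error record, not a crash
  expect_equal(pr$errors$gene_id, "gD")
  expect_false("gD" %in% names(pr$sequences))
})

test_that("total information content follows the entropy arithmetic", {
  uniform <- matrix(0.25, 4, 8)
  expect_equal(compute_tic(uniform), 0)
  fixed <- matrix(0, 4, 8); fixed[1, ] <- 1
  expect_equal(compute_tic(fixed), 16)
  half <- fixed; half[, 8] <- c(0.5, 0.5, 0, 0)
  expect_equal(compute_tic(half), 15)
  # property: 0 <= TIC <= 2w for random PWMs
  set.seed(3)
  for (i in 1:25) {
    w <- sample(8:10, 1)
    p <- matrix(rgamma(4 * w, 1), 4, w)
    p <- sweep(p, 2, colSums(p), "/")
    tic <- compute_tic(p)
    expect_gte(tic, 0)
    expect_lte(tic, 2 * w)
  }
  expect_error(compute_tic(matrix(0.3, 4, 4)), "sum to 1")
})

test_that("site calling equals a brute-force full scan", {
  set.seed(5)
  seqs <- planted_promoters(50, 80, "TGACGTCA", carriers = 1:25)
  pwm <- matrix(0.04, 4, 8)
  kmer <- match(strsplit("TGACGTCA", "")[[1]], c("A", "C", "G", "T"))
  pwm[cbind(kmer, 1:8)] <- 0.88
  motif <- structure(list(pwm = pwm, width = 8L, consensus = "TGACGTCA",
                          background = rep(0.25, 4), site_threshold = 0.875,
                          strand_mode = "both"), class = "motif_model")
  sites <- scan_sites(motif, seqs)
  # independent full scan: score every offset on both strands by loops
  lo <- log2(pwm / 0.25)
  cutoff <- 0.875 * sum(apply(lo, 2, max))
  expected <- 0L
  for (g in names(seqs)) {
    for (strand in c("+", "-")) {
      s <- if (strand == "+") seqs[[g]] else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(seqs[[g]])))
      v <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
      for (off in 1:(length(v) - 7)) {
        sc <- sum(lo[cbind(v[off:(off + 7)], 1:8)])
        if (sc >= cutoff) {
          expected <- expected + 1L
          expect_true(any(sites$gene == g & sites$offset == off &
                            sites$strand == strand))
        }
      }
    }
  }
  expect_equal(nrow(sites), expected)
  # a reverse-strand-only site is found only in both-strand mode
  one <- c(s1 = paste0(strrep("A", 30), "TGACGTCG", strrep("A", 30)))
  rc_only <- c(s1 = as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(one[[1]]))))
  fwd_motif <- motif
  fwd_motif$strand_mode <- "forward"
  fwd_motif$pwm[, 8] <- c(0.04, 0.04, 0.88, 0.04)  # non-palindromic TGACGTCG
  expect_equal(score_occurrence(fwd_motif, rc_only), 0)
  both_motif <- fwd_motif
  both_motif$strand_mode <- "both"
  expect_equal(score_occurrence(both_motif, rc_only), 100)
})

test_that("a planted motif is discovered with its occurrence", {
  set.seed(7)
  seqs <- planted_promoters(60, 600, "TGACGTCA",
                            carriers = which(runif(60) < 0.7))
  cfg <- discovery_config(n_motifs = 3, widths = 8, max_iter = 25,
                          n_seeds = 2, seed = 1)
  ms <- discover_motifs(seqs, cfg)
  expect_true(recovered_pattern(ms, "TGACGTCA"))
  # PWM columns are normalized and the model is self-consistent
  for (m in ms) {
    expect_equal(colSums(m$pwm), rep(1, m$width), tolerance = 1e-9)
    expect_equal(m$occurrence_pct,
                 100 * length(unique(m$sites$gene)) / length(seqs))
  }
  # determinism under a fixed seed
  ms2 <- discover_motifs(seqs, cfg)
  expect_identical(lapply(ms, `[[`, "pwm"), lapply(ms2, `[[`, "pwm"))
})

test_that("degenerate and invalid inputs are handled", {
  mono <- setNames(rep(strrep("A", 100), 6), sprintf("s%d", 1:6))
  cfg <- discovery_config(n_motifs = 2, widths = 8, max_iter = 10, seed = 1)
  ms <- discover_motifs(mono, cfg)
  # a homopolymer yields no informative motif above the floor on both strands
  expect_true(all(vapply(ms, function(m) m$tic >= cfg$tic_floor, logical(1))))
  expect_error(discover_motifs(setNames(rep(strrep("N", 50), 6),
                                        sprintf("s%d", 1:6)), cfg),
               "unambiguous")
  expect_error(discover_motifs(setNames(rep("ACGT", 6), sprintf("s%d", 1:6)),
                               cfg), "width")
  expect_error(discover_motifs(c(a = strrep("ACGT", 20)), cfg), "at least 5")
})

test_that("background subtraction follows the binomial tail oracle", {
  set.seed(9)
  pwm <- matrix(0.01, 4, 8)
  kmer <- match(strsplit("TGACGTCA", "")[[1]], c("A", "C", "G", "T"))
  pwm[cbind(kmer, 1:8)] <- 0.97
  motif <- structure(list(pwm = pwm, width = 8L, consensus = "TGACGTCA",
                          background = rep(0.25, 4), site_threshold = 0.875,
                          strand_mode = "forward", occurrence_pct = 70,
                          tic = compute_tic(pwm)), class = "motif_model")
  fg <- planted_promoters(100, 200, "TGACGTCA", carriers = 1:70)
  bg65 <- planted_promoters(100, 200, "TGACGTCA", carriers = 1:65)
  bg10 <- planted_promoters(100, 200, "TGACGTCA", carriers = 1:10)
  # fg 70% vs bg 65%: no enrichment, removed
  expect_length(background_filter(list(motif), fg, bg65, n_tests = 1), 0L)
  # fg 70% vs bg 10%: kept with a small e-value matching the oracle
  kept <- background_filter(list(motif), fg, bg10, n_tests = 1)
  expect_length(kept, 1L)
  bg_rate <- kept[[1]]$bg_occurrence_pct / 100
  oracle <- sum(dbinom(70:100, 100, bg_rate))
  expect_equal(kept[[1]]$e_value, oracle, tolerance = 1e-9)
  expect_lt(kept[[1]]$e_value, 1e-3)
  # fg equal to bg: removed
  expect_length(background_filter(list(motif), fg,
                                  planted_promoters(100, 200, "TGACGTCA",
                                                    carriers = 1:70),
                                  n_tests = 1), 0L)
  expect_error(background_filter(list(motif), fg, character(0)), "empty")
})

test_that("recovery power increases with the planted rate", {
  rates <- c(0.3, 0.9)
  hits <- sapply(rates, function(r) {
    n_rec <- 0L
    for (s in 1:5) {
      set.seed(100 + s)
      seqs <- planted_promoters(50, 400, "TGACGTCA",
                                carriers = which(runif(50) < r))
      ms <- discover_motifs(seqs, discovery_config(n_motifs = 2, widths = 8,
                                                   max_iter = 20, n_seeds = 2,
                                                   seed = s))
      if (recovered_pattern(ms, "TGACGTCA", min_occ = 100 * r * 0.8)) {
        n_rec <- n_rec + 1L
      }
    }
    n_rec
  })
  expect_gte(hits[2], hits[1])
  expect_gte(hits[2], 4L)
})
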