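test_that("configuration invariants are enforced", {
  expect_error(simulation_config(phase_mixture = c(0.5, 0.5, 0.5)), "sum to 1")
  expect_error(simulation_config(noise_sd = -0.1), "non-negative")
  expect_error(simulation_config(planted_rate = 1.5), "\\[0, 1\\]")
  expect_error(simulation_config(chilling_timepoints = c(2, 1)), "increasing")
  expect_error(generate_gene_universe(simulation_config(n_genes = 0)),
               "positive")
})

test_that("gene universe is deterministic and hits the TF fraction", {
  cfg <- simulation_config(n_genes = 2604, tf_fraction = 0.06, seed = 7)
  u1 <- generate_gene_universe(cfg)
  u2 <- generate_gene_universe(cfg)
  expect_identical(u1, u2)
  # ~148 of 2,604 genes are TFs: binomial 99.9% interval around 6%
  n_tf <- sum(u1$is_tf)
  expect_gte(n_tf, qbinom(0.0005, 2604, 0.06))
  expect_lte(n_tf, qbinom(0.9995, 2604, 0.06))
  expect_true(all(u1$tf_family[u1$is_tf] %in%
                    c("bZIP", "AP2/ERF", "MYB", "WRKY", "bHLH", "NAC")))
  u0 <- generate_gene_universe(simulation_config(n_genes = 500,
                                                 tf_fraction = 0, seed = 1))
  expect_equal(sum(u0$is_tf), 0L)
})

test_that("noise-free time courses are recovered exactly by the calls", {
  cfg <- simulation_config(n_genes = 400, noise_sd = 0, seed = 3)
  u <- generate_gene_universe(cfg)
  tc <- simulate_timecourse(u, cfg)
  up <- call_upregulated(tc$chilling)
  expect_setequal(up$gene_id, tc$truth$up)
  expect_setequal(call_downregulated(tc$chilling)$gene_id, tc$truth$down)
  expect_setequal(call_h2o2_responsive(tc$h2o2), tc$truth$h2o2)
  # assigned phases match the planted ones
  planted <- tc$truth$genes$phase[match(up$gene_id, tc$truth$genes$gene_id)]
  expect_equal(up$phase, planted)
})

test_that("a pure phase-1 mixture yields only phase-1 genes", {
  cfg <- simulation_config(n_genes = 300, noise_sd = 0,
                           phase_mixture = c(1, 0, 0), seed = 2)
  tc <- simulate_timecourse(generate_gene_universe(cfg), cfg)
  up <- call_upregulated(tc$chilling)
  expect_true(all(up$phase == 1L))
})

test_that("p-values match t.test on replicate draws", {
  cfg <- simulation_config(n_genes = 30, noise_sd = 0.4, n_replicates = 4,
                           seed = 9)
  u <- generate_gene_universe(cfg)
  # re-derive one cell's p-value with stats::t.test on the same replicates
  mu <- matrix(1.5, 2, 3)
  set.seed(1)
  m <- chillregnet:::noisy_matrix(mu, cfg, c("a", "b"), c(1, 3, 6))
  set.seed(1)
  reps <- array(mu, dim = c(2, 3, 4)) + rnorm(24, sd = 0.4)
  for (i in 1:2) for (j in 1:3) {
    expect_equal(m$p[i, j], t.test(reps[i, j, ])$p.value, tolerance = 1e-12)
    expect_equal(m$ratio[i, j], mean(reps[i, j, ]), tolerance = 1e-12)
  }
})

test_that("planted promoter occurrence matches the configured rate", {
  cfg <- simulation_config(n_genes = 400, n_clusters = 2, up_fraction = 0.6,
                           planted_rate = 0.7, noise_sd = 0, seed = 21)
  u <- generate_gene_universe(cfg)
  tc <- simulate_timecourse(u, cfg)
  prom <- simulate_promoters(u, tc$truth, cfg)
  cl1 <- tc$truth$clusters$cluster[1]
  pat <- tc$truth$clusters$pattern[1]
  members <- tc$truth$genes$gene_id[!is.na(tc$truth$genes$cluster) &
                                      tc$truth$genes$cluster == cl1]
  n <- length(members)
  carrying <- sum(vapply(members, function(g) {
    s <- prom$sequences[[g]]
    Biostrings::countPattern(pat, s, fixed = FALSE) +
      Biostrings::countPattern(chillregnet:::iupac_revcomp(pat), s,
                               fixed = FALSE) > 0
  }, logical(1)))
  expect_gte(carrying, qbinom(0.005, n, 0.7))
  expect_lte(carrying, qbinom(0.995, n, 0.7))
  # rate 1 plants in every member promoter
  cfg1 <- simulation_config(n_genes = 200, n_clusters = 2, planted_rate = 1,
                            noise_sd = 0, seed = 22)
  u1 <- generate_gene_universe(cfg1)
  tc1 <- simulate_timecourse(u1, cfg1)
  p1 <- simulate_promoters(u1, tc1$truth, cfg1)
  mem <- tc1$truth$genes$gene_id[!is.na(tc1$truth$genes$cluster)]
  expect_setequal(unique(p1$instances$gene), mem)
  # a pattern longer than the promoter is a configuration error
  cfg_bad <- simulation_config(n_genes = 50, promoter_length = 6, seed = 1)
  u_bad <- generate_gene_universe(cfg_bad)
  tc_bad <- simulate_timecourse(u_bad, cfg_bad)
  expect_error(simulate_promoters(u_bad, tc_bad$truth, cfg_bad), "longer")
  # determinism
  pa <- simulate_promoters(u1, tc1$truth, cfg1)
  expect_identical(as.character(pa$sequences), as.character(p1$sequences))
})

test_that("QTL planting controls the up-TF association rate", {
  cfg <- simulation_config(n_genes = 800, qtl_enrichment_factor = 5, seed = 13)
  u <- generate_gene_universe(cfg)
  tc <- simulate_timecourse(u, cfg)
  q <- simulate_qtl_map(u, tc$truth, cfg)
  up_tf <- tc$truth$genes$gene_id[tc$truth$genes$role == "up" &
                                    tc$truth$genes$is_tf]
  rate <- mean(q$associations$associated[q$associations$gene_id %in% up_tf])
  target <- min(1, 5 * q$coverage)
  expect_gte(rate, qbinom(0.005, length(up_tf), target) / length(up_tf))
  expect_lte(rate, qbinom(0.995, length(up_tf), target) / length(up_tf))
  # an empty QTL map yields zero associations
  cfg0 <- simulation_config(n_genes = 100, n_qtl = 0, seed = 1)
  u0 <- generate_gene_universe(cfg0)
  tc0 <- simulate_timecourse(u0, cfg0)
  q0 <- simulate_qtl_map(u0, tc0$truth, cfg0)
  expect_equal(sum(q0$associations$associated), 0L)
})

test_that("a bundle writes and reads back loss-free with a manifest", {
  dir <- withr::local_tempdir()
  b <- small_bundle(seed = 5, n_genes = 200, n_clusters = 3)
  write_study_bundle(b, dir)
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"))
  expect_true(all(file.exists(file.path(dir, man$file))))
  b2 <- read_study_bundle(dir)
  expect_equal(b2$chilling$ratio, b$chilling$ratio, tolerance = 1e-10)
  expect_equal(b2$chilling$p, b$chilling$p, tolerance = 1e-10)
  expect_identical(as.character(b2$promoters), as.character(b$promoters))
  expect_setequal(b2$truth$up, b$truth$up)
  expect_equal(b2$qtl, b$qtl)
  # fixed seed: regenerating and rewriting gives identical checksums
  dir2 <- withr::local_tempdir()
  write_study_bundle(small_bundle(seed = 5, n_genes = 200, n_clusters = 3),
                     dir2)
  man2 <- jsonlite::fromJSON(file.path(dir2, "manifest.json"))
  expect_equal(man$md5, man2$md5)
})
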