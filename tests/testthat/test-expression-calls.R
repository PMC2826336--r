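grid <- c(0.5, 2, 4, 6, 12, 18, 24, 36, 48, 96)

mk_tcm <- function(ratios, ps = NULL, timepoints = grid) {
  ratio <- matrix(ratios, nrow = 1,
                  dimnames = list("g1", NULL))
  p <- if (is.null(ps)) matrix(0.01, 1, length(timepoints)) else
    matrix(ps, nrow = 1)
  rownames(p) <- "g1"
  time_course_matrix(ratio, p, timepoints)
}

test_that("time_course_matrix validates its invariants", {
  expect_error(mk_tcm(rep(0, 3), timepoints = c(2, 2, 4)), "increasing")
  r <- matrix(0, 1, 2); rownames(r) <- "g1"
  expect_error(time_course_matrix(r, matrix(2, 1, 2), c(1, 2)), "p-values")
  expect_error(time_course_matrix(r, matrix(c(0.5, NA), 1, 2), c(1, 2)),
               "missing")
  expect_error(time_course_matrix(matrix(0, 1, 2), matrix(0.5, 1, 2),
                                  c(1, 2)), "gene ids")
})

test_that("upregulation requires two consecutive induced samples", {
  # flat profile: nothing called
  expect_equal(nrow(call_upregulated(mk_tcm(rep(0, 10)))), 0L)
  # induced at adjacent samples 2 h and 4 h
  v <- rep(0, 10); v[grid %in% c(2, 4)] <- 2.0
  calls <- call_upregulated(mk_tcm(v))
  expect_equal(calls$gene_id, "g1")
  expect_equal(calls$induced[[1]], c(2, 4))
  expect_equal(calls$phase, 1L)
  # induced at 2 h and 6 h with 4 h below threshold: two length-1 runs
  v <- rep(0, 10); v[grid %in% c(2, 6)] <- 2.0
  expect_equal(nrow(call_upregulated(mk_tcm(v))), 0L)
  # the p-value filter applies per time point
  v <- rep(0, 10); v[grid %in% c(2, 4)] <- 2.0
  ps <- rep(0.01, 10); ps[grid == 4] <- 0.2
  expect_equal(nrow(call_upregulated(mk_tcm(v, ps))), 0L)
  # the never-down guard excludes genes with a significant repressed sample
  v <- rep(0, 10); v[grid %in% c(2, 4)] <- 2.0; v[grid == 48] <- -2.0
  expect_equal(nrow(call_upregulated(mk_tcm(v))), 0L)
  cfg <- call_config(require_never_down = FALSE)
  expect_equal(nrow(call_upregulated(mk_tcm(v), cfg)), 1L)
  expect_error(call_upregulated(mk_tcm(rep(0, 2), timepoints = c(1, 2)),
                                call_config(min_consecutive_up = 3)),
               "fewer time points")
})

test_that("downregulation needs one repressed sample and no up-threshold ratio", {
  v <- rep(0, 10); v[3] <- -2.0
  expect_equal(call_downregulated(mk_tcm(v))$gene_id, "g1")
  # an up-threshold ratio excludes, regardless of its p-value
  v <- rep(0, 10); v[grid == 2] <- -2.0; v[grid == 48] <- 2.0
  ps <- rep(0.01, 10); ps[grid == 48] <- 0.9
  expect_equal(nrow(call_downregulated(mk_tcm(v, ps))), 0L)
  cfg <- call_config(down_excludes_by_ratio_only = FALSE)
  expect_equal(nrow(call_downregulated(mk_tcm(v, ps), cfg)), 1L)
  expect_equal(nrow(call_downregulated(mk_tcm(rep(0, 10)))), 0L)
})

test_that("oxidative-mimic call is the single-time-point variant", {
  h_grid <- c(1, 3, 6)
  v <- c(0, 2.0, 0)
  expect_equal(call_h2o2_responsive(mk_tcm(v, timepoints = h_grid)), "g1")
  expect_equal(length(call_h2o2_responsive(
    mk_tcm(v, ps = rep(0.2, 3), timepoints = h_grid))), 0L)
  # threshold boundary is inclusive
  expect_equal(call_h2o2_responsive(mk_tcm(c(1.8, 0, 0), timepoints = h_grid)),
               "g1")
})

test_that("waves are maximal runs of consecutive samples", {
  w <- segment_waves(c(2, 4, 6), grid)
  expect_equal(nrow(w), 1L)
  expect_equal(c(w$start, w$end, w$duration), c(2, 6, 4))
  w2 <- segment_waves(c(2, 4, 36, 48), grid)
  expect_equal(nrow(w2), 2L)
  expect_equal(w2$start, c(2, 36))
  expect_equal(segment_waves(numeric(0), grid)$duration, numeric(0))
  # consecutive means adjacent samples, not adjacent hours
  w3 <- segment_waves(c(6, 12), grid)
  expect_equal(nrow(w3), 1L)
  expect_error(segment_waves(c(5), grid), "subset")
})

test_that("phases split at 6 h and 24 h with inclusive upper bounds", {
  cfg <- call_config()
  expect_equal(assign_phase(0.5, cfg), 1L)
  expect_equal(assign_phase(6, cfg), 1L)
  expect_equal(assign_phase(12, cfg), 2L)
  expect_equal(assign_phase(24, cfg), 2L)
  expect_equal(assign_phase(36, cfg), 3L)
  expect_error(assign_phase(NA_real_, cfg), "undefined")
})

test_that("set overlap partitions exactly, reproducing the headline counts", {
  # 2,604 upregulated genes of which 1,516 overlap the H2O2 set
  up <- sprintf("u%04d", 1:2604)
  h2o2 <- c(up[1:1516], sprintf("x%04d", 1:400))
  ov <- overlap_sets(up, h2o2)
  expect_equal(ov$counts[["both"]], 1516L)
  expect_equal(ov$counts[["only_a"]], 1088L)
  expect_equal(ov$counts[["a"]],
               ov$counts[["both"]] + ov$counts[["only_a"]])
  # TF subsets 86 chilling-only + 62 shared = 148
  expect_equal(86L + 62L, 148L %/% 1L)
  ov2 <- overlap_sets(letters[1:3], LETTERS[1:3])
  expect_equal(length(ov2$both), 0L)
})

test_that("calls agree with the brute-force scanner on random profiles", {
  set.seed(42)
  for (rep in 1:3) {
    m <- random_tcm(300)
    up <- call_upregulated(m)$gene_id
    dn <- call_downregulated(m)$gene_id
    expect_setequal(up, brute_force_up(m$ratio, m$p))
    expect_setequal(dn, brute_force_down(m$ratio, m$p))
    # up and down calls are disjoint by construction
    expect_length(intersect(up, dn), 0L)
    # phase partition is exhaustive and exclusive over the up set
    phases <- call_upregulated(m)$phase
    expect_true(all(phases %in% 1:3))
  }
})
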