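test_that("the packaged catalog loads and validates", {
  cat <- load_element_catalog()
  expect_true(all(c("as1/ocs/TGA-like", "ABRE-like", "DRE/CRT-like",
                    "GCC-box-like", "MYB2-box-like", "GARE-like",
                    "pyrimidine-box-like", "W-box-like", "MYC2-box-like")
                  %in% cat$class))
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("class\tbroad_category\tiupac_pattern\ttf_family\tsource",
               "x\tx\tACGQ\tbZIP\tz"), bad)
  expect_error(load_element_catalog(bad), "IUPAC")
})

test_that("consensus-to-class matching follows the compatibility rule", {
  m <- match_element_class("TGACGTCA")
  expect_equal(m$element_class, "as1/ocs/TGA-like")
  expect_equal(m$tf_family, "bZIP")
  # a GCC-box-rich consensus lands in the GCC-box class
  g <- match_element_class("CCGCCGCCG")
  expect_equal(g$element_class, "GCC-box-like")
  expect_equal(g$broad_category, "GCC-box/JAre-like")
  # an incompatible consensus stays unassigned
  r <- match_element_class("ATATATAT",
                           catalog = data.frame(
                             class = "x", broad_category = "x",
                             iupac_pattern = "GCGCGCGC", tf_family = "bZIP",
                             stringsAsFactors = FALSE))
  expect_equal(r$element_class, "unassigned")
  # matching is orientation-aware
  rc <- match_element_class(chillregnet:::iupac_revcomp("TACCGACA"))
  expect_equal(rc$element_class, "DRE/CRT-like")
})

test_that("total scores sum qualifying occurrence percentages", {
  tab <- data.frame(
    cluster = "C100A",
    motif = c("GGTTTGTA", "GAGGAAGA", "AAACAATG", "GCAATATA", "LOW"),
    broad_category = c(rep("as1/ocs/TGA-like", 4), "as1/ocs/TGA-like"),
    occurrence_pct = c(71, 69, 61, 58, 49), stringsAsFactors = FALSE)
  cs <- class_scores(tab)
  expect_equal(cs$total_score, 259)      # the 49% motif does not qualify
  expect_equal(cs$n_motif_species, 4L)
  # pooled DRE/CRT + rav1 category sums across sub-classes
  tab2 <- data.frame(cluster = "C81", motif = c("GTGGMGAC", "TCTMAACA"),
                     broad_category = "DRE/CRT/rav1-like",
                     occurrence_pct = c(61, 67), stringsAsFactors = FALSE)
  expect_equal(class_scores(tab2)$total_score, 128)
  # a single sub-50 motif leaves the class out entirely
  tab3 <- data.frame(cluster = "c", motif = "m", broad_category = "x",
                     occurrence_pct = 49, stringsAsFactors = FALSE)
  expect_equal(nrow(class_scores(tab3)), 0L)
})

test_that("scores equal an independent brute-force recomputation", {
  set.seed(6)
  tab <- data.frame(
    cluster = sample(c("A", "B"), 60, replace = TRUE),
    motif = sprintf("m%02d", 1:60),
    broad_category = sample(c("x", "y", "z"), 60, replace = TRUE),
    occurrence_pct = round(runif(60, 30, 95)), stringsAsFactors = FALSE)
  cs <- class_scores(tab)
  for (i in seq_len(nrow(cs))) {
    keep <- tab$cluster == cs$cluster[i] &
      tab$broad_category == cs$broad_category[i] & tab$occurrence_pct >= 50
    expect_equal(cs$total_score[i], sum(tab$occurrence_pct[keep]))
  }
  # removing a motif never increases any class score
  drop1 <- class_scores(tab[-1, , drop = FALSE])
  for (i in seq_len(nrow(drop1))) {
    before <- cs$total_score[cs$cluster == drop1$cluster[i] &
                               cs$broad_category == drop1$broad_category[i]]
    expect_gte(before, drop1$total_score[i])
  }
})

test_that("dominant classes rank by score with the species tiebreak", {
  enr <- data.frame(cluster = "c",
                    broad_category = c("as1", "GARE", "GCC"),
                    total_score = c(259, 120, 60),
                    n_motif_species = c(4L, 2L, 1L), stringsAsFactors = FALSE)
  expect_equal(dominant_classes(enr), c("as1", "GARE", "GCC"))
  expect_equal(dominant_classes(enr[1, , drop = FALSE]), "as1")
  tie <- data.frame(cluster = "c", broad_category = c("a", "b"),
                    total_score = c(100, 100), n_motif_species = c(1L, 3L),
                    stringsAsFactors = FALSE)
  expect_equal(dominant_classes(tie), c("b", "a"))
  expect_equal(dominant_classes(enr[0, , drop = FALSE]), character(0))
})

test_that("printed element labels pool into the graphing categories", {
  expect_equal(pool_element_labels(c("GA response element-like",
                                     "Pyrimidine box-like")),
               rep("GARE/pyrimidine-box-like", 2))
  expect_equal(pool_element_labels("MYB1-box-like"), "MYB2-box-like")
  expect_equal(pool_element_labels(c("DRE/CRT-like", "rav1b element-like")),
               rep("DRE/CRT/rav1-like", 2))
  expect_equal(pool_element_labels("RSG element"), "other")
})
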