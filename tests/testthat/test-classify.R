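make_two_profiles <- function() {
  list(toy_calibrated_profile(len = 30, seed = 1, name = "famA"),
       toy_calibrated_profile(len = 30, seed = 2, name = "famB"))
}

test_that("single passing profile wins; failing all gives unclassified", {
  ps <- make_two_profiles()
  dom <- setNames(sample_from_profile(ps[[1]], seed = 5), "d1")
  asg <- classify_competitive(dom, ps[1], evalue_cutoff = 0.01, db_size = 10)
  expect_equal(asg$family, "famA")
  expect_true(is.na(asg$margin)) # fewer than 2 passing profiles
  junk <- setNames(paste(rep("A", 40), collapse = ""), "d2")
  asg2 <- classify_competitive(junk, ps, evalue_cutoff = 1e-8, db_size = 10)
  expect_equal(asg2$family, "unclassified")
})

test_that("exact tie goes to the lexicographically smallest family, margin 0", {
  p1 <- toy_calibrated_profile(len = 20, seed = 3, name = "zeta")
  p2 <- p1
  p2$name <- "alpha"
  dom <- setNames(sample_from_profile(p1, seed = 9), "d1")
  asg <- classify_competitive(dom, list(p1, p2), evalue_cutoff = 10,
                              db_size = 1)
  expect_equal(asg$family, "alpha")
  expect_equal(asg$margin, 0)
})

test_that("duplicate profile names are a configuration error", {
  p <- toy_calibrated_profile(seed = 1, name = "same")
  expect_error(classify_competitive(setNames("ACD", "x"), list(p, p)),
               "duplicate")
})

test_that("classification is invariant to domain and profile ordering", {
  ps <- make_two_profiles()
  doms <- setNames(
    c(sample_from_profile(ps[[1]], seed = 11), sample_from_profile(ps[[2]], seed = 12),
      sample_from_profile(ps[[1]], seed = 13)),
    c("a", "b", "c"))
  a1 <- classify_competitive(doms, ps, db_size = 3)
  a2 <- classify_competitive(doms[c(3, 1, 2)], rev(ps), db_size = 3)
  a2 <- a2[match(a1$seq_id, a2$seq_id), ]
  expect_equal(a1$family, a2$family)
  expect_equal(a1$best_bit_score, a2$best_bit_score)
})

test_that("synthetic families are recovered by competitive classification", {
  # default (stated-world) profile lengths and divergence; counts scaled down
  sim <- make_family_db(n_families = 4, n_per_family = 8, n_decoys = 0,
                        seed = 31)
  profiles <- lapply(seq_along(sim$profiles), function(i)
    calibrate(smooth_profile(sim$profiles[[i]]), n_samples = 200,
              sample_len = 350, seed = 900 + i))
  doms <- setNames(sim$db$seq, sim$db$seq_id)
  asg <- classify_competitive(doms, profiles, evalue_cutoff = 0.01,
                              db_size = length(doms))
  truth <- sim$truth$family[match(asg$seq_id, sim$truth$seq_id)]
  expect_gte(mean(asg$family == truth), 0.9)
})

test_that("taxon profile: hand count, fixed row order, totals conserved", {
  asg <- data.frame(seq_id = c("s1", "s2", "s3", "s4", "s5"),
                    family = c("UXS", "UXS", "UGE", "unclassified", "UGE"),
                    best_bit_score = c(50, 40, 30, NA, 20),
                    margin = c(1, 1, 1, NA, 1),
                    sink = FALSE, stringsAsFactors = FALSE)
  taxmap <- c(s1 = "Bacteria", s2 = "Bacteria", s3 = "Fungi")
  tp <- build_taxon_profile(asg, taxmap)
  expect_equal(rownames(tp$counts), TAXON_GROUPS)
  expect_equal(unname(tp$counts["Bacteria", "UXS"]), 2L)
  expect_equal(unname(tp$counts["Fungi", "UGE"]), 1L)
  expect_equal(sum(tp$counts), 3L)
  expect_equal(tp$unclassified, 1L)
  expect_equal(sum(tp$unknown_taxon), 1L) # s5 has no taxon mapping
  expect_equal(sum(tp$counts) + tp$unclassified + sum(tp$unknown_taxon) +
                 sum(tp$sink), tp$n_input)
  # empty input gives an all-zero matrix
  tp0 <- build_taxon_profile(asg[0, ], taxmap, families = c("UXS", "UGE"))
  expect_true(all(tp0$counts == 0L))
})

test_that("sink families are excluded from the matrix but tracked", {
  asg <- data.frame(seq_id = c("s1", "s2"),
                    family = c("cladeB", "UXS"),
                    best_bit_score = c(10, 20), margin = c(1, 1),
                    sink = c(TRUE, FALSE), stringsAsFactors = FALSE)
  tp <- build_taxon_profile(asg, c(s1 = "Bacteria", s2 = "Bacteria"))
  expect_false("cladeB" %in% colnames(tp$counts))
  expect_equal(unname(tp$sink["cladeB"]), 1L)
  expect_equal(sum(tp$counts) + sum(tp$sink), 2L)
})

test_that("taxonomy TSV reader validates the vocabulary", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("seq_id\tgroup", "s1\tBacteria", "s2\tunknown"), f)
  tm <- read_taxonomy_tsv(f)
  expect_equal(unname(tm["s1"]), "Bacteria")
  writeLines(c("seq_id\tgroup", "s1\tPlantae"), f)
  expect_error(read_taxonomy_tsv(f), "unknown taxon group")
})
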