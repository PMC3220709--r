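test_that("generators are pure functions of the seed", {
  p1 <- make_random_profile(20, seed = 7)
  p2 <- make_random_profile(20, seed = 7)
  expect_identical(p1$match_emissions, p2$match_emissions)
  expect_identical(sample_from_profile(p1, seed = 3, n = 5),
                   sample_from_profile(p2, seed = 3, n = 5))
  s1 <- make_family_db(n_families = 2, n_per_family = 3, n_decoys = 2,
                       len_range = c(30, 40), seed = 9)
  s2 <- make_family_db(n_families = 2, n_per_family = 3, n_decoys = 2,
                       len_range = c(30, 40), seed = 9)
  expect_identical(s1$db$seq, s2$db$seq)
  expect_identical(s1$truth, s2$truth)
  g1 <- make_genomes(n_genomes = 4, genome_size = 30, seed = 5)
  g2 <- make_genomes(n_genomes = 4, genome_size = 30, seed = 5)
  expect_identical(g1$tables, g2$tables)
  expect_identical(g1$truth, g2$truth)
})

test_that("different seeds give different profiles (consensus differs)", {
  diffs <- vapply(1:20, function(s) {
    a <- make_random_profile(30, seed = s)$consensus
    b <- make_random_profile(30, seed = s + 1000)$consensus
    a != b
  }, logical(1))
  expect_true(all(diffs))
})

test_that("low concentration approaches point-mass columns", {
  mean_max <- vapply(c(0.001, 0.05, 1), function(cc)
    mean(apply(make_random_profile(40, concentration = cc,
                                   seed = 3)$match_emissions, 1, max)),
    numeric(1))
  expect_gt(mean_max[1], 0.95)          # near point mass in the limit
  expect_true(all(diff(mean_max) < 0))  # flatter as concentration grows
})

test_that("degenerate generator: no indels reproduces the consensus", {
  p <- make_random_profile(15, concentration = 0.001, seed = 11)
  # point-mass emissions and forced M->M transitions
  p$match_emissions <- t(vapply(seq_len(p$M), function(k) {
    e <- rep(0, 20)
    e[which.max(p$match_emissions[k, ])] <- 1
    e
  }, numeric(20)))
  colnames(p$match_emissions) <- AA_ALPHABET
  p$transitions[-p$M, "MM"] <- 1
  p$transitions[-p$M, "MI"] <- 0
  p$transitions[-p$M, "MD"] <- 0
  p$entry <- c(BM = 1, BD = 0)
  p$consensus <- paste(AA_ALPHABET[apply(p$match_emissions, 1, which.max)],
                       collapse = "")
  expect_error(validate_profile(p), NA)
  expect_identical(sample_from_profile(p, seed = 1), p$consensus)
})

test_that("per-column emission frequencies obey the law of large numbers", {
  p <- make_random_profile(4, concentration = 0.3, seed = 13)
  p$transitions[-p$M, "MM"] <- 1
  p$transitions[-p$M, "MI"] <- 0
  p$transitions[-p$M, "MD"] <- 0
  p$entry <- c(BM = 1, BD = 0)
  draws <- sample_from_profile(p, seed = 2, n = 10000)
  chars <- do.call(rbind, strsplit(draws, ""))
  for (k in seq_len(p$M)) {
    freq <- table(factor(chars[, k], levels = AA_ALPHABET)) / nrow(chars)
    expect_true(all(abs(as.numeric(freq) - p$match_emissions[k, ]) < 0.02))
  }
})

test_that("mutate_sequence applies the expected substitution load", {
  p <- make_random_profile(200, seed = 17)
  s <- sample_from_profile(p, seed = 1)
  m <- nsephylo:::mutate_sequence(s, 0.15, seed = 2)
  expect_equal(nchar(m), nchar(s))
  frac <- mean(strsplit(s, "")[[1]] != strsplit(m, "")[[1]])
  expect_gt(frac, 0.05)
  expect_lt(frac, 0.30)
  expect_identical(nsephylo:::mutate_sequence(s, 0, seed = 2), s)
})

test_that("fusions concatenate N + linker + C with exact truth coordinates", {
  np <- make_random_profile(30, seed = 21, name = "n")
  cp <- make_random_profile(25, seed = 22, name = "c")
  fus <- make_fusions(np, cp, linker_len = 0, n = 3, seed = 4)
  expect_equal(nrow(fus$truth), 3L)
  for (i in 1:3)
    expect_equal(fus$truth$c_start[i], fus$truth$n_end[i] + 1L)
  fus10 <- make_fusions(np, cp, linker_len = 10, n = 2, seed = 4)
  expect_equal(fus10$truth$c_start, fus10$truth$n_end + 11L)
  expect_equal(nchar(fus10$db$seq[1]),
               fus10$truth$n_end[1] + 10L +
                 (nchar(fus10$db$seq[1]) - fus10$truth$c_start[1] + 1L))
})

test_that("family db truth is sufficient to locate every planted domain", {
  sim <- make_family_db(n_families = 3, n_per_family = 4, n_decoys = 5,
                        len_range = c(30, 40), seed = 27)
  expect_equal(nrow(sim$truth), 3 * 4 + 5)
  planted <- sim$truth[sim$truth$family != "decoy", ]
  for (i in seq_len(nrow(planted))) {
    sq <- sim$db$seq[sim$db$seq_id == planted$seq_id[i]]
    expect_true(planted$domain_end[i] <= nchar(sq))
    expect_gte(planted$domain_start[i], 1L)
  }
  expect_equal(sum(sim$truth$family == "decoy"), 5L)
})

test_that("make_genomes plants within the stated span and validates input", {
  sim <- make_genomes(n_genomes = 6, genome_size = 40, planted_fraction = 1.0,
                      planted_span = 4, seed = 8)
  expect_true(all(sim$truth$planted))
  for (tb in sim$tables) {
    pos <- tb$ordinal[!is.na(tb$label)]
    expect_lte(max(pos) - min(pos) + 1L, 4L)
    expect_gte(length(unique(tb$label[!is.na(tb$label)])), 2L)
  }
  expect_error(make_genomes(n_genomes = 2, genome_size = 5, planted_span = 9),
               "exceeds genome size")
})
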