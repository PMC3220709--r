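test_that("p and Poisson distances match closed forms", {
  m <- msa(c("a", "b", "c"), c("AAAA", "AAAT", "AAAA"))
  D <- distance_matrix(m, "p")
  expect_equal(unname(D["a", "b"]), 0.25)
  expect_equal(unname(D["a", "c"]), 0)
  P <- distance_matrix(m, "poisson")
  expect_equal(unname(P["a", "b"]), -log(0.75), tolerance = 1e-12)
  expect_true(isSymmetric(D))
  expect_equal(unname(diag(D)), rep(0, 3))
  # gaps: only mutually non-gap columns count
  m2 <- msa(c("a", "b", "c"), c("AA--", "A-T-", "AAAA"))
  expect_equal(unname(distance_matrix(m2)["a", "b"]), 0) # only column 1 shared
  m3 <- msa(c("a", "b", "c"), c("A-", "-A", "AA"))
  expect_error(distance_matrix(m3), "no non-gap columns")
  # saturated pair is capped with a warning under the Poisson correction
  m4 <- msa(c("a", "b", "c"), c("AAAA", "CCCC", "AACC"))
  expect_warning(P4 <- distance_matrix(m4, "poisson"), "capped")
  expect_equal(unname(P4["a", "b"]), -log(1e-3), tolerance = 1e-9)
})

test_that("three-taxon NJ uses the closed-form branch lengths", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  el <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(el["A"]), (3 + 4 - 5) / 2)
  expect_equal(unname(el["B"]), (3 + 5 - 4) / 2)
  expect_equal(unname(el["C"]), (4 + 5 - 3) / 2)
})

test_that("additive 4-taxon matrix: AB|CD topology with internal branch 2", {
  labs <- c("A", "B", "C", "D")
  D <- matrix(4, 4, 4, dimnames = list(labs, labs))
  D[1, 2] <- D[2, 1] <- 2
  D[3, 4] <- D[4, 3] <- 2
  diag(D) <- 0
  tr <- nj_tree(D)
  # brute-force oracle over the 3 unrooted quartet topologies: pick the one
  # whose induced split has zero least-squares residual
  splits <- list(c("A", "B"), c("A", "C"), c("A", "D"))
  resid <- vapply(splits, function(s) {
    # four-point condition residual for split {s} | rest
    o <- setdiff(labs, s)
    abs((D[s[1], o[1]] + D[s[2], o[2]]) - (D[s[1], o[2]] + D[s[2], o[1]]))
  }, numeric(1))
  best <- splits[[which.min(resid)]]
  expect_equal(best, c("A", "B"))
  bip <- oracle_bipartitions(tr)
  expect_true(any(vapply(bip, function(b)
    identical(b, c("A", "B")) || identical(b, c("C", "D")), logical(1))))
  # internal branch length: total tree length = 2*1 + 2*1 + ... reconstruct
  internal <- tr$edge.length[tr$edge[, 2] > length(tr$tip.label)]
  expect_equal(sort(internal, decreasing = TRUE)[1], 2, tolerance = 1e-9)
  # path lengths reproduce the additive matrix
  pd <- ape::cophenetic.phylo(tr)[labs, labs]
  expect_equal(unname(pd), unname(D), tolerance = 1e-9)
})

test_that("NJ recovers random additive trees (consistency) and matches ape::nj", {
  skip_if_not_installed("phangorn")
  set.seed(17)
  for (rep in 1:15) {
    n <- sample(4:8, 1)
    true <- ape::rtree(n, br = function(k) runif(k, 0.3, 1.5))
    true$node.label <- NULL
    D <- ape::cophenetic.phylo(true)
    D <- D[sort(rownames(D)), sort(rownames(D))]
    mine <- nj_tree(D)
    expect_equal(phangorn::RF.dist(ape::unroot(true), mine), 0)
    # dual route: agrees with ape's independent NJ implementation
    expect_equal(phangorn::RF.dist(ape::nj(as.dist(D)), mine), 0)
    # additivity: path lengths reproduce the input matrix
    pd <- ape::cophenetic.phylo(mine)[rownames(D), rownames(D)]
    expect_equal(unname(pd), unname(D), tolerance = 1e-9)
  }
})

test_that("nj_tree input contracts and negative-branch clamping", {
  D <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(D), ">= 3")
  D3 <- matrix(c(0, 1, 2, 1.5, 0, 1, 2, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(D3), "not symmetric")
  # violating the triangle inequality forces a negative estimate
  D4 <- matrix(c(0, 10, 1, 10, 0, 1, 1, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_warning(tr <- nj_tree(D4), "clamped")
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap: planted central split is strongly supported", {
  m <- two_block_msa()
  tr <- bootstrap_supports(m, B = 100, seed = 3)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(sup[!is.na(sup)] >= 0 & sup[!is.na(sup)] <= 100))
  sc <- extract_subclade(tr, c("a1", "a2", "a3", "a4"), min_support = 70)
  expect_setequal(sc$leaves, c("a1", "a2", "a3", "a4"))
  expect_gte(sc$support, 95)
  expect_false(sc$low_support)
})

test_that("B = 0 gives a tree without supports; B < 0 errors", {
  m <- two_block_msa()
  tr <- bootstrap_supports(m, B = 0, seed = 1)
  expect_null(tr$node.label)
  expect_error(bootstrap_supports(m, B = -1), ">= 0")
})

test_that("bootstrap supports are invariant to row permutation", {
  m <- two_block_msa()
  s1 <- extract_subclade(bootstrap_supports(m, B = 50, seed = 5),
                         c("b1", "b2", "b3", "b4"))$support
  perm <- c(5, 2, 8, 1, 4, 7, 3, 6)
  m2 <- msa(m$ids[perm], m$rows[perm])
  s2 <- extract_subclade(bootstrap_supports(m2, B = 50, seed = 5),
                         c("b1", "b2", "b3", "b4"))$support
  expect_equal(s1, s2)
})

test_that("subclade extraction on the worked Newick example", {
  tr <- ape::read.tree(text = "((A:1,B:1)90:1,(C:1,D:1)60:1,E:1);")
  sc <- extract_subclade(tr, c("A", "B"), min_support = 70)
  expect_setequal(sc$leaves, c("A", "B"))
  expect_equal(sc$support, 90)
  expect_false(sc$low_support)
  sc2 <- extract_subclade(tr, c("C", "D"), min_support = 70)
  expect_equal(sc2$support, 60)
  expect_true(sc2$low_support)
  # seeds = all leaves -> full leaf set
  sc3 <- extract_subclade(tr, c("A", "B", "C", "D", "E"))
  expect_setequal(sc3$leaves, tr$tip.label)
  # seeds spanning the root of every rooting
  sc4 <- extract_subclade(tr, c("A", "C", "E"))
  expect_setequal(sc4$leaves, tr$tip.label)
  expect_match(sc4$note, "span the root")
  expect_error(extract_subclade(tr, c("A", "Z")), "unknown seed")
})

test_that("subclade extraction agrees with brute-force bipartitions", {
  set.seed(23)
  for (rep in 1:8) {
    n <- sample(5:12, 1)
    tr <- ape::rtree(n)
    tr <- ape::unroot(tr)
    bip <- oracle_bipartitions(tr)
    tips <- tr$tip.label
    seeds <- sample(tips, sample(2:3, 1))
    # oracle: smallest side over all bipartitions (and their complements)
    # containing the seeds
    sides <- c(bip, lapply(bip, function(b) sort(setdiff(tips, b))),
               list(sort(tips)))
    ok <- Filter(function(s) all(seeds %in% s), sides)
    best <- ok[[which.min(lengths(ok))]]
    sc <- extract_subclade(tr, seeds)
    expect_equal(sort(sc$leaves), best)
  }
})

test_that("Newick round-trip preserves topology and supports", {
  m <- two_block_msa()
  tr <- bootstrap_supports(m, B = 20, seed = 9)
  f <- tempfile(fileext = ".nwk")
  write_newick(tr, f)
  tr2 <- read_newick(f)
  expect_setequal(tr2$tip.label, tr$tip.label)
  sc1 <- extract_subclade(tr, c("a1", "a2", "a3", "a4"))
  sc2 <- extract_subclade(tr2, c("a1", "a2", "a3", "a4"))
  expect_equal(sc1$support, sc2$support)
})
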