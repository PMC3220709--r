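mk_table <- function(labels_at, size = 20, genome = "g1", contig = "c1") {
  lab <- rep(NA_character_, size)
  for (nm in names(labels_at)) lab[labels_at[[nm]]] <- nm
  gene_table(genome, contig, seq_len(size), sprintf("%s_g%03d", genome,
                                                    seq_len(size)),
             "+", lab)
}

test_that("adjacent distinct labels give one call of span 2", {
  tb <- mk_table(list(B = 5, C = 6))
  calls <- synteny_scan(tb)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$span, 2L)
  expect_equal(calls$n_distinct, 2L)
})

test_that("window boundary: span 7 calls, span 8 does not", {
  hit <- synteny_scan(mk_table(list(B = 3, C = 9)))   # span 7
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$span, 7L)
  miss <- synteny_scan(mk_table(list(B = 3, C = 10))) # span 8
  expect_equal(nrow(miss), 0L)
})

test_that("two copies of the same label do not qualify", {
  lab <- rep(NA_character_, 20)
  lab[c(4, 6)] <- "B"
  tb <- gene_table("g1", "c1", 1:20, sprintf("g%02d", 1:20), "+", lab)
  expect_equal(nrow(synteny_scan(tb)), 0L)
})

test_that("calls never cross contig boundaries", {
  df <- rbind(
    data.frame(genome_id = "g1", contig = "c1", ordinal = 1:5,
               gene_id = sprintf("a%d", 1:5), strand = "+",
               label = c(NA, NA, NA, "B", NA), stringsAsFactors = FALSE),
    data.frame(genome_id = "g1", contig = "c2", ordinal = 1:5,
               gene_id = sprintf("b%d", 1:5), strand = "+",
               label = c("C", NA, NA, NA, NA), stringsAsFactors = FALSE))
  class(df) <- c("gene_table", "data.frame")
  expect_equal(nrow(synteny_scan(df)), 0L)
})

test_that("unsorted gene tables are rejected", {
  df <- data.frame(genome_id = "g1", contig = "c1", ordinal = c(1, 3, 2),
                   gene_id = c("a", "b", "c"), strand = "+",
                   label = c("B", "C", NA), stringsAsFactors = FALSE)
  expect_error(synteny_scan(df), "not sorted")
  expect_error(gene_table("g1", "c1", c(1, 3, 2), c("a", "b", "c")),
               "not sorted")
})

test_that("shrinking the window never creates a call", {
  sim <- make_genomes(n_genomes = 10, genome_size = 60, planted_fraction = 0.5,
                      planted_span = 5, seed = 3)
  for (tb in sim$tables) {
    wide <- synteny_scan(tb, window_span = 9)
    narrow <- synteny_scan(tb, window_span = 5)
    # every narrow call lies inside some wide call
    if (nrow(narrow)) {
      expect_gt(nrow(wide), 0L)
      for (i in seq_len(nrow(narrow)))
        expect_true(any(wide$start <= narrow$start[i] &
                          wide$end >= narrow$end[i]))
    }
  }
})

test_that("maximal non-nested windows are reported", {
  # B..C..B: the full span qualifies and nests the sub-windows
  tb <- mk_table(list(B = 4, C = 6), size = 10)
  tb$label[8] <- "B"
  calls <- synteny_scan(tb)
  expect_equal(nrow(calls), 1L)
  expect_equal(c(calls$start, calls$end), c(4L, 8L))
})

test_that("planted clusters are always recovered at window >= planted span", {
  for (seed in 1:5) {
    sim <- make_genomes(n_genomes = 8, genome_size = 80, planted_fraction = 0.5,
                        planted_span = 5, seed = seed)
    gf <- genome_fraction(sim$tables, window_span = 7, min_distinct = 2)
    planted <- sim$truth$genome_id[sim$truth$planted]
    expect_true(all(gf$per_genome[planted]))
  }
})

test_that("genome_fraction counts genomes with at least one call", {
  t1 <- mk_table(list(B = 2, C = 3), genome = "g1")
  t2 <- mk_table(list(B = 2, C = 15), genome = "g2")  # too far apart
  t3 <- mk_table(list(B = 9, C = 11), genome = "g3")
  gf <- genome_fraction(list(t1, t2, t3))
  expect_equal(gf$n_with_call, 2L)
  expect_equal(gf$n_total, 3L)
  expect_equal(gf$fraction, 2 / 3)
  expect_error(genome_fraction(list()), "empty")
})

test_that("gene-table TSV round-trip", {
  tb <- mk_table(list(B = 3, C = 5), size = 8)
  f <- tempfile(fileext = ".tsv")
  nsephylo:::write_tsv(tb, f)
  tb2 <- read_gene_table_tsv(f)
  expect_equal(tb2$ordinal, tb$ordinal)
  expect_equal(tb2$label, tb$label)
  expect_equal(nrow(synteny_scan(tb2)), 1L)
})

test_that("GFF3 gene tables order genes by start within contig", {
  skip_if_not_installed("rtracklayer")
  f <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "c1\tsrc\tgene\t100\t200\t.\t+\t.\tID=gene1;family=dehydratase_46",
    "c1\tsrc\tgene\t500\t600\t.\t-\t.\tID=gene2",
    "c1\tsrc\tgene\t300\t400\t.\t+\t.\tID=gene3;family=epimerase_35"), f)
  tb <- read_gene_table_gff3(f, genome_id = "g1")
  expect_equal(tb$gene_id, c("gene1", "gene3", "gene2"))
  expect_equal(tb$ordinal, 1:3)
  expect_equal(tb$label, c("dehydratase_46", "epimerase_35", NA))
  expect_equal(nrow(synteny_scan(tb)), 1L)
})
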