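# Alignment with two clearly divergent 4-sequence blocks: the central split
# is the planted signal for bootstrap-support checks.
two_block_msa <- function() {
  b1 <- "ACDEFGHIKLMNPQRSTVWY"
  b2 <- "YWVTSRQPNMLKIHGFEDCA"
  jitter <- function(s, pos, ch) {
    substr(s, pos, pos) <- ch
    s
  }
  msa(c("a1", "a2", "a3", "a4", "b1", "b2", "b3", "b4"),
      c(b1, jitter(b1, 3, "W"), jitter(b1, 7, "A"), jitter(b1, 11, "C"),
        b2, jitter(b2, 4, "K"), jitter(b2, 9, "M"), jitter(b2, 15, "V")))
}

# Builds a complete, deterministic pipeline fixture (FASTA database, serialized
# calibrated profiles, taxonomy, alignment, gene tables, flat config) in `dir`.
# Everything is generated in code; nothing is stored in the repository.
build_pipeline_fixture <- function(dir, seed = 101L, bootstrap_B = 25L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- make_family_db(n_families = 3, n_per_family = 4,
                        len_range = c(40, 60), n_decoys = 4, seed = seed)
  profiles <- lapply(seq_along(sim$profiles), function(i)
    calibrate(smooth_profile(sim$profiles[[i]]), n_samples = 150,
              sample_len = 100, seed = seed + i))
  np <- calibrate(make_random_profile(45, seed = seed + 50, name = "rhm_n"),
                  n_samples = 150, sample_len = 100, seed = seed + 51)
  cp <- calibrate(make_random_profile(45, seed = seed + 60, name = "nrs_er"),
                  n_samples = 150, sample_len = 100, seed = seed + 61)
  fus <- make_fusions(np, cp, linker_len = 8, n = 2, seed = seed + 70)

  db <- sequence_db(c(sim$db$seq_id, fus$db$seq_id),
                    c(sim$db$seq, fus$db$seq))
  write_fasta(db, file.path(dir, "db.fasta"))

  prof_paths <- vapply(profiles, function(p) {
    f <- file.path(dir, paste0(p$name, ".hmm"))
    write_profile(p, f)
    basename(f)
  }, character(1))
  write_profile(np, file.path(dir, "rhm_n.hmm"))
  write_profile(cp, file.path(dir, "nrs_er.hmm"))

  tax <- data.frame(seq_id = db$seq_id,
                    group = rep(c("Viridiplantae", "Bacteria", "Fungi"),
                                length.out = nrow(db)),
                    stringsAsFactors = FALSE)
  nsephylo:::write_tsv(tax, file.path(dir, "taxonomy.tsv"))

  b1 <- "ACDEFGHIKLMNPQRSTVWY"
  b2 <- "YWVTSRQPNMLKIHGFEDCA"
  sub1 <- function(s, i, ch) { substr(s, i, i) <- ch; s }
  m <- msa(c("a1", "a2", "a3", "a4", "o1", "o2", "o3", "o4"),
           c(b1, sub1(b1, 3, "W"), sub1(b1, 7, "A"), sub1(b1, 11, "C"),
             b2, sub1(b2, 4, "K"), sub1(b2, 9, "M"), sub1(b2, 15, "V")))
  write_msa_fasta(m, file.path(dir, "phylo.fasta"))

  genomes <- make_genomes(n_genomes = 4, genome_size = 40,
                          planted_fraction = 0.5, planted_span = 4,
                          seed = seed + 90)
  gt_paths <- vapply(seq_along(genomes$tables), function(i) {
    f <- file.path(dir, sprintf("genome%02d.tsv", i))
    nsephylo:::write_tsv(genomes$tables[[i]], f)
    basename(f)
  }, character(1))

  cfg <- c(
    "# nsephylo pipeline fixture config",
    "db_fasta: db.fasta",
    paste0("harvest_profile: ", prof_paths[1]),
    paste0("family_profiles: ", paste(prof_paths, collapse = ",")),
    "n_profile: rhm_n.hmm",
    "c_profile: nrs_er.hmm",
    "taxonomy_tsv: taxonomy.tsv",
    "msa_fasta: phylo.fasta",
    paste0("gene_tables: ", paste(gt_paths, collapse = ",")),
    "subclade_seeds: a1,a2,a3,a4",
    "evalue_cutoff: 0.01",
    "min_support: 70",
    "window_span: 7",
    "min_distinct: 2",
    paste0("bootstrap_B: ", bootstrap_B),
    "seed: 11")
  cfg_path <- file.path(dir, "config.txt")
  writeLines(cfg, cfg_path)
  cfg_path
}
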