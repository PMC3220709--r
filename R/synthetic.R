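# Ground-truth-labeled synthetic data: profile-emitted protein families with
# tunable divergence, residue-shuffled decoys, bi-domain fusion proteins, and
# genomes with planted co-clustered gene labels. Every generator is a pure
# function of its arguments and seed (bit-identical reruns).
#
# Default world (chosen once, see the methods vignette): profile length
# 80-120, Dirichlet concentration 0.2 (strongly conserved columns),
# divergence 0.15 substitutions per residue, flanks 20-80 background
# residues, 10-residue linkers.

#' Draw a random profile HMM
#'
#' Match emissions are drawn per column from a symmetric Dirichlet with the
#' given concentration (small values give near-point-mass columns); the
#' remaining model structure (transitions, background, insert emissions) uses
#' the package defaults.
#'
#' @param length Number of match states (>= 1).
#' @param concentration Positive Dirichlet concentration (default 0.2).
#' @param seed Integer seed.
#' @param name Family label (default `"random"`).
#' @return A `profile_hmm`.
#' @export
make_random_profile <- function(length, concentration = 0.2, seed = 1L,
                                name = "random") {
  seed <- as.numeric(seed)
  if (!is.numeric(length) || length < 1L)
    stop("length must be >= 1", call. = FALSE)
  if (!is.numeric(concentration) || concentration <= 0)
    stop("concentration must be positive", call. = FALSE)
  M <- as.integer(length)
  em <- with_seed(seed, {
    g <- matrix(rgamma(M * 20, shape = concentration), M, 20)
    g / rowSums(g)
  })
  colnames(em) <- AA_ALPHABET
  bg <- rep(1 / 20, 20)
  prof <- structure(list(
    name = as.character(name), M = M, match_emissions = em,
    insert_emissions = bg, transitions = profile_transition_matrix(M),
    entry = DEFAULT_ENTRY, background = bg,
    gap_threshold = 0.5, pseudocount_weight = 0,
    match_columns = seq_len(M),
    consensus = paste(AA_ALPHABET[apply(em, 1, which.max)], collapse = ""),
    calibration = NULL), class = "profile_hmm")
  validate_profile(prof)
  prof
}

#' Sample sequences generatively from a profile HMM
#'
#' Traverses the model's states from entry to exit, emitting match residues
#' from the column distributions and insert residues from the insert
#' distribution; delete states skip columns.
#'
#' @param prof A `profile_hmm`.
#' @param seed Integer seed.
#' @param n Number of sequences (default 1).
#' @return Character vector of residue strings (zero-length emissions are
#'   impossible while entry and transition constants keep match states
#'   reachable; an all-delete traversal returns an empty string).
#' @export
sample_from_profile <- function(prof, seed = 1L, n = 1L) {
  validate_profile(prof)
  with_seed(seed, {
    vapply(seq_len(n), function(i) sample_one(prof), character(1))
  })
}

sample_one <- function(prof) {
  tr <- prof$transitions
  out <- integer(0)
  M <- prof$M
  # entry
  state <- if (runif(1) < prof$entry[["BM"]]) "M" else "D"
  k <- 1L
  repeat {
    if (state == "M")
      out <- c(out, sample.int(20, 1, prob = prof$match_emissions[k, ]))
    if (k == M) break
    if (state == "M") {
      r <- runif(1)
      if (r < tr[k, "MM"]) {
        state <- "M"
      } else if (r < tr[k, "MM"] + tr[k, "MI"]) {
        # insert loop, then move on to the next match state
        repeat {
          out <- c(out, sample.int(20, 1, prob = prof$insert_emissions))
          if (runif(1) < tr[k, "IM"]) break
        }
        state <- "M"
      } else {
        state <- "D"
      }
    } else { # D
      state <- if (runif(1) < tr[k, "DM"]) "M" else "D"
    }
    k <- k + 1L
  }
  idx_to_seq(out)
}

# i.i.d. point substitutions: each residue replaced, with probability `rate`,
# by a uniform draw over the other 19 residues
mutate_sequence <- function(seq, rate, seed) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(seq)
  with_seed(seed, {
    idx <- seq_to_idx(seq)
    hit <- runif(length(idx)) < rate
    if (any(hit)) {
      repl <- vapply(idx[hit], function(a)
        sample(setdiff(seq_len(20), a), 1L), integer(1))
      idx[hit] <- repl
    }
    idx_to_seq(idx)
  })
}

# composition-preserving, signal-destroying decoy
shuffle_sequence <- function(seq, seed) {
  with_seed(seed, {
    idx <- seq_to_idx(seq)
    idx_to_seq(sample(idx))
  })
}

random_background_seq <- function(len, background = rep(1 / 20, 20)) {
  if (len == 0L) return("")
  idx_to_seq(sample.int(20, len, replace = TRUE, prob = background))
}

#' Simulate a labeled multi-family protein database
#'
#' Emits `n_per_family` domain sequences from each of `n_families` random
#' profiles, applies i.i.d. point substitutions at the divergence rate,
#' embeds each domain in random background flanks, and adds residue-shuffled
#' decoys (composition preserved, signal destroyed).
#'
#' @param n_families Number of families (default 13).
#' @param n_per_family Sequences per family (default 50).
#' @param len_range Profile length range, inclusive (default `c(80, 120)`).
#' @param divergence Substitution rate per residue in [0, 1] (default 0.15).
#' @param flank_range Flank length range per side (default `c(20, 80)`).
#' @param n_decoys Number of decoy sequences (default 200).
#' @param concentration Dirichlet concentration for the profiles (default 0.2).
#' @param seed Integer seed.
#' @return List: `db` (a [sequence_db()]), `profiles` (list of generating
#'   `profile_hmm`s named `fam01`, ...), `truth` (data frame `seq_id`,
#'   `family` (`"decoy"` for decoys), `domain_start`, `domain_end`).
#' @export
make_family_db <- function(n_families = 13L, n_per_family = 50L,
                           len_range = c(80L, 120L), divergence = 0.15,
                           flank_range = c(20L, 80L), n_decoys = 200L,
                           concentration = 0.2, seed = 1L) {
  seed <- as.numeric(seed)
  fam_names <- sprintf("fam%02d", seq_len(n_families))
  profiles <- lapply(seq_len(n_families), function(f)
    make_random_profile(
      length = with_seed(seed * 1000L + f, sample(len_range[1]:len_range[2], 1L)),
      concentration = concentration, seed = seed * 1000L + f,
      name = fam_names[f]))
  names(profiles) <- fam_names

  ids <- character(); seqs <- character()
  truth <- data.frame(seq_id = character(), family = character(),
                      domain_start = integer(), domain_end = integer(),
                      stringsAsFactors = FALSE)
  counter <- 0L
  for (f in seq_len(n_families)) {
    doms <- sample_from_profile(profiles[[f]], seed = seed * 2000L + f,
                                n = n_per_family)
    for (i in seq_len(n_per_family)) {
      counter <- counter + 1L
      sub_seed <- seed * 100000L + counter
      dom <- mutate_sequence(doms[i], divergence, sub_seed)
      fl <- with_seed(sub_seed + 1L, {
        lens <- sample(flank_range[1]:flank_range[2], 2L, replace = TRUE)
        c(random_background_seq(lens[1]), random_background_seq(lens[2]))
      })
      id <- sprintf("%s_seq%03d", fam_names[f], i)
      ids <- c(ids, id)
      seqs <- c(seqs, paste0(fl[1], dom, fl[2]))
      truth <- rbind(truth, data.frame(
        seq_id = id, family = fam_names[f],
        domain_start = nchar(fl[1]) + 1L,
        domain_end = nchar(fl[1]) + nchar(dom),
        stringsAsFactors = FALSE))
    }
  }
  if (n_decoys > 0L) {
    for (d in seq_len(n_decoys)) {
      src <- ids[with_seed(seed * 3000L + d, sample.int(length(ids), 1L))]
      dec <- shuffle_sequence(seqs[match(src, ids)], seed * 3000L + d)
      id <- sprintf("decoy%03d", d)
      ids <- c(ids, id)
      seqs <- c(seqs, dec)
      truth <- rbind(truth, data.frame(
        seq_id = id, family = "decoy",
        domain_start = NA_integer_, domain_end = NA_integer_,
        stringsAsFactors = FALSE))
    }
  }
  list(db = sequence_db(ids, seqs, source_name = "synthetic_families"),
       profiles = profiles, truth = truth)
}

#' Simulate bi-domain fusion proteins
#'
#' Each sequence is an N-profile sample, a uniform-random linker of
#' `linker_len` residues, then a C-profile sample.
#'
#' @param n_profile,c_profile Generating `profile_hmm`s.
#' @param linker_len Linker length in residues (default 10).
#' @param n Number of fusions (>= 1).
#' @param seed Integer seed.
#' @param divergence Optional substitution rate applied to the domain parts
#'   (default 0).
#' @return List: `db` (a [sequence_db()]), `truth` (data frame `seq_id`,
#'   `n_end`, `c_start` giving the 1-based domain boundaries).
#' @export
make_fusions <- function(n_profile, c_profile, linker_len = 10L, n = 1L,
                         seed = 1L, divergence = 0) {
  seed <- as.numeric(seed)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (linker_len < 0L) stop("linker_len must be >= 0", call. = FALSE)
  ids <- sprintf("fusion%03d", seq_len(n))
  nparts <- sample_from_profile(n_profile, seed = seed * 10L + 1L, n = n)
  cparts <- sample_from_profile(c_profile, seed = seed * 10L + 2L, n = n)
  seqs <- character(n)
  truth <- data.frame(seq_id = ids, n_end = NA_integer_,
                      c_start = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    np <- mutate_sequence(nparts[i], divergence, seed * 50L + 2L * i)
    cp <- mutate_sequence(cparts[i], divergence, seed * 50L + 2L * i + 1L)
    linker <- with_seed(seed * 70L + i, random_background_seq(linker_len))
    seqs[i] <- paste0(np, linker, cp)
    truth$n_end[i] <- nchar(np)
    truth$c_start[i] <- nchar(np) + linker_len + 1L
  }
  list(db = sequence_db(ids, seqs, source_name = "synthetic_fusions"),
       truth = truth)
}

#' Simulate genomes with planted gene-label clusters
#'
#' Each genome is a single contig of `genome_size` unlabeled filler genes.
#' In a planted genome, 2-3 labeled genes (distinct labels from `labels`)
#' are placed within a random window of `planted_span` consecutive genes;
#' in a non-planted genome the same number of labeled genes is placed at
#' independent uniform positions.
#'
#' @param n_genomes Number of genomes (default 20).
#' @param genome_size Genes per genome (default 100).
#' @param planted_fraction Fraction of genomes that receive a planted
#'   cluster (default 0.5).
#' @param planted_span Window size for planted clusters (>= 2, <=
#'   `genome_size`; default 5).
#' @param labels Label vocabulary (default the three rhamnose-pathway
#'   activities).
#' @param seed Integer seed.
#' @return List: `tables` (list of [gene_table()]s), `truth` (data frame
#'   `genome_id`, `planted`).
#' @export
make_genomes <- function(n_genomes = 20L, genome_size = 100L,
                         planted_fraction = 0.5, planted_span = 5L,
                         labels = c("dehydratase_46", "epimerase_35",
                                    "reductase_4"),
                         seed = 1L) {
  seed <- as.numeric(seed)
  if (planted_span > genome_size)
    stop("planted_span exceeds genome size", call. = FALSE)
  if (planted_span < 2L) stop("planted_span must be >= 2", call. = FALSE)
  n_planted <- round(n_genomes * planted_fraction)
  tables <- vector("list", n_genomes)
  truth <- data.frame(genome_id = sprintf("genome%03d", seq_len(n_genomes)),
                      planted = seq_len(n_genomes) <= n_planted,
                      stringsAsFactors = FALSE)
  for (g in seq_len(n_genomes)) {
    tables[[g]] <- with_seed(seed * 500L + g, {
      k <- sample(2:min(3L, length(labels)), 1L)
      labs <- sample(labels, k)
      lab_col <- rep(NA_character_, genome_size)
      if (truth$planted[g]) {
        anchor <- sample.int(genome_size - planted_span + 1L, 1L)
        pos <- sort(sample(anchor:(anchor + planted_span - 1L), k))
      } else {
        pos <- sort(sample.int(genome_size, k))
      }
      lab_col[pos] <- labs
      gene_table(truth$genome_id[g], contig = "c1",
                 ordinal = seq_len(genome_size),
                 gene_id = sprintf("%s_g%04d", truth$genome_id[g],
                                   seq_len(genome_size)),
                 strand = "+", label = lab_col)
    })
  }
  list(tables = tables, truth = truth)
}
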