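# Glocal Viterbi and Forward scoring. Scores are log2-odds (bits) against a
# background null model; the dynamic programming (natural-log accumulation)
# lives in src/glocal.cpp. "Glocal" means the alignment is global with
# respect to the model -- all M columns are traversed through match or delete
# states -- and local with respect to the target sequence: any contiguous
# subsequence may be consumed, and flanking residues are free under the null.

LN2 <- log(2)

# Precompute everything sequence-independent once per profile; returns
# forward/viterbi closures. Used internally by all scanning loops so that
# validation and log tables are not recomputed per sequence.
make_scorer <- function(prof) {
  validate_profile(prof)
  lodds <- log(prof$match_emissions) -
    matrix(log(prof$background), nrow = prof$M, ncol = 20, byrow = TRUE)
  tr <- log(prof$transitions)
  ltMM <- tr[, "MM"]; ltMI <- tr[, "MI"]; ltMD <- tr[, "MD"]
  ltIM <- tr[, "IM"]; ltII <- tr[, "II"]
  ltDM <- tr[, "DM"]; ltDD <- tr[, "DD"]
  lbm <- log(prof$entry[["BM"]]); lbd <- log(prof$entry[["BD"]])
  to_idx <- function(seq) {
    if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
      stop("sequence must be a non-empty residue string", call. = FALSE)
    seq_to_idx(seq)
  }
  list(
    forward = function(seq) {
      mlo <- lodds[, to_idx(seq), drop = FALSE]
      .cpp_glocal_forward(mlo, ltMM, ltMI, ltMD, ltIM, ltII, ltDM, ltDD,
                          lbm, lbd) / LN2
    },
    viterbi = function(seq) {
      mlo <- lodds[, to_idx(seq), drop = FALSE]
      res <- .cpp_glocal_viterbi(mlo, ltMM, ltMI, ltMD, ltIM, ltII,
                                 ltDM, ltDD, lbm, lbd)
      list(bit_score = res$score_nats / LN2, start = res$start,
           end = res$end)
    })
}

#' Viterbi score and envelope of a sequence against a profile
#'
#' Finds the highest-probability glocal alignment: the model is traversed
#' from column 1 to M while consuming a contiguous subsequence of `seq`.
#' The returned envelope is the consumed span (1-based, inclusive).
#'
#' @param prof A `profile_hmm`.
#' @param seq Non-empty residue string over the 20-letter alphabet.
#' @return A list with `bit_score` (log2-odds against the background null)
#'   and `start`, `end` (envelope coordinates).
#' @export
score_viterbi <- function(prof, seq) {
  make_scorer(prof)$viterbi(seq)
}

#' Forward score of a sequence against a profile
#'
#' Sums probability over all glocal alignments (instead of taking the best
#' one, as [score_viterbi()] does); this is the score used for E-values and
#' competitive classification.
#'
#' @inheritParams score_viterbi
#' @return Bit score (log2-odds, numeric scalar).
#' @export
score_forward <- function(prof, seq) {
  make_scorer(prof)$forward(seq)
}
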