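# Profile HMM construction. The model is a simplified Plan7-like glocal
# architecture: every path traverses all M columns through match or delete
# states, consumes a contiguous subsequence of the target, and flanking
# residues are free under the null model. Insert emissions equal the
# background, and insert/delete transition probabilities are fixed constants
# (below), so the only free parameters estimated from the alignment are the
# match-column emission distributions.

# Fixed transition constants (probabilities). Documented in the serialization
# header; chosen once as conventional Plan7-like magnitudes.
DEFAULT_TRANSITIONS <- c(MM = 0.90, MI = 0.05, MD = 0.05,
                         IM = 0.50, II = 0.50,
                         DM = 0.80, DD = 0.20)
DEFAULT_ENTRY <- c(BM = 0.95, BD = 0.05)

#' Henikoff position-based sequence weights
#'
#' Computes the 1994 position-based weights: in each column, a row holding
#' residue `a` receives `1 / (r * s)` where `r` is the number of distinct
#' (non-gap) residues in the column and `s` the count of `a`; gap rows
#' receive nothing from that column. Raw weights are the per-row sums over
#' all columns.
#'
#' @param m An [msa()] object.
#' @param normalize If `TRUE` (default) weights are scaled to mean 1; if
#'   `FALSE` the raw column-sum weights are returned.
#' @return Numeric vector of weights, one per alignment row.
#' @examples
#' henikoff_weights(msa(c("a","b","c"), c("AA","AA","AT")), normalize = FALSE)
#' # 7/12, 7/12, 5/6
#' @export
henikoff_weights <- function(m, normalize = TRUE) {
  stopifnot(inherits(m, "nse_msa"))
  cm <- msa_matrix(m)
  w <- numeric(m$n)
  for (j in seq_len(m$width)) {
    col <- cm[, j]
    res <- col[col != "-"]
    if (!length(res)) next
    tab <- table(res)
    r <- length(tab)
    contrib <- ifelse(col == "-", 0, 1 / (r * as.numeric(tab[col])))
    contrib[is.na(contrib)] <- 0
    w <- w + contrib
  }
  if (normalize) {
    if (sum(w) == 0) w <- rep(1, m$n) else w <- w * m$n / sum(w)
  }
  w
}

#' Build a profile HMM from a multiple sequence alignment
#'
#' Match columns are those whose gap fraction is strictly below
#' `gap_threshold` (columns exactly at the threshold become insert columns).
#' Match emissions are Henikoff-weighted residue counts blended with
#' background-proportional pseudocounts of total weight `pseudocount_weight`
#' per column. Insert emissions are fixed to the background, and all
#' transition probabilities are fixed constants (see the serialized header).
#'
#' @param m An [msa()] object with at least 2 rows.
#' @param name Family label for the model.
#' @param gap_threshold Match-column gap-fraction threshold in (0, 1];
#'   default 0.5.
#' @param pseudocount_weight Total pseudocount weight added per column
#'   (default 1.0); 0 gives unsmoothed point-mass columns.
#' @param background Length-20 residue frequency vector over [AA_ALPHABET]
#'   (default uniform 1/20).
#' @return An object of class `profile_hmm` with fields `name`, `M`,
#'   `match_emissions` (M x 20), `insert_emissions`, `transitions` (M x 7,
#'   columns MM, MI, MD, IM, II, DM, DD; row M holds the exit convention
#'   MM = DM = 1), `entry` (B->M1, B->D1), `background`, `match_columns`,
#'   `consensus`, and `calibration` (`NULL` until [calibrate()]).
#' @export
build_profile <- function(m, name = "profile",
                          gap_threshold = 0.5,
                          pseudocount_weight = 1.0,
                          background = NULL) {
  stopifnot(inherits(m, "nse_msa"))
  if (m$n < 2L) stop("model building requires at least 2 aligned sequences",
                     call. = FALSE)
  if (!is.numeric(gap_threshold) || gap_threshold <= 0 || gap_threshold > 1)
    stop("gap_threshold must be in (0, 1]", call. = FALSE)
  if (!is.numeric(pseudocount_weight) || pseudocount_weight < 0)
    stop("pseudocount_weight must be non-negative", call. = FALSE)
  background <- background %||% rep(1 / 20, 20)
  check_prob_vec(background, 20, "background")

  cm <- msa_matrix(m)
  gap_frac <- colMeans(cm == "-")
  match_cols <- which(gap_frac < gap_threshold)
  if (!length(match_cols))
    stop("no column qualifies as a match column at gap_threshold ",
         gap_threshold, call. = FALSE)

  w <- henikoff_weights(m, normalize = TRUE)
  M <- length(match_cols)
  em <- matrix(0, M, 20, dimnames = list(NULL, AA_ALPHABET))
  for (k in seq_len(M)) {
    col <- cm[, match_cols[k]]
    for (i in seq_len(m$n)) {
      if (col[i] == "-") next
      a <- match(col[i], AA_ALPHABET)
      em[k, a] <- em[k, a] + w[i]
    }
    tot <- sum(em[k, ])
    em[k, ] <- (em[k, ] + pseudocount_weight * background) /
      (tot + pseudocount_weight)
    if (pseudocount_weight == 0 && tot == 0)
      stop(sprintf("match column %d is all-gap and pseudocount_weight is 0", k),
           call. = FALSE)
  }

  prof <- structure(list(
    name = as.character(name),
    M = M,
    match_emissions = em,
    insert_emissions = background,
    transitions = profile_transition_matrix(M),
    entry = DEFAULT_ENTRY,
    background = background,
    gap_threshold = gap_threshold,
    pseudocount_weight = pseudocount_weight,
    match_columns = match_cols,
    consensus = paste(AA_ALPHABET[apply(em, 1, which.max)], collapse = ""),
    calibration = NULL
  ), class = "profile_hmm")
  validate_profile(prof)
  prof
}

# M x 7 transition matrix with the fixed constants; row M encodes exit
# (M_M -> E and D_M -> E with probability 1).
profile_transition_matrix <- function(M) {
  tr <- matrix(rep(DEFAULT_TRANSITIONS, each = M), nrow = M,
               dimnames = list(NULL, names(DEFAULT_TRANSITIONS)))
  tr[M, ] <- c(1, 0, 0, 1, 0, 1, 0)
  tr
}

#' Blend a profile's match emissions with background pseudocounts
#'
#' Applies the same background-proportional smoothing rule as
#' [build_profile()] to an existing emission table: each column is treated
#' as `effective_n` observations and blended with `pseudocount_weight`
#' pseudo-observations of the background,
#' `e' = (effective_n * e + pseudocount_weight * bg) / (effective_n +
#' pseudocount_weight)`. Profiles used as scoring models should always be
#' smoothed: an unsmoothed (e.g. simulation-truth) profile can contain
#' near-zero emissions whose log-odds penalties are unboundedly harsh, which
#' no alignment-built model exhibits.
#'
#' @param prof A `profile_hmm`.
#' @param effective_n Pseudo-depth of the emission estimate (default 10,
#'   a typical seed-alignment depth).
#' @param pseudocount_weight Total background pseudocount weight per column
#'   (default 1.0, as in [build_profile()]).
#' @return The profile with smoothed match emissions (calibration cleared,
#'   since scores change).
#' @export
smooth_profile <- function(prof, effective_n = 10, pseudocount_weight = 1.0) {
  validate_profile(prof)
  stopifnot(effective_n > 0, pseudocount_weight >= 0)
  bg <- matrix(prof$background, prof$M, 20, byrow = TRUE)
  prof$match_emissions <- (effective_n * prof$match_emissions +
                             pseudocount_weight * bg) /
    (effective_n + pseudocount_weight)
  colnames(prof$match_emissions) <- AA_ALPHABET
  prof$pseudocount_weight <- pseudocount_weight
  prof$calibration <- NULL
  prof
}

#' Validate a profile HMM object
#'
#' Checks the structural invariants: emission rows and outgoing transition
#' distributions sum to 1 within 1e-9, all probabilities are non-negative,
#' and `M >= 1`.
#'
#' @param prof A `profile_hmm` object.
#' @return The profile, invisibly; errors on violation.
#' @export
validate_profile <- function(prof) {
  if (!inherits(prof, "profile_hmm")) stop("not a profile_hmm", call. = FALSE)
  if (!is.numeric(prof$M) || prof$M < 1) stop("M must be >= 1", call. = FALSE)
  if (nrow(prof$match_emissions) != prof$M)
    stop("match_emissions must have M rows", call. = FALSE)
  for (k in seq_len(prof$M))
    check_prob_vec(prof$match_emissions[k, ], 20,
                   sprintf("match emissions, column %d", k))
  check_prob_vec(prof$insert_emissions, 20, "insert emissions")
  check_prob_vec(prof$background, 20, "background")
  check_prob_vec(prof$entry, 2, "entry distribution")
  tr <- prof$transitions
  for (k in seq_len(prof$M)) {
    check_prob_vec(tr[k, c("MM", "MI", "MD")], 3,
                   sprintf("M-state transitions, column %d", k))
    check_prob_vec(tr[k, c("IM", "II")], 2,
                   sprintf("I-state transitions, column %d", k))
    check_prob_vec(tr[k, c("DM", "DD")], 2,
                   sprintf("D-state transitions, column %d", k))
  }
  invisible(prof)
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("profile_hmm '%s': M = %d match states\n", x$name, x$M))
  cat(sprintf("  consensus: %s\n",
              if (x$M > 60) paste0(substr(x$consensus, 1, 60), "...")
              else x$consensus))
  if (is.null(x$calibration)) {
    cat("  calibration: none\n")
  } else {
    cat(sprintf("  calibration: Gumbel mu = %.3f bits, lambda = %.4f (n = %d, len = %d)\n",
                x$calibration$mu, x$calibration$lam,
                x$calibration$n_samples, x$calibration$sample_len))
  }
  invisible(x)
}

is_calibrated <- function(prof) !is.null(prof$calibration)
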