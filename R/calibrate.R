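# E-value calibration: Forward bit scores of i.i.d. background-sampled random
# sequences are fitted with a maximum-likelihood Gumbel (type-I extreme value)
# distribution; E-values are the fitted tail probability scaled by the
# database size.

#' Maximum-likelihood Gumbel fit
#'
#' Fits location `mu` and rate `lam` (= 1/scale) of a Gumbel distribution
#' for maxima, `P(X > s) = 1 - exp(-exp(-lam * (s - mu)))`, by maximum
#' likelihood (profile likelihood in the scale parameter solved with
#' [stats::uniroot()]).
#'
#' @param x Numeric vector of scores (length >= 2, non-degenerate).
#' @return List with `mu` and `lam`.
#' @export
gumbel_fit <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 2L || !all(is.finite(x)))
    stop("need >= 2 finite scores to fit a Gumbel", call. = FALSE)
  s <- sd(x)
  if (s == 0)
    stop("degenerate score distribution (all scores equal); cannot calibrate",
         call. = FALSE)
  xbar <- mean(x)
  # MLE estimating equation for the scale beta:
  #   beta = xbar - sum(x * exp(-x/beta)) / sum(exp(-x/beta))
  g <- function(beta) {
    z <- exp(-(x - min(x)) / beta) # shift for numerical stability
    beta - xbar + sum(x * z) / sum(z)
  }
  lo <- s * 0.01
  hi <- s * 100
  beta <- uniroot(g, c(lo, hi), tol = 1e-10, extendInt = "yes")$root
  mu <- -beta * log(mean(exp(-(x - min(x)) / beta))) + min(x)
  list(mu = mu, lam = 1 / beta)
}

# Upper-tail probability of the fitted Gumbel, computed with expm1 so that
# very high scores keep full relative precision.
gumbel_tail <- function(s, mu, lam) {
  -expm1(-exp(-lam * (s - mu)))
}

#' Calibrate a profile HMM for E-value computation
#'
#' Scores `n_samples` random sequences of length `sample_len`, drawn i.i.d.
#' from the profile's background distribution, with [score_forward()], and
#' fits a Gumbel distribution to the resulting bit scores. Deterministic for
#' a fixed seed.
#'
#' @param prof A `profile_hmm`.
#' @param n_samples Number of random sequences (>= 100; default 1000).
#' @param sample_len Length of each random sequence (default 350).
#' @param seed Integer seed for the random-sequence generator.
#' @return The profile with its `calibration` field set to a
#'   `calibration_params` list (`mu`, `lam`, `n_samples`, `sample_len`,
#'   `seed`).
#' @export
calibrate <- function(prof, n_samples = 1000L, sample_len = 350L, seed = 1L) {
  validate_profile(prof)
  if (n_samples < 100L) stop("n_samples must be >= 100", call. = FALSE)
  if (sample_len < 1L) stop("sample_len must be >= 1", call. = FALSE)
  scores <- calibration_scores(prof, n_samples, sample_len, seed)
  fit <- gumbel_fit(scores)
  prof$calibration <- structure(
    list(mu = fit$mu, lam = fit$lam, n_samples = as.integer(n_samples),
         sample_len = as.integer(sample_len), seed = as.integer(seed)),
    class = "calibration_params")
  prof
}

# Forward bit scores of the calibration sample (also used by coverage tests).
calibration_scores <- function(prof, n_samples, sample_len, seed) {
  scorer <- make_scorer(prof)
  with_seed(seed, {
    vapply(seq_len(n_samples), function(i) {
      s <- idx_to_seq(sample.int(20, sample_len, replace = TRUE,
                                 prob = prof$background))
      scorer$forward(s)
    }, numeric(1))
  })
}

#' E-value of a bit score under a profile's Gumbel calibration
#'
#' `E = db_size * P(S > bit_score)` under the fitted Gumbel: strictly
#' decreasing in the score and linear in the database size.
#'
#' @param bit_score Numeric bit score(s).
#' @param calib A `calibration_params` object (a profile's `calibration`
#'   field).
#' @param db_size Positive integer: number of sequences in the searched
#'   database.
#' @return Non-negative E-value(s), same length as `bit_score`.
#' @export
evalue <- function(bit_score, calib, db_size) {
  if (is.null(calib)) stop("profile is not calibrated", call. = FALSE)
  if (!is.numeric(db_size) || length(db_size) != 1L || db_size <= 0)
    stop("db_size must be a positive integer", call. = FALSE)
  db_size * gumbel_tail(bit_score, calib$mu, calib$lam)
}
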