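# Domain-architecture calls: a protein hit by both an N-terminal-domain
# profile (4,6-dehydratase-like) and a C-terminal-domain profile
# (3,5-epimerase-4-reductase-like), with non-overlapping envelopes in N-then-C
# order, is a bi-domain fusion; single hits give N-only / C-only.

ARCH_LABELS <- c("N-only", "C-only", "bi-domain", "none")

# best hit of one profile on one sequence (Forward bits + Viterbi envelope),
# or NULL if the E-value misses the cutoff
best_hit <- function(seq_id, seq, prof, evalue_cutoff, db_size) {
  fwd <- score_forward(prof, seq)
  ev <- evalue(fwd, prof$calibration, db_size)
  if (ev >= evalue_cutoff) return(NULL)
  vit <- score_viterbi(prof, seq)
  data.frame(seq_id = seq_id, profile = prof$name,
             start = vit$start, end = vit$end,
             bit_score = fwd, e_value = ev, stringsAsFactors = FALSE)
}

#' Classify one protein as single-domain, bi-domain, or neither
#'
#' Both profiles are scored independently at the E-value cutoff. If both
#' pass, the envelope overlap fraction (intersection length over the shorter
#' envelope) is compared with `max_overlap_frac`: non-overlapping envelopes
#' with the N envelope starting before the C envelope give `bi-domain`;
#' overlap beyond the threshold, or C-before-N order, resolves to the
#' higher-scoring profile's single-domain label with an explanatory `note`.
#' One passing profile gives `N-only`/`C-only`; none gives `none`.
#'
#' @param seq_id Sequence identifier.
#' @param seq Residue string.
#' @param n_profile Calibrated profile for the N-terminal domain.
#' @param c_profile Calibrated profile for the C-terminal domain (name must
#'   differ from `n_profile`).
#' @param evalue_cutoff Positive cutoff (default 0.01).
#' @param db_size Database size for E-values.
#' @param max_overlap_frac Maximum tolerated envelope overlap fraction
#'   (default 0.2).
#' @return One-row data frame: `seq_id`, `label`, `n_start`, `n_end`,
#'   `n_bit`, `n_evalue`, `c_start`, `c_end`, `c_bit`, `c_evalue`, `note`.
#' @export
detect_architecture <- function(seq_id, seq, n_profile, c_profile,
                                evalue_cutoff = 0.01, db_size = 1L,
                                max_overlap_frac = 0.2) {
  if (identical(n_profile$name, c_profile$name))
    stop("N and C profiles must have distinct names", call. = FALSE)
  for (p in list(n_profile, c_profile))
    if (!is_calibrated(p))
      stop("profile '", p$name, "' is not calibrated", call. = FALSE)
  nh <- best_hit(seq_id, seq, n_profile, evalue_cutoff, db_size)
  ch <- best_hit(seq_id, seq, c_profile, evalue_cutoff, db_size)
  label <- "none"; note <- ""
  if (!is.null(nh) && !is.null(ch)) {
    inter <- max(0L, min(nh$end, ch$end) - max(nh$start, ch$start) + 1L)
    shorter <- min(nh$end - nh$start + 1L, ch$end - ch$start + 1L)
    ovl <- inter / shorter
    if (ovl > max_overlap_frac) {
      label <- if (nh$bit_score >= ch$bit_score) "N-only" else "C-only"
      note <- sprintf("overlap fraction %.2f > %.2f; resolved to higher-scoring domain",
                      ovl, max_overlap_frac)
    } else if (nh$start < ch$start) {
      label <- "bi-domain"
    } else {
      label <- if (nh$bit_score >= ch$bit_score) "N-only" else "C-only"
      note <- "both-unordered: C envelope precedes N envelope"
    }
  } else if (!is.null(nh)) {
    label <- "N-only"
  } else if (!is.null(ch)) {
    label <- "C-only"
  }
  data.frame(seq_id = seq_id, label = label,
             n_start = if (is.null(nh)) NA_integer_ else nh$start,
             n_end = if (is.null(nh)) NA_integer_ else nh$end,
             n_bit = if (is.null(nh)) NA_real_ else nh$bit_score,
             n_evalue = if (is.null(nh)) NA_real_ else nh$e_value,
             c_start = if (is.null(ch)) NA_integer_ else ch$start,
             c_end = if (is.null(ch)) NA_integer_ else ch$end,
             c_bit = if (is.null(ch)) NA_real_ else ch$bit_score,
             c_evalue = if (is.null(ch)) NA_real_ else ch$e_value,
             note = note, stringsAsFactors = FALSE)
}

#' Architecture calls for every sequence of a database
#'
#' @param db A [sequence_db()].
#' @inheritParams detect_architecture
#' @param db_size Database size for E-values; defaults to `nrow(db)`.
#' @return Data frame of calls (one row per sequence), class
#'   `architecture_calls`.
#' @export
detect_architectures <- function(db, n_profile, c_profile,
                                 evalue_cutoff = 0.01, db_size = NULL,
                                 max_overlap_frac = 0.2) {
  stopifnot(inherits(db, "sequence_db"))
  db_size <- db_size %||% nrow(db)
  out <- do.call(rbind, lapply(seq_len(nrow(db)), function(i)
    detect_architecture(db$seq_id[i], db$seq[i], n_profile, c_profile,
                        evalue_cutoff, db_size, max_overlap_frac)))
  class(out) <- c("architecture_calls", "data.frame")
  out
}

#' Contingency table of architecture labels by taxon group
#'
#' @param calls Data frame of architecture calls.
#' @param taxmap Named character vector seq_id -> taxon group; unmapped
#'   sequences count as `"unknown"`.
#' @return Integer matrix, rows = labels (`N-only`, `C-only`, `bi-domain`,
#'   `none`), columns = taxon groups present (fixed order then `"unknown"`);
#'   cell sum equals `nrow(calls)`.
#' @export
summarize_architectures <- function(calls, taxmap = character()) {
  stopifnot(is.data.frame(calls))
  groups <- c(TAXON_GROUPS, "unknown")
  tab <- matrix(0L, length(ARCH_LABELS), length(groups),
                dimnames = list(ARCH_LABELS, groups))
  for (i in seq_len(nrow(calls))) {
    g <- unname(taxmap[calls$seq_id[i]])
    if (is.na(g) || is.null(g)) g <- "unknown"
    tab[calls$label[i], g] <- tab[calls$label[i], g] + 1L
  }
  tab
}
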