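# Domain harvesting: scan a protein database with one calibrated profile and
# keep the trimmed Viterbi envelopes of all sequences passing the E-value
# cutoff (strict inequality).

#' Construct a protein sequence database
#'
#' @param seq_id Unique sequence identifiers.
#' @param seq Non-empty residue strings.
#' @param desc Optional descriptions (default empty).
#' @param source_name Label for the database (default "db").
#' @return A data frame of class `sequence_db` with columns `seq_id`,
#'   `desc`, `seq`.
#' @export
sequence_db <- function(seq_id, seq, desc = "", source_name = "db") {
  seq_id <- as.character(seq_id)
  seq <- toupper(as.character(seq))
  if (anyDuplicated(seq_id)) stop("seq_ids must be unique", call. = FALSE)
  if (any(!nzchar(seq))) stop("sequences must be non-empty", call. = FALSE)
  db <- data.frame(seq_id = seq_id, desc = rep_len(as.character(desc),
                                                   length(seq_id)),
                   seq = seq, stringsAsFactors = FALSE)
  attr(db, "source_name") <- source_name
  class(db) <- c("sequence_db", "data.frame")
  db
}

#' Read a protein FASTA file into a sequence database
#'
#' @param path FASTA file path.
#' @param source_name Database label (default: the file name).
#' @return A [sequence_db()].
#' @export
read_fasta_db <- function(path, source_name = basename(path)) {
  aa <- Biostrings::readAAStringSet(path)
  full <- names(aa)
  ids <- sub("\\s.*$", "", full)
  desc <- sub("^\\S+\\s*", "", full)
  sequence_db(ids, as.character(aa), desc, source_name)
}

#' Write a sequence database (or any named sequences) as FASTA
#'
#' @param x A [sequence_db()] or a named character vector of sequences.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (inherits(x, "sequence_db")) {
    ids <- x$seq_id
    seqs <- x$seq
  } else {
    ids <- names(x)
    seqs <- as.character(x)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(ids)) {
    writeLines(paste0(">", ids[i]), con)
    writeLines(seqs[i], con)
  }
  invisible(path)
}

#' Extract the envelope substring of a domain hit
#'
#' @param seq Residue string.
#' @param hit A list or one-row data frame with 1-based inclusive `start`
#'   and `end` fields.
#' @return The substring `seq[start..end]`.
#' @export
trim_envelope <- function(seq, hit) {
  start <- as.integer(hit$start)
  end <- as.integer(hit$end)
  if (is.na(start) || is.na(end) || start < 1L || end < start ||
      end > nchar(seq))
    stop(sprintf("envelope (%s, %s) out of bounds for sequence of length %d",
                 hit$start, hit$end, nchar(seq)), call. = FALSE)
  substr(seq, start, end)
}

#' Harvest significant domain envelopes from a database
#'
#' Scores every sequence with [score_forward()] (the score the E-value is
#' computed from) and takes the envelope of the best glocal alignment from
#' [score_viterbi()]. One best envelope is reported per sequence; hits are
#' retained when `e_value < evalue_cutoff` (strict), and the retained domain
#' strings are the envelope substrings.
#'
#' @param db A [sequence_db()].
#' @param prof A calibrated `profile_hmm`.
#' @param evalue_cutoff Positive E-value cutoff (default 0.01).
#' @param db_size Database size used for E-values; defaults to `nrow(db)`.
#' @return A list of class `harvest_result`: `hits` (data frame with columns
#'   `seq_id`, `profile`, `start`, `end`, `bit_score`, `e_value`, ordered by
#'   `seq_id` then `start`), `domains` (named character vector of trimmed
#'   envelope strings), `cutoff`, `db_size`.
#' @export
harvest_domains <- function(db, prof, evalue_cutoff = 0.01, db_size = NULL) {
  stopifnot(inherits(db, "sequence_db"))
  if (!is_calibrated(prof))
    stop("profile must be calibrated before harvesting (see calibrate())",
         call. = FALSE)
  if (!is.numeric(evalue_cutoff) || evalue_cutoff <= 0)
    stop("evalue_cutoff must be positive", call. = FALSE)
  db_size <- db_size %||% nrow(db)
  hits <- data.frame(seq_id = character(), profile = character(),
                     start = integer(), end = integer(),
                     bit_score = numeric(), e_value = numeric(),
                     stringsAsFactors = FALSE)
  domains <- character()
  scorer <- make_scorer(prof)
  if (nrow(db)) {
    for (i in seq_len(nrow(db))) {
      fwd <- scorer$forward(db$seq[i])
      ev <- evalue(fwd, prof$calibration, db_size)
      if (ev < evalue_cutoff) {
        vit <- scorer$viterbi(db$seq[i])
        hits <- rbind(hits, data.frame(
          seq_id = db$seq_id[i], profile = prof$name,
          start = vit$start, end = vit$end,
          bit_score = fwd, e_value = ev, stringsAsFactors = FALSE))
        domains[db$seq_id[i]] <- trim_envelope(db$seq[i], vit)
      }
    }
    ord <- order(hits$seq_id, hits$start)
    hits <- hits[ord, , drop = FALSE]
    rownames(hits) <- NULL
    domains <- domains[hits$seq_id]
  }
  structure(list(hits = hits, domains = domains,
                 cutoff = evalue_cutoff, db_size = db_size),
            class = "harvest_result")
}

#' @export
print.harvest_result <- function(x, ...) {
  cat(sprintf("harvest_result: %d hits at E < %g (db_size = %d)\n",
              nrow(x$hits), x$cutoff, x$db_size))
  if (nrow(x$hits)) print(head(x$hits, 10L))
  invisible(x)
}

#' Write a hits table as TSV
#'
#' Columns: seq_id, profile, start, end, bit_score, e_value.
#'
#' @param hits Data frame of hits (e.g. `harvest_result$hits`).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_hits_tsv <- function(hits, path) {
  write_tsv(hits[, c("seq_id", "profile", "start", "end",
                     "bit_score", "e_value")], path)
}
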