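# Competitive family classification: each domain sequence is Forward-scored
# against every family profile; among profiles passing the E-value cutoff the
# highest bit score wins ("more similar to the corresponding model than to
# the others"). Aggregation produces a family-by-taxon count matrix.

#' Fixed taxon-group vocabulary (row order of the count matrix)
#' @format Character vector of length 6.
#' @export
TAXON_GROUPS <- c("Viridiplantae", "Fungi", "Metazoa", "Other eukaryotes",
                  "Archaea", "Bacteria")

#' Competitively classify domains into families
#'
#' For each domain, every profile is Forward-scored; profiles are eligible
#' when their E-value (at `db_size`) is strictly below `evalue_cutoff`.
#' The eligible profile with the highest bit score is assigned; exact score
#' ties go to the lexicographically smallest family name with margin 0. A
#' domain with no eligible profile is `"unclassified"`.
#'
#' @param domains Named character vector of residue strings (names are
#'   seq_ids), or a data frame with columns `seq_id` and `seq`.
#' @param profiles List of calibrated `profile_hmm` objects with unique
#'   names. A profile may carry `sink = TRUE` to mark it as an absorbing
#'   family whose assignments are reported but excluded from count matrices.
#' @param evalue_cutoff Positive eligibility cutoff (default 0.01).
#' @param db_size Database size for E-values; defaults to the number of
#'   domains.
#' @return Data frame of class `family_assignment` with columns `seq_id`,
#'   `family` (profile name or `"unclassified"`), `best_bit_score`, `margin`
#'   (best minus second-best eligible bit score; `NA` when fewer than two
#'   profiles pass), and `sink` (logical).
#' @export
classify_competitive <- function(domains, profiles, evalue_cutoff = 0.01,
                                 db_size = NULL) {
  if (is.data.frame(domains))
    domains <- setNames(domains$seq, domains$seq_id)
  if (is.null(names(domains)) || anyDuplicated(names(domains)))
    stop("domains must be uniquely named by seq_id", call. = FALSE)
  if (!length(profiles)) stop("need at least one profile", call. = FALSE)
  pnames <- vapply(profiles, function(p) p$name, character(1))
  if (anyDuplicated(pnames))
    stop("duplicate profile names: ",
         paste(unique(pnames[duplicated(pnames)]), collapse = ", "),
         call. = FALSE)
  for (p in profiles)
    if (!is_calibrated(p))
      stop("profile '", p$name, "' is not calibrated", call. = FALSE)
  sink_flag <- vapply(profiles, function(p) isTRUE(p$sink), logical(1))
  names(sink_flag) <- pnames
  db_size <- db_size %||% length(domains)
  scorers <- lapply(profiles, make_scorer)

  res <- lapply(seq_along(domains), function(i) {
    bits <- vapply(scorers, function(sc) sc$forward(domains[[i]]), numeric(1))
    evs <- vapply(seq_along(profiles), function(k)
      evalue(bits[k], profiles[[k]]$calibration, db_size), numeric(1))
    pass <- which(evs < evalue_cutoff)
    if (!length(pass)) {
      return(data.frame(seq_id = names(domains)[i], family = "unclassified",
                        best_bit_score = NA_real_, margin = NA_real_,
                        sink = FALSE, stringsAsFactors = FALSE))
    }
    best_bit <- max(bits[pass])
    winners <- pass[bits[pass] == best_bit]
    fam <- sort(pnames[winners])[1] # lexicographic tie-break
    margin <- if (length(pass) >= 2L) {
      if (length(winners) >= 2L) 0
      else best_bit - max(bits[setdiff(pass, winners)])
    } else NA_real_
    data.frame(seq_id = names(domains)[i], family = fam,
               best_bit_score = best_bit, margin = margin,
               sink = unname(sink_flag[fam]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  class(out) <- c("family_assignment", "data.frame")
  out
}

#' Read a taxonomy map (seq_id -> taxon group) from TSV
#'
#' The file must have two columns, `seq_id` and `group`; groups outside the
#' six-label vocabulary in [TAXON_GROUPS] raise an error (use `"unknown"`
#' for unmapped sequences, or simply omit them).
#'
#' @param path TSV path with a header line.
#' @return Named character vector: `names` are seq_ids, values are groups.
#' @export
read_taxonomy_tsv <- function(path) {
  df <- read_tsv(path)
  if (!all(c("seq_id", "group") %in% names(df)))
    stop("taxonomy TSV needs columns seq_id and group", call. = FALSE)
  bad <- setdiff(unique(df$group), c(TAXON_GROUPS, "unknown"))
  if (length(bad))
    stop("unknown taxon group(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  setNames(df$group, df$seq_id)
}

#' Aggregate family assignments into a taxon-by-family count matrix
#'
#' Rows follow the fixed order of [TAXON_GROUPS]. Assignments that are
#' `"unclassified"`, mapped to an unknown taxon, or assigned to a sink
#' family are tracked in separate marginals and excluded from the main
#' matrix; the matrix total plus marginals always equals the number of
#' input assignments.
#'
#' @param assignments A `family_assignment` data frame from
#'   [classify_competitive()].
#' @param taxmap Named character vector seq_id -> group (see
#'   [read_taxonomy_tsv()]); sequences absent from the map count as
#'   `"unknown"`.
#' @param families Optional character vector fixing the column set/order;
#'   defaults to the sorted non-sink families observed.
#' @return A list of class `taxon_profile`: `counts` (6 x F integer matrix),
#'   `unclassified` (count), `unknown_taxon` (per-family counts of classified
#'   sequences with unknown taxon), `sink` (counts per sink family),
#'   `n_input`.
#' @export
build_taxon_profile <- function(assignments, taxmap = character(),
                                families = NULL) {
  stopifnot(is.data.frame(assignments))
  grp <- function(id) {
    g <- unname(taxmap[id])
    if (is.na(g) || is.null(g)) "unknown" else g
  }
  main <- assignments[assignments$family != "unclassified" &
                        !assignments$sink, , drop = FALSE]
  families <- families %||% sort(unique(main$family))
  counts <- matrix(0L, length(TAXON_GROUPS), length(families),
                   dimnames = list(TAXON_GROUPS, families))
  unknown_taxon <- setNames(integer(length(families)), families)
  for (i in seq_len(nrow(main))) {
    g <- grp(main$seq_id[i])
    f <- main$family[i]
    if (!f %in% families) next
    if (g == "unknown") unknown_taxon[f] <- unknown_taxon[f] + 1L
    else counts[g, f] <- counts[g, f] + 1L
  }
  sink_tab <- table(assignments$family[assignments$sink])
  structure(list(counts = counts,
                 unclassified = sum(assignments$family == "unclassified"),
                 unknown_taxon = unknown_taxon,
                 sink = setNames(as.integer(sink_tab), names(sink_tab)),
                 n_input = nrow(assignments)),
            class = "taxon_profile")
}

#' @export
print.taxon_profile <- function(x, ...) {
  cat("taxon_profile: counts of classified sequences (taxon group x family)\n")
  print(x$counts)
  cat(sprintf("unclassified: %d; unknown taxon: %d; sink-family: %d; input: %d\n",
              x$unclassified, sum(x$unknown_taxon), sum(x$sink), x$n_input))
  invisible(x)
}

#' Write a taxon-by-family count matrix as TSV
#'
#' @param tp A `taxon_profile`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_taxon_profile_tsv <- function(tp, path) {
  df <- data.frame(group = rownames(tp$counts), tp$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
}
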