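# Multiple sequence alignments: a light container plus aligned-FASTA and
# Stockholm readers. Rows are equal-length strings over the 20 amino acids
# plus '-' (Stockholm '.' gaps are normalized to '-').

#' Construct a multiple sequence alignment object
#'
#' @param ids Character vector of unique sequence identifiers.
#' @param rows Character vector of aligned residue strings, all the same
#'   length, over the 20 amino acids plus the gap character `-`.
#' @return An object of class `nse_msa` with elements `ids`, `rows`,
#'   `n` (rows) and `width` (columns).
#' @examples
#' msa(c("a", "b"), c("AC-D", "ACED"))
#' @export
msa <- function(ids, rows) {
  ids <- as.character(ids)
  rows <- toupper(as.character(rows))
  rows <- gsub(".", "-", rows, fixed = TRUE)
  if (length(ids) != length(rows))
    stop("ids and rows must have equal length", call. = FALSE)
  if (length(rows) < 1L) stop("alignment needs at least one row", call. = FALSE)
  if (anyDuplicated(ids)) stop("sequence identifiers must be unique", call. = FALSE)
  w <- unique(nchar(rows))
  if (length(w) != 1L) stop("all alignment rows must have equal length", call. = FALSE)
  if (w == 0L) stop("alignment has zero columns", call. = FALSE)
  ok <- c(AA_ALPHABET, "-")
  for (i in seq_along(rows)) {
    chars <- strsplit(rows[i], "")[[1]]
    bad <- which(!chars %in% ok)
    if (length(bad))
      stop(sprintf("unknown residue '%s' in row '%s' column %d",
                   chars[bad[1]], ids[i], bad[1]), call. = FALSE)
  }
  structure(list(ids = ids, rows = rows, n = length(rows), width = w),
            class = "nse_msa")
}

#' @export
print.nse_msa <- function(x, ...) {
  cat(sprintf("nse_msa: %d sequences x %d columns\n", x$n, x$width))
  show <- head(seq_len(x$n), 6L)
  for (i in show)
    cat(sprintf("  %-15s %s\n", x$ids[i],
                if (x$width > 60) paste0(substr(x$rows[i], 1, 60), "...")
                else x$rows[i]))
  if (x$n > 6L) cat(sprintf("  ... and %d more\n", x$n - 6L))
  invisible(x)
}

# character matrix view (rows x columns)
msa_matrix <- function(m) {
  do.call(rbind, strsplit(m$rows, ""))
}

#' Read a multiple sequence alignment
#'
#' Reads aligned FASTA (via Biostrings) or Stockholm format. Format is
#' detected from the first non-blank line (`# STOCKHOLM` header versus `>`)
#' unless given explicitly.
#'
#' @param path File path.
#' @param format One of `"auto"`, `"fasta"`, `"stockholm"`.
#' @return An [msa()] object.
#' @export
read_msa <- function(path, format = c("auto", "fasta", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    first <- readLines(path, n = 50L, warn = FALSE)
    first <- first[nzchar(trimws(first))][1]
    format <- if (grepl("^# STOCKHOLM", first)) "stockholm" else "fasta"
  }
  if (format == "fasta") {
    aa <- Biostrings::readAAStringSet(path)
    ids <- sub("\\s.*$", "", names(aa))
    return(msa(ids, as.character(aa)))
  }
  read_stockholm(path)
}

# Minimal single-alignment Stockholm parser: sequence lines are
# "<name> <aligned seq>", possibly wrapped over interleaved blocks;
# '#=' annotation and '//' terminator lines are skipped.
read_stockholm <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^# STOCKHOLM", lines[1]))
    stop("not a Stockholm file (missing '# STOCKHOLM' header): ", path,
         call. = FALSE)
  seqs <- list()
  order <- character()
  for (ln in lines[-1]) {
    ln <- trimws(ln)
    if (!nzchar(ln) || startsWith(ln, "#") || ln == "//") next
    parts <- strsplit(ln, "\\s+")[[1]]
    if (length(parts) != 2L)
      stop("malformed Stockholm sequence line: ", ln, call. = FALSE)
    id <- parts[1]
    if (is.null(seqs[[id]])) {
      seqs[[id]] <- parts[2]
      order <- c(order, id)
    } else {
      seqs[[id]] <- paste0(seqs[[id]], parts[2])
    }
  }
  if (!length(seqs)) stop("no sequences in Stockholm file: ", path, call. = FALSE)
  msa(order, unlist(seqs[order], use.names = FALSE))
}

#' Write an alignment as aligned FASTA
#'
#' @param m An [msa()] object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_msa_fasta <- function(m, path) {
  stopifnot(inherits(m, "nse_msa"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(m$n)) {
    writeLines(paste0(">", m$ids[i]), con)
    writeLines(m$rows[i], con)
  }
  invisible(path)
}
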