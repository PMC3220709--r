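# Shared constants and small internal helpers.

#' The 20-letter amino-acid alphabet used throughout the package
#'
#' Residues are ordered alphabetically by one-letter code; all emission and
#' background vectors are indexed in this order.
#'
#' @format A character vector of length 20.
#' @export
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

GAP_CHARS <- c("-", ".")

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards so generators are pure functions of the seed.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  seed <- abs(as.numeric(seed)) %% 2147483647 # keep derived seeds in int range
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Split a residue string into an index vector over AA_ALPHABET.
# Unknown symbols raise an error naming the first offending position.
seq_to_idx <- function(seq, what = "sequence") {
  chars <- strsplit(toupper(seq), "")[[1]]
  idx <- match(chars, AA_ALPHABET)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("unknown residue '%s' at position %d of %s",
                 chars[bad], bad, what), call. = FALSE)
  }
  idx
}

idx_to_seq <- function(idx) paste(AA_ALPHABET[idx], collapse = "")

check_prob_vec <- function(p, n, what, tol = 1e-9) {
  if (length(p) != n || any(!is.finite(p)) || any(p < 0))
    stop(sprintf("%s must be %d non-negative finite numbers", what, n),
         call. = FALSE)
  if (abs(sum(p) - 1) > tol)
    stop(sprintf("%s must sum to 1 (got %.12f)", what, sum(p)), call. = FALSE)
  invisible(p)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
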