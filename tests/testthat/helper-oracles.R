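# Independent oracles used by the unit and acceptance tests. These must stay
# independent of the code paths they check: the path enumerator walks the
# model's state graph recursively, and the bipartition oracle works directly
# on the edge matrix.

# Exhaustive glocal path enumeration: every path enters the model at an
# emitting match state (possibly after a closed-form B->D..D chain), traverses
# all columns through match/delete states with optional inserts between
# consecutive matches, and exits from M_M or through trailing deletes.
# Returns Forward (log2 sum over paths) and Viterbi (log2 best path) scores.
oracle_scores <- function(prof, seq) {
  idx <- match(strsplit(seq, "")[[1]], AA_ALPHABET)
  stopifnot(!anyNA(idx))
  L <- length(idx)
  M <- prof$M
  tr <- log(prof$transitions)
  lbm <- log(prof$entry[["BM"]])
  lbd <- log(prof$entry[["BD"]])
  mlo <- log(prof$match_emissions) -
    matrix(log(prof$background), M, 20, byrow = TRUE)
  weights <- numeric(0)

  extend_match <- function(k, pos, lw) extend(k, pos, lw + mlo[k, idx[pos]])

  # called with the path sitting on match state k having just emitted `pos`
  extend <- function(k, pos, lw) {
    if (k == M) {
      weights <<- c(weights, lw + tr[M, "MM"]) # M_M -> E
      return(invisible())
    }
    # M_k -> M_{k+1}
    if (pos + 1 <= L) extend_match(k + 1, pos + 1, lw + tr[k, "MM"])
    # M_k -> I_k^m -> M_{k+1}, m >= 1 inserted background residues
    m <- 1
    while (pos + m + 1 <= L) {
      w <- lw + tr[k, "MI"] + (m - 1) * tr[k, "II"] + tr[k, "IM"]
      extend_match(k + 1, pos + m + 1, w)
      m <- m + 1
    }
    # M_k -> D_{k+1} -> ... (deletes, then a match or the exit)
    chain <- lw + tr[k, "MD"]
    kk <- k + 1
    repeat {
      if (kk == M) { # trailing deletes to D_M -> E
        weights <<- c(weights, chain + tr[M, "DM"])
        break
      }
      if (pos + 1 <= L)
        extend_match(kk + 1, pos + 1, chain + tr[kk, "DM"])
      chain <- chain + tr[kk, "DD"]
      kk <- kk + 1
    }
  }

  for (i in seq_len(L)) {
    for (k in seq_len(M)) {
      ent <- if (k == 1) lbm
      else lbd + (if (k > 2) sum(tr[seq_len(k - 2), "DD"]) else 0) +
        tr[k - 1, "DM"]
      extend_match(k, i, ent)
    }
  }
  mx <- max(weights)
  list(forward = (mx + log(sum(exp(weights - mx)))) / log(2),
       viterbi = mx / log(2))
}

# All non-trivial bipartitions of an unrooted tree, computed from the edge
# matrix by component search after deleting each internal edge.
oracle_bipartitions <- function(tree) {
  nt <- length(tree$tip.label)
  edges <- tree$edge
  out <- list()
  for (e in seq_len(nrow(edges))) {
    child <- edges[e, 2]
    if (child <= nt) next # pendant edge: trivial split
    # collect tips reachable from `child` without crossing edge e
    stack <- child
    tips <- integer(0)
    seen <- child
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      kids <- edges[edges[, 1] == v, 2]
      for (u in kids) {
        if (u %in% seen) next
        seen <- c(seen, u)
        if (u <= nt) tips <- c(tips, u) else stack <- c(stack, u)
      }
    }
    out[[length(out) + 1L]] <- sort(tree$tip.label[tips])
  }
  out
}

# Small calibrated random profile for unit tests (cheap calibration).
toy_calibrated_profile <- function(len = 30L, seed = 1L, name = "toy",
                                   n_samples = 150L, sample_len = 80L) {
  calibrate(make_random_profile(len, seed = seed, name = name),
            n_samples = n_samples, sample_len = sample_len, seed = seed + 7L)
}
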