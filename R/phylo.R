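# Distance-based trees with bootstrap supports and seed-anchored subclade
# extraction. Neighbor-joining is implemented here (Saitou-Nei agglomeration
# with a documented tie rule); trees are standard ape "phylo" objects so
# externally built maximum-likelihood trees can be imported from Newick and
# fed to the same subclade machinery. Internal-node labels carry supports as
# percentages in [0, 100], whatever their origin (bootstrap % or SH-test
# values x 100).

#' Pairwise distance matrix from an alignment
#'
#' `p` is the mismatch fraction over mutually non-gap columns; `poisson` is
#' the corrected distance `-ln(1 - p)`. For the Poisson correction, `p` is
#' capped at `1 - 1e-3` (maximum distance `-ln(1e-3)` ~ 6.91) with a warning,
#' so saturated pairs stay finite.
#'
#' @param m An [msa()] object with >= 3 sequences.
#' @param model `"p"` (default) or `"poisson"`.
#' @return Symmetric numeric matrix with zero diagonal, dimnames = sequence
#'   ids.
#' @export
distance_matrix <- function(m, model = c("p", "poisson")) {
  model <- match.arg(model)
  stopifnot(inherits(m, "nse_msa"))
  if (m$n < 3L) stop("need >= 3 sequences for a distance matrix", call. = FALSE)
  cm <- msa_matrix(m)
  gap <- cm == "-"
  n <- m$n
  D <- matrix(0, n, n, dimnames = list(m$ids, m$ids))
  capped <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !gap[i, ] & !gap[j, ]
      if (!any(ok))
        stop(sprintf("sequences '%s' and '%s' share no non-gap columns",
                     m$ids[i], m$ids[j]), call. = FALSE)
      p <- mean(cm[i, ok] != cm[j, ok])
      if (model == "poisson") {
        if (p > 1 - 1e-3) { p <- 1 - 1e-3; capped <- TRUE }
        p <- -log(1 - p)
      }
      D[i, j] <- D[j, i] <- p
    }
  }
  if (capped)
    warning("saturated pair(s): p capped at 1 - 1e-3 for the Poisson correction")
  D
}

check_dist <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D) || nrow(D) < 3L)
    stop("distance matrix must be square with >= 3 labels", call. = FALSE)
  if (is.null(rownames(D))) stop("distance matrix must have labels", call. = FALSE)
  if (max(abs(D - t(D))) > 1e-12)
    stop("distance matrix is not symmetric", call. = FALSE)
  if (any(abs(diag(D)) > 1e-12))
    stop("distance matrix diagonal must be zero", call. = FALSE)
  bad <- grepl("[,():;[:space:]]", rownames(D))
  if (any(bad))
    stop("labels may not contain Newick metacharacters: ",
         paste(rownames(D)[bad], collapse = ", "), call. = FALSE)
  invisible(D)
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining. Q-matrix ties are broken deterministically by
#' the lexicographically smallest pair of cluster representative labels (the
#' smallest leaf label in each cluster). Negative branch-length estimates are
#' clamped to 0 with a warning. The result is an unrooted `ape::phylo` tree.
#'
#' @param D Symmetric distance matrix with labeled rows/columns (>= 3).
#' @return An unrooted `phylo` object.
#' @export
nj_tree <- function(D) {
  check_dist(D)
  labels <- rownames(D)
  nwk <- labels            # newick fragment per active cluster
  rep_lab <- labels        # representative (smallest) leaf label per cluster
  clamped <- FALSE
  clamp <- function(x) {
    if (x < 0) { clamped <<- TRUE; 0 } else x
  }
  n <- length(labels)
  while (n > 3L) {
    R <- rowSums(D)
    Q <- (n - 2) * D - outer(R, R, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key1 <- pmin(rep_lab[cand[, 1]], rep_lab[cand[, 2]])
    key2 <- pmax(rep_lab[cand[, 1]], rep_lab[cand[, 2]])
    pick <- order(key1, key2)[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    bi <- clamp(0.5 * D[i, j] + (R[i] - R[j]) / (2 * (n - 2)))
    bj <- clamp(D[i, j] - (0.5 * D[i, j] + (R[i] - R[j]) / (2 * (n - 2))))
    newnwk <- sprintf("(%s:%.12g,%s:%.12g)", nwk[i], bi, nwk[j], bj)
    newrep <- min(rep_lab[i], rep_lab[j])
    ks <- setdiff(seq_len(n), c(i, j))
    newd <- 0.5 * (D[i, ks] + D[j, ks] - D[i, j])
    D <- D[ks, ks, drop = FALSE]
    D <- rbind(cbind(D, newd), c(newd, 0))
    nwk <- c(nwk[ks], newnwk)
    rep_lab <- c(rep_lab[ks], newrep)
    n <- n - 1L
  }
  # three-point closed form for the final star
  a <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  b <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  c3 <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  if (clamped)
    warning("negative branch-length estimate(s) clamped to 0")
  txt <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 nwk[1], a, nwk[2], b, nwk[3], c3)
  ape::read.tree(text = txt)
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Builds the tree from the full alignment, then resamples alignment columns
#' with replacement `B` times, rebuilds the tree from each replicate, and
#' stores on each internal node the percentage of replicate trees containing
#' the same bipartition. With `B = 0` no supports are attached.
#'
#' @param m An [msa()] object (>= 3 sequences).
#' @param B Number of bootstrap replicates (>= 0; default 100).
#' @param seed Integer seed for column resampling.
#' @param model Distance model passed to [distance_matrix()].
#' @return A `phylo` tree; internal-node labels (`node.label`) hold supports
#'   in [0, 100] (root label empty), absent when `B = 0`.
#' @export
bootstrap_supports <- function(m, B = 100L, seed = 1L,
                               model = c("p", "poisson")) {
  model <- match.arg(model)
  if (!is.numeric(B) || B < 0) stop("B must be >= 0", call. = FALSE)
  B <- as.integer(B)
  base <- nj_tree(distance_matrix(m, model))
  if (B == 0L) return(base)
  reps <- with_seed(seed, {
    lapply(seq_len(B), function(b) {
      cols <- sample.int(m$width, m$width, replace = TRUE)
      rows <- vapply(strsplit(m$rows, ""), function(ch)
        paste(ch[cols], collapse = ""), character(1))
      suppressWarnings(nj_tree(distance_matrix(msa(m$ids, rows), model)))
    })
  })
  counts <- ape::prop.clades(base, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supports <- 100 * counts / B
  # first internal node is the (trifurcating) root of the unrooted tree: no
  # bipartition of its own
  lab <- formatC(supports, format = "fg")
  lab[1] <- ""
  base$node.label <- lab
  base
}

#' Read / write a support-annotated Newick tree
#'
#' Thin wrappers over `ape::read.tree` / `ape::write.tree`; internal-node
#' labels are interpreted as supports in [0, 100].
#'
#' @param path File path.
#' @return For `read_newick`, a `phylo` object.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ape::read.tree(path)
}

#' @rdname read_newick
#' @param tree A `phylo` object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# all bipartition "sides below a node": list over internal nodes (node
# Ntip + i -> element i), each a vector of tip labels
node_tip_sets <- function(tree) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  lapply(pp, function(idx) labs[idx])
}

#' Extract the smallest supported clade containing a set of seed leaves
#'
#' Enumerates every bipartition of the (unrooted) tree and returns the
#' smallest side containing all seeds, together with the support of the
#' defining split. When no proper bipartition side contains all seeds (the
#' seeds span the root under every rooting), the full leaf set is returned
#' with a note.
#'
#' @param tree A `phylo` object; internal-node labels, if present, are read
#'   as supports in [0, 100].
#' @param seeds Character vector of leaf labels (all must be in the tree).
#' @param min_support Threshold below which (or when support is absent)
#'   `low_support` is flagged; default 70.
#' @param name Optional family name recorded in the result.
#' @return A list of class `subclade`: `name`, `leaves`, `support`
#'   (`NA` when absent), `low_support`, `note`.
#' @export
extract_subclade <- function(tree, seeds, min_support = 70, name = "") {
  stopifnot(inherits(tree, "phylo"))
  seeds <- as.character(seeds)
  if (!length(seeds)) stop("seeds must be non-empty", call. = FALSE)
  missing <- setdiff(seeds, tree$tip.label)
  if (length(missing))
    stop("unknown seed id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  tips <- tree$tip.label
  sets <- node_tip_sets(tree)             # clades below each internal node
  supports <- rep(NA_real_, length(sets))
  if (!is.null(tree$node.label)) {
    sup <- suppressWarnings(as.numeric(tree$node.label))
    supports[seq_along(sup)] <- sup
  }
  # candidate sides: each internal edge contributes the clade below it and
  # its complement; node 1 (root) gives only the trivial full set
  cand_leaves <- list(tips)
  cand_support <- NA_real_
  best <- NULL; best_sup <- NA_real_
  for (i in seq_along(sets)[-1]) {
    for (side in list(sets[[i]], setdiff(tips, sets[[i]]))) {
      if (all(seeds %in% side) &&
          (is.null(best) || length(side) < length(best))) {
        best <- side
        best_sup <- supports[i]
      }
    }
  }
  note <- ""
  if (is.null(best) || length(best) == length(tips)) {
    best <- tips
    best_sup <- NA_real_
    if (length(seeds) < length(tips))
      note <- "seeds span the root: smallest containing clade is the full leaf set"
  }
  structure(list(name = name, leaves = sort(best), support = best_sup,
                 low_support = is.na(best_sup) || best_sup < min_support,
                 note = note),
            class = "subclade")
}

#' @export
print.subclade <- function(x, ...) {
  cat(sprintf("subclade%s: %d leaves, support %s%s\n",
              if (nzchar(x$name)) paste0(" '", x$name, "'") else "",
              length(x$leaves),
              if (is.na(x$support)) "NA" else format(x$support),
              if (x$low_support) " [low support]" else ""))
  if (nzchar(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Subclade report for several seed sets
#'
#' @param tree A `phylo` object.
#' @param seed_sets Named list of character vectors of seed leaf labels.
#' @param min_support Support threshold (default 70).
#' @return Data frame with one row per family: `family`, `n_leaves`,
#'   `support`, `low_support`, `leaves` (comma-joined).
#' @export
subclade_report <- function(tree, seed_sets, min_support = 70) {
  stopifnot(is.list(seed_sets), !is.null(names(seed_sets)))
  rows <- lapply(names(seed_sets), function(nm) {
    sc <- extract_subclade(tree, seed_sets[[nm]], min_support, name = nm)
    data.frame(family = nm, n_leaves = length(sc$leaves),
               support = sc$support, low_support = sc$low_support,
               leaves = paste(sc$leaves, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
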