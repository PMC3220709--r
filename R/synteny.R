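# Gene-neighborhood synteny scan: find windows of at most `window_span`
# consecutive genes (inclusive gene count) containing at least `min_distinct`
# distinct family labels, within one contig. This mirrors the prokaryotic
# rmlB/rmlC/rmlD-style analysis: "at least two of the three genes clustered
# within a region spanning seven genes" reads as ordinal span <= 7.

#' Construct an ordered gene table
#'
#' @param genome_id Genome identifier (scalar).
#' @param contig Contig per gene.
#' @param ordinal Integer gene position within its contig; must be strictly
#'   increasing within each contig.
#' @param gene_id Gene identifiers.
#' @param strand `"+"`/`"-"` (ignored by the scan; default `"+"`).
#' @param label Family label per gene, `NA` for unlabeled filler genes.
#' @return Data frame of class `gene_table`.
#' @export
gene_table <- function(genome_id, contig, ordinal, gene_id,
                       strand = "+", label = NA_character_) {
  df <- data.frame(genome_id = as.character(genome_id),
                   contig = as.character(contig),
                   ordinal = as.integer(ordinal),
                   gene_id = as.character(gene_id),
                   strand = rep_len(as.character(strand), length(gene_id)),
                   label = rep_len(as.character(label), length(gene_id)),
                   stringsAsFactors = FALSE)
  check_gene_table(df)
  class(df) <- c("gene_table", "data.frame")
  df
}

check_gene_table <- function(df) {
  need <- c("genome_id", "contig", "ordinal", "gene_id", "strand", "label")
  if (!all(need %in% names(df)))
    stop("gene table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  for (ctg in unique(df$contig)) {
    o <- df$ordinal[df$contig == ctg]
    if (any(diff(o) <= 0))
      stop("gene table not sorted: ordinals must be strictly increasing ",
           "within contig '", ctg, "'", call. = FALSE)
  }
  invisible(df)
}

#' Read a gene table from the simple TSV dialect
#'
#' Expected columns: `genome_id`, `contig`, `ordinal`, `gene_id`, `strand`,
#' `label` (empty/`NA` label means unlabeled).
#'
#' @param path TSV path.
#' @return A [gene_table()].
#' @export
read_gene_table_tsv <- function(path) {
  df <- read_tsv(path, colClasses = c(label = "character"))
  df$label[!is.na(df$label) & df$label == ""] <- NA_character_
  gene_table(df$genome_id[1], df$contig, df$ordinal, df$gene_id,
             df$strand, df$label)
}

#' Read a gene table from GFF3
#'
#' `gene`-type features are ordered by start coordinate within each seqname
#' to produce ordinals; family labels are taken from the GFF attribute named
#' by `label_attr` (missing attribute = unlabeled) or, if `label_map` is
#' given, by gene ID lookup.
#'
#' @param path GFF3 file path.
#' @param genome_id Genome identifier for the table.
#' @param label_attr Attribute column carrying the family label (default
#'   `"family"`).
#' @param label_map Optional named character vector gene_id -> label,
#'   overriding `label_attr`.
#' @return A [gene_table()].
#' @export
read_gene_table_gff3 <- function(path, genome_id = basename(path),
                                 label_attr = "family", label_map = NULL) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("rtracklayer is required to read GFF3", call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "gene"]
  if (!length(gr)) stop("no gene features in ", path, call. = FALSE)
  df <- data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   gene_id = as.character(gr$ID),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  df$label <- if (!is.null(label_map)) unname(label_map[df$gene_id])
  else if (label_attr %in% names(S4Vectors::mcols(gr)))
    as.character(S4Vectors::mcols(gr)[[label_attr]])
  else NA_character_
  df <- df[order(df$contig, df$start), ]
  df$ordinal <- as.integer(stats::ave(df$start, df$contig, FUN = seq_along))
  gene_table(genome_id, df$contig, df$ordinal, df$gene_id, df$strand,
             df$label)
}

#' Scan a gene table for co-clustered family labels
#'
#' Reports maximal, non-nested windows within a contig whose labeled genes
#' span at most `window_span` ordinals (inclusive gene count) and carry at
#' least `min_distinct` distinct family labels. Strand is ignored; windows
#' never cross contigs.
#'
#' @param table A [gene_table()].
#' @param window_span Maximum inclusive gene-count span (>= 2; default 7).
#' @param min_distinct Minimum number of distinct labels (>= 2; default 2).
#' @return Data frame of calls: `genome_id`, `contig`, `start`, `end`
#'   (ordinals of the first/last labeled gene), `span`, `n_distinct`,
#'   `gene_ids`, `labels` (comma-joined); zero rows when nothing qualifies.
#' @export
synteny_scan <- function(table, window_span = 7L, min_distinct = 2L) {
  check_gene_table(table)
  if (window_span < 2L) stop("window_span must be >= 2", call. = FALSE)
  if (min_distinct < 2L) stop("min_distinct must be >= 2", call. = FALSE)
  empty <- data.frame(genome_id = character(), contig = character(),
                      start = integer(), end = integer(), span = integer(),
                      n_distinct = integer(), gene_ids = character(),
                      labels = character(), stringsAsFactors = FALSE)
  out <- empty
  for (ctg in unique(table$contig)) {
    sub <- table[table$contig == ctg & !is.na(table$label), , drop = FALSE]
    if (nrow(sub) < 2L) next
    # candidate windows anchored on pairs of labeled genes
    cand <- list()
    for (i in seq_len(nrow(sub) - 1L)) {
      for (j in (i + 1L):nrow(sub)) {
        span <- sub$ordinal[j] - sub$ordinal[i] + 1L
        if (span > window_span) break
        inside <- sub[i:j, , drop = FALSE]
        if (length(unique(inside$label)) >= min_distinct)
          cand[[length(cand) + 1L]] <- c(i, j)
      }
    }
    if (!length(cand)) next
    # keep maximal non-nested windows
    keep <- rep(TRUE, length(cand))
    for (a in seq_along(cand)) {
      for (b in seq_along(cand)) {
        if (a == b || !keep[a]) next
        if (cand[[b]][1] <= cand[[a]][1] && cand[[b]][2] >= cand[[a]][2] &&
            !identical(cand[[b]], cand[[a]]))
          keep[a] <- FALSE
      }
    }
    for (w in cand[keep]) {
      inside <- sub[w[1]:w[2], , drop = FALSE]
      out <- rbind(out, data.frame(
        genome_id = table$genome_id[1], contig = ctg,
        start = inside$ordinal[1], end = inside$ordinal[nrow(inside)],
        span = inside$ordinal[nrow(inside)] - inside$ordinal[1] + 1L,
        n_distinct = length(unique(inside$label)),
        gene_ids = paste(inside$gene_id, collapse = ","),
        labels = paste(inside$label, collapse = ","),
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Fraction of genomes with at least one synteny call
#'
#' @param tables List of [gene_table()] objects (one per genome; non-empty).
#' @inheritParams synteny_scan
#' @return List: `n_with_call`, `n_total`, `fraction`, and `per_genome`
#'   (logical vector named by genome id).
#' @export
genome_fraction <- function(tables, window_span = 7L, min_distinct = 2L) {
  if (!length(tables)) stop("empty genome list", call. = FALSE)
  hit <- vapply(tables, function(tb)
    nrow(synteny_scan(tb, window_span, min_distinct)) > 0L, logical(1))
  names(hit) <- vapply(tables, function(tb) tb$genome_id[1], character(1))
  list(n_with_call = sum(hit), n_total = length(hit),
       fraction = sum(hit) / length(hit), per_genome = hit)
}
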