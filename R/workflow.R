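# End-to-end orchestration: harvest -> classify -> architecture -> phylo ->
# synteny from a single flat config, with a machine-readable JSON report and
# a plain-text log. All randomness is funneled through the config seed and
# echoed in the report; reruns with identical config and seeds produce
# byte-identical stage outputs and report.

PIPELINE_DEFAULTS <- list(evalue_cutoff = 0.01, min_support = 70,
                          window_span = 7L, min_distinct = 2L,
                          bootstrap_B = 100L, seed = 1L)

#' Read a flat pipeline configuration file
#'
#' One `key: value` pair per line; `#` starts a comment. List-valued keys
#' (`family_profiles`, `gene_tables`, `subclade_seeds`) are comma-separated.
#' See [run_pipeline()] for the recognized keys.
#'
#' @param path Config file path.
#' @return Named list of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stop("malformed config line: ", ln, call. = FALSE)
    cfg[[m[2]]] <- trimws(m[3])
  }
  pipeline_config(cfg, base_dir = dirname(path))
}

#' Normalize and validate a pipeline configuration
#'
#' @param cfg Named list of raw config values (strings or R values).
#' @param base_dir Directory that relative input paths are resolved against.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(cfg, base_dir = ".") {
  num_keys <- c("evalue_cutoff", "min_support", "window_span", "min_distinct",
                "bootstrap_B", "seed")
  list_keys <- c("family_profiles", "gene_tables", "subclade_seeds")
  path_keys <- c("db_fasta", "harvest_profile", "n_profile", "c_profile",
                 "taxonomy_tsv", "msa_fasta", "family_profiles", "gene_tables")
  for (k in num_keys)
    cfg[[k]] <- as.numeric(cfg[[k]] %||% PIPELINE_DEFAULTS[[k]])
  for (k in list_keys)
    if (!is.null(cfg[[k]]) && is.character(cfg[[k]]) && length(cfg[[k]]) == 1L)
      cfg[[k]] <- trimws(strsplit(cfg[[k]], ",")[[1]])
  for (k in path_keys) {
    if (is.null(cfg[[k]])) next
    p <- cfg[[k]]
    rel <- !grepl("^(/|[A-Za-z]:)", p)
    p[rel] <- file.path(base_dir, p[rel])
    missing <- p[!file.exists(p)]
    if (length(missing))
      stop("config error: input file(s) not found: ",
           paste(missing, collapse = ", "), call. = FALSE)
    cfg[[k]] <- p
  }
  if (cfg$evalue_cutoff <= 0) stop("evalue_cutoff must be positive", call. = FALSE)
  if (cfg$window_span < 2) stop("window_span must be >= 2", call. = FALSE)
  if (cfg$min_distinct < 2) stop("min_distinct must be >= 2", call. = FALSE)
  if (cfg$bootstrap_B < 0) stop("bootstrap_B must be >= 0", call. = FALSE)
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes up to five stages, each driven by the presence of its inputs in
#' the config:
#' \describe{
#'   \item{harvest}{`db_fasta` + `harvest_profile`: scan the database,
#'     write `hits.tsv` and `domains.fasta`.}
#'   \item{classify}{`family_profiles` (+ optional `taxonomy_tsv`):
#'     competitively classify the harvested domains, write
#'     `assignments.tsv` and `taxon_profile.tsv`.}
#'   \item{architecture}{`n_profile` + `c_profile`: call single-/bi-domain
#'     architectures over the database, write `architecture.tsv`.}
#'   \item{phylo}{`msa_fasta`: NJ tree with `bootstrap_B` bootstrap
#'     replicates, write `tree.nwk`; with `subclade_seeds` also
#'     `subclades.tsv`.}
#'   \item{synteny}{`gene_tables`: window scan, write `synteny.tsv`.}
#' }
#' Missing input files abort before any stage runs; a failure inside a stage
#' is recorded in the report and later stages still run. The JSON report
#' (`report.json`) contains per-stage summaries, all parameters and seeds.
#'
#' @param config A `pipeline_config`, a raw named list, or a config file
#'   path.
#' @param out_dir Output directory (created if needed); defaults to the
#'   config's `out_dir` or a tempdir subdirectory.
#' @return The report, invisibly (a named list; also written as JSON).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config"))
    config <- pipeline_config(config)
  out_dir <- out_dir %||% config$out_dir %||%
    file.path(tempdir(), "nsephylo_run")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  cat(sprintf("[%s] nsephylo pipeline start\n", Sys.time()), file = log_path)
  logmsg <- function(...) cat(sprintf("[%s] %s\n", Sys.time(),
                                      sprintf(...)),
                              file = log_path, append = TRUE)
  report <- list(
    package = "nsephylo",
    version = as.character(utils::packageVersion("nsephylo")),
    parameters = config[c("evalue_cutoff", "min_support", "window_span",
                          "min_distinct", "bootstrap_B", "seed")],
    stages = list())

  run_stage <- function(name, enabled, expr) {
    if (!enabled) {
      logmsg("stage %s: skipped (inputs not configured)", name)
      report$stages[[name]] <<- list(status = "skipped")
      return(invisible(NULL))
    }
    logmsg("stage %s: start", name)
    res <- tryCatch(list(status = "ok", summary = expr),
                    error = function(e)
                      list(status = "failed", error = conditionMessage(e)))
    logmsg("stage %s: %s", name, res$status)
    report$stages[[name]] <<- res
  }

  harvest_res <- NULL
  run_stage("harvest",
            !is.null(config$db_fasta) && !is.null(config$harvest_profile), {
      db <- read_fasta_db(config$db_fasta)
      prof <- read_profile(config$harvest_profile)
      harvest_res <- harvest_domains(db, prof, config$evalue_cutoff)
      write_hits_tsv(harvest_res$hits, file.path(out_dir, "hits.tsv"))
      write_fasta(harvest_res$domains, file.path(out_dir, "domains.fasta"))
      list(n_sequences = nrow(db), n_hits = nrow(harvest_res$hits),
           cutoff = config$evalue_cutoff, db_size = harvest_res$db_size)
  })

  taxmap <- if (!is.null(config$taxonomy_tsv))
    read_taxonomy_tsv(config$taxonomy_tsv) else character()

  run_stage("classify",
            !is.null(config$family_profiles) && !is.null(harvest_res), {
      profiles <- lapply(config$family_profiles, read_profile)
      asg <- classify_competitive(harvest_res$domains, profiles,
                                  config$evalue_cutoff,
                                  db_size = harvest_res$db_size)
      write_tsv(asg, file.path(out_dir, "assignments.tsv"))
      tp <- build_taxon_profile(asg, taxmap)
      write_taxon_profile_tsv(tp, file.path(out_dir, "taxon_profile.tsv"))
      fam_counts <- table(asg$family)
      list(n_domains = nrow(asg),
           families = as.list(setNames(as.integer(fam_counts),
                                       names(fam_counts))),
           unclassified = tp$unclassified)
  })

  run_stage("architecture",
            !is.null(config$db_fasta) && !is.null(config$n_profile) &&
              !is.null(config$c_profile), {
      db <- read_fasta_db(config$db_fasta)
      np <- read_profile(config$n_profile)
      cp <- read_profile(config$c_profile)
      calls <- detect_architectures(db, np, cp, config$evalue_cutoff)
      write_tsv(calls, file.path(out_dir, "architecture.tsv"))
      tab <- table(factor(calls$label, levels = ARCH_LABELS))
      as.list(setNames(as.integer(tab), names(tab)))
  })

  run_stage("phylo", !is.null(config$msa_fasta), {
      m <- read_msa(config$msa_fasta)
      tree <- bootstrap_supports(m, B = as.integer(config$bootstrap_B),
                                 seed = config$seed)
      write_newick(tree, file.path(out_dir, "tree.nwk"))
      summ <- list(n_leaves = length(tree$tip.label),
                   bootstrap_B = as.integer(config$bootstrap_B))
      if (!is.null(config$subclade_seeds)) {
        sc <- extract_subclade(tree, config$subclade_seeds,
                               min_support = config$min_support)
        write_tsv(data.frame(family = "seeded", n_leaves = length(sc$leaves),
                             support = sc$support,
                             low_support = sc$low_support,
                             leaves = paste(sc$leaves, collapse = ",")),
                  file.path(out_dir, "subclades.tsv"))
        summ$subclade <- list(n_leaves = length(sc$leaves),
                              support = sc$support,
                              low_support = sc$low_support)
      }
      summ
  })

  run_stage("synteny", !is.null(config$gene_tables), {
      tables <- lapply(config$gene_tables, read_gene_table_tsv)
      calls <- do.call(rbind, lapply(tables, synteny_scan,
                                     window_span = config$window_span,
                                     min_distinct = config$min_distinct))
      write_tsv(calls, file.path(out_dir, "synteny.tsv"))
      gf <- genome_fraction(tables, config$window_span, config$min_distinct)
      list(n_calls = nrow(calls), n_with_call = gf$n_with_call,
           n_total = gf$n_total, fraction = gf$fraction)
  })

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  logmsg("pipeline done")
  invisible(report)
}
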