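# Plain-text profile serialization. The format is line-oriented:
#
#   # nsephylo profile HMM v1
#   # glocal architecture; fixed insert/delete transition priors;
#   # insert emissions = background; flanking residues free under the null
#   name <label>
#   M <int>
#   gap_threshold <num>
#   pseudocount_weight <num>
#   alphabet ACDEFGHIKLMNPQRSTVWY
#   background <20 numbers>
#   entry <P(B->M1)> <P(B->D1)>
#   insert_emissions <20 numbers>
#   calibration <mu> <lam> <n_samples> <sample_len> <seed>     [optional]
#   match <k> <20 numbers>            (k = 1..M)
#   trans <k> <MM> <MI> <MD> <IM> <II> <DM> <DD>
#
# Numbers are printed with %.17g so serialize -> parse -> serialize is
# byte-identical.

fmt_num <- function(x) sprintf("%.17g", x)

#' Serialize a profile HMM to a plain-text file
#'
#' @param prof A `profile_hmm` object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @seealso [read_profile()]
#' @export
write_profile <- function(prof, path) {
  validate_profile(prof)
  out <- c(
    "# nsephylo profile HMM v1",
    "# glocal architecture; fixed insert/delete transition priors;",
    "# insert emissions = background; flanking residues free under the null",
    paste("name", prof$name),
    paste("M", prof$M),
    paste("gap_threshold", fmt_num(prof$gap_threshold %||% NA_real_)),
    paste("pseudocount_weight", fmt_num(prof$pseudocount_weight %||% NA_real_)),
    paste("alphabet", paste(AA_ALPHABET, collapse = "")),
    paste("background", paste(fmt_num(prof$background), collapse = " ")),
    paste("entry", paste(fmt_num(prof$entry), collapse = " ")),
    paste("insert_emissions",
          paste(fmt_num(prof$insert_emissions), collapse = " "))
  )
  if (is_calibrated(prof)) {
    cal <- prof$calibration
    out <- c(out, paste("calibration", fmt_num(cal$mu), fmt_num(cal$lam),
                        cal$n_samples, cal$sample_len, cal$seed))
  }
  for (k in seq_len(prof$M)) {
    out <- c(out,
             paste("match", k,
                   paste(fmt_num(prof$match_emissions[k, ]), collapse = " ")),
             paste("trans", k,
                   paste(fmt_num(prof$transitions[k, ]), collapse = " ")))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a serialized profile HMM
#'
#' @param path Path to a file written by [write_profile()].
#' @return A `profile_hmm` object.
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, " ")
  keys <- vapply(kv, `[[`, "", 1L)
  get1 <- function(key) {
    i <- which(keys == key)
    if (!length(i)) stop("profile file missing field: ", key, call. = FALSE)
    kv[[i[1]]][-1]
  }
  M <- as.integer(get1("M")[1])
  em <- matrix(NA_real_, M, 20, dimnames = list(NULL, AA_ALPHABET))
  tr <- matrix(NA_real_, M, 7,
               dimnames = list(NULL, names(DEFAULT_TRANSITIONS)))
  for (i in which(keys == "match")) {
    v <- kv[[i]]
    em[as.integer(v[2]), ] <- as.numeric(v[-(1:2)])
  }
  for (i in which(keys == "trans")) {
    v <- kv[[i]]
    tr[as.integer(v[2]), ] <- as.numeric(v[-(1:2)])
  }
  if (anyNA(em) || anyNA(tr))
    stop("profile file is missing match/trans lines for some columns",
         call. = FALSE)
  cal <- NULL
  if ("calibration" %in% keys) {
    v <- as.numeric(get1("calibration"))
    cal <- structure(list(mu = v[1], lam = v[2], n_samples = as.integer(v[3]),
                          sample_len = as.integer(v[4]), seed = as.integer(v[5])),
                     class = "calibration_params")
  }
  prof <- structure(list(
    name = paste(get1("name"), collapse = " "),
    M = M,
    match_emissions = em,
    insert_emissions = as.numeric(get1("insert_emissions")),
    transitions = tr,
    entry = setNames(as.numeric(get1("entry")), c("BM", "BD")),
    background = as.numeric(get1("background")),
    gap_threshold = as.numeric(get1("gap_threshold")[1]),
    pseudocount_weight = as.numeric(get1("pseudocount_weight")[1]),
    match_columns = NULL,
    consensus = paste(AA_ALPHABET[apply(em, 1, which.max)], collapse = ""),
    calibration = cal
  ), class = "profile_hmm")
  validate_profile(prof)
  prof
}
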