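#' Read protein sequences from FASTA
#'
#' @param path FASTA file (single- or multi-record).
#' @return named character vector of one-letter sequences; names are the
#'   record ids (first whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  seqs <- as.character(set)
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L)
  seqs
}

#' Write protein sequences to FASTA
#'
#' @param sequences named character vector of sequences.
#' @param path output file.
#' @export
write_fasta <- function(sequences, path) {
  set <- Biostrings::AAStringSet(sequences)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a per-residue R2 table
#'
#' Tab-separated with a header line; columns `index` (1-based residue
#' position), `aa` (one-letter code), `r2` (s^-1, empty or `NA` when
#' unobserved) and optionally `flag` (any non-empty value excludes the row
#' from scoring).  Comment lines start with `#`.  Rows absent from the
#' table are treated as unobserved.  The residue letters are checked
#' against the companion sequence position by position.
#'
#' @param path table file.
#' @param sequence the companion one-letter sequence.
#' @return list with `values` (numeric, NA where unobserved) and `mask`
#'   (logical; `FALSE` at Pro, unobserved and flagged positions).
#' @export
read_r2_table <- function(path, sequence) {
  aa <- resolve_sequence(sequence)
  n <- length(aa)
  tbl <- read.delim(path, comment.char = "#", na.strings = c("", "NA"),
                    stringsAsFactors = FALSE)
  need <- c("index", "aa", "r2")
  if (!all(need %in% names(tbl))) {
    stop("R2 table must have columns ", paste(need, collapse = ", "))
  }
  if (nrow(tbl) > 0) {
    if (anyNA(tbl$index) || any(tbl$index < 1L) || any(tbl$index > n)) {
      stop("R2 table indices must lie in 1..", n)
    }
    if (is.unsorted(tbl$index, strictly = TRUE)) {
      stop("R2 table indices must be strictly increasing")
    }
    mismatch <- which(toupper(tbl$aa) != aa[tbl$index])
    if (length(mismatch)) {
      stop("R2 table residue letters disagree with the sequence at ",
           "position(s) ", paste(tbl$index[utils::head(mismatch, 5L)],
                                 collapse = ","))
    }
  }
  values <- rep(NA_real_, n)
  values[tbl$index] <- tbl$r2
  flagged <- rep(FALSE, n)
  if ("flag" %in% names(tbl)) flagged[tbl$index] <- !is.na(tbl$flag)
  mask <- !is.na(values) & !flagged & aa != "P"
  list(values = values, mask = mask)
}

#' Write a per-residue R2 table
#'
#' @param values numeric per-residue rates (NA rows are written with an
#'   empty r2 field so the mask round-trips).
#' @param sequence companion one-letter sequence.
#' @param path output file.
#' @param flag optional character vector of exclusion notes (NA = none).
#' @export
write_r2_table <- function(values, sequence, path, flag = NULL) {
  aa <- resolve_sequence(sequence)
  if (length(values) != length(aa)) stop("values/sequence length mismatch")
  tbl <- data.frame(index = seq_along(aa), aa = aa, r2 = values)
  if (!is.null(flag)) tbl$flag <- flag
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# per-residue backbone amide R2 (s^-1)", con)
  write.table(tbl, con, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

#' Read helix-propensity scores from a PsiPred-style ss2 file
#'
#' Columnar secondary-structure output: per-residue rows with index,
#' residue letter, state call, and the coil/helix/strand scores.  Any
#' preamble lines before the first row matching this layout are skipped.
#' The helix-score column is extracted and validated against the companion
#' sequence.
#'
#' @param path ss2 file.
#' @param sequence companion one-letter sequence.
#' @return numeric vector of per-residue helix scores in [0, 1].
#' @export
read_ss2 <- function(path, sequence) {
  aa <- resolve_sequence(sequence)
  lines <- readLines(path)
  pat <- "^\\s*\\d+\\s+[A-Za-z]\\s+[A-Za-z]\\s+[0-9.]+\\s+[0-9.]+\\s+[0-9.]+\\s*$"
  rows <- grep(pat, lines, value = TRUE)
  if (length(rows) == 0L) stop("no ss2 data rows found in ", path)
  parts <- strsplit(trimws(rows), "\\s+")
  idx <- vapply(parts, function(p) as.integer(p[1]), 0L)
  lett <- toupper(vapply(parts, `[[`, "", 2L))
  helix <- vapply(parts, function(p) as.numeric(p[5]), 0)
  if (length(idx) != length(aa)) {
    stop("ss2 file has ", length(idx), " rows but the sequence has ",
         length(aa), " residues")
  }
  mismatch <- which(lett != aa)
  if (length(mismatch)) {
    stop("ss2 residue letters disagree with the sequence at position(s) ",
         paste(utils::head(idx[mismatch], 5L), collapse = ","))
  }
  if (any(helix < 0 | helix > 1)) stop("helix scores must lie in [0, 1]")
  helix
}

#' Write helix scores in ss2 layout
#'
#' Emits the standard two-line preamble followed by per-residue rows
#' (index, residue, state call, coil/helix/strand scores to 3 decimals).
#' The coil score is written as the complement of the helix score and the
#' strand score as 0.
#'
#' @param helix_scores per-residue helix scores in [0, 1].
#' @param sequence companion one-letter sequence.
#' @param path output file.
#' @export
write_ss2 <- function(helix_scores, sequence, path) {
  aa <- resolve_sequence(sequence)
  if (length(helix_scores) != length(aa)) stop("length mismatch")
  state <- ifelse(helix_scores >= 0.5, "H", "C")
  lines <- c("# PSIPRED VFORMAT (idpr2 writer)", "",
             sprintf("%4d %s %s  %6.3f %6.3f %6.3f", seq_along(aa), aa,
                     state, 1 - helix_scores, helix_scores, 0))
  writeLines(lines, path)
  invisible(path)
}

#' Read a model parameter file
#'
#' Flat key-value text: one `key<TAB>value` row per parameter, with the 20
#' q entries keyed by one-letter code plus `b`; `#` lines are comments and
#' may carry metadata.  Values are stored with 17 significant digits so a
#' write/read round trip is bit-exact.
#'
#' @param path parameter file.
#' @param kernel distance kernel to attach, see [model_params()].
#' @return a [model_params()] object.
#' @export
read_params <- function(path, kernel = "lorentzian") {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed parameter line(s): ",
                     paste(lines[bad], collapse = "; "))
  keys <- vapply(parts, `[[`, "", 1L)
  vals <- as.numeric(vapply(parts, `[[`, "", 2L))
  if (anyNA(vals)) stop("non-numeric parameter value(s)")
  kv <- setNames(vals, keys)
  if (!"b" %in% keys) stop("parameter file is missing key 'b'")
  missing <- setdiff(AA20, keys)
  if (length(missing)) {
    stop("parameter file is missing q entr",
         if (length(missing) > 1) "ies: " else "y: ",
         paste(missing, collapse = ","))
  }
  if (any(kv <= 0)) {
    stop("non-positive parameter value for key(s) ",
         paste(names(kv)[kv <= 0], collapse = ","))
  }
  model_params(kv[AA20], kv[["b"]], kernel = kernel)
}

#' Write a model parameter file
#'
#' @param params a [model_params()] object.
#' @param path output file.
#' @param metadata optional named character vector written as `# key: value`
#'   comment lines (e.g. a training-set hash or date).
#' @export
write_params <- function(params, path, metadata = NULL) {
  stopifnot(inherits(params, "model_params"))
  lines <- character(0)
  if (!is.null(metadata)) {
    lines <- sprintf("# %s: %s", names(metadata), metadata)
  }
  lines <- c(lines,
             sprintf("%s\t%.17g", AA20, params$q[AA20]),
             sprintf("b\t%.17g", params$b))
  writeLines(lines, path)
  invisible(path)
}

#' Read a dataset manifest
#'
#' A YAML document listing, per protein, paths (relative to the manifest)
#' to its FASTA, R2 table and optional ss2 file, plus a role:
#' \preformatted{
#' proteins:
#'   - id: prot1
#'     fasta: prot1.fasta
#'     r2: prot1.r2.tsv
#'     ss2: prot1.ss2      # optional
#'     role: train         # or test
#' }
#'
#' @param path manifest file.
#' @param load if `TRUE` (default) read every referenced file and return
#'   records; otherwise return the parsed manifest list.
#' @return when `load = TRUE`, a list with `records` (list of
#'   [protein_record()]s) and `roles` (named character vector).
#' @export
read_manifest <- function(path, load = TRUE) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$proteins) || !length(doc$proteins)) {
    stop("manifest must contain a non-empty 'proteins' list")
  }
  base <- dirname(normalizePath(path))
  if (!load) return(doc)
  records <- list()
  roles <- character(0)
  for (entry in doc$proteins) {
    for (field in c("id", "fasta", "r2")) {
      if (is.null(entry[[field]])) {
        stop("manifest entry", if (!is.null(entry$id)) paste0(" '", entry$id, "'"),
             " is missing required field '", field, "'")
      }
    }
    role <- if (is.null(entry$role)) "train" else entry$role
    if (!role %in% c("train", "test")) {
      stop("role must be 'train' or 'test' for '", entry$id, "'")
    }
    seqs <- read_fasta(file.path(base, entry$fasta))
    sq <- if (entry$id %in% names(seqs)) seqs[[entry$id]] else seqs[[1L]]
    r2 <- read_r2_table(file.path(base, entry$r2), sq)
    hs <- if (!is.null(entry$ss2)) read_ss2(file.path(base, entry$ss2), sq)
    records[[entry$id]] <- protein_record(entry$id, sq,
                                          measured_r2 = r2$values,
                                          mask = r2$mask,
                                          helix_scores = hs)
    roles[entry$id] <- role
  }
  list(records = unname(records), roles = roles)
}

#' Write a dataset manifest and its data files
#'
#' Serializes a list of records to per-protein FASTA and R2 tables (and ss2
#' files where helix scores are present) in `dir`, plus a manifest YAML
#' that [read_manifest()] accepts.
#'
#' @param records list of [protein_record()]s.
#' @param dir output directory (created if needed).
#' @param roles optional named character vector of roles (default all
#'   "train").
#' @return path to the manifest file.
#' @export
write_manifest <- function(records, dir, roles = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  for (rec in records) {
    fa <- paste0(rec$id, ".fasta")
    r2 <- paste0(rec$id, ".r2.tsv")
    write_fasta(setNames(rec$sequence, rec$id), file.path(dir, fa))
    vals <- rec$measured_r2
    vals[!rec$mask & rec$aa != "P"] <- NA  # unobserved rows stay masked
    write_r2_table(vals, rec$sequence, file.path(dir, r2))
    entry <- list(id = rec$id, fasta = fa, r2 = r2,
                  role = if (is.null(roles)) "train" else unname(roles[rec$id]))
    if (!is.null(rec$helix_scores)) {
      s2 <- paste0(rec$id, ".ss2")
      write_ss2(rec$helix_scores, rec$sequence, file.path(dir, s2))
      entry$ss2 <- s2
    }
    entries[[length(entries) + 1L]] <- entry
  }
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(list(proteins = entries), manifest)
  manifest
}

#' Load the bundled benchmark summary table
#'
#' A compiled per-protein summary of published R2 datasets for 45 training
#' and 9 test IDPs: name, set membership, residue count, experimental
#' conditions, mean and standard deviation of measured R2, and prediction
#' RMSE (with a second, helix-boosted RMSE where that correction applies).
#'
#' @param path optional override; defaults to the copy shipped in
#'   `inst/extdata`.
#' @return data.frame with columns `name`, `set`, `n_res`, `temp_K`,
#'   `field_MHz`, `mean_r2`, `sd_r2`, `rmse`, `rmse_boosted`.
#' @export
read_benchmark_summary <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "idp_r2_benchmark.tsv", package = "idpr2",
                        mustWork = TRUE)
  }
  tbl <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("name", "set", "mean_r2", "sd_r2", "rmse")
  if (!all(need %in% names(tbl))) {
    stop("benchmark summary must have columns ", paste(need, collapse = ", "))
  }
  tbl
}

#' Serialize a fit or cross-validation report to JSON
#'
#' @param x a `fit_result` or `crossval_report`.
#' @param path output file.
#' @export
write_report <- function(x, path) {
  strip <- function(p) list(q = as.list(p$q), b = p$b, kernel = p$kernel)
  out <- unclass(x)
  # named atomic vectors must become objects, not bare arrays
  for (field in c("scales", "per_protein_rmse", "per_protein_rmse_heldout",
                  "heldout_scales", "folds")) {
    if (!is.null(out[[field]])) out[[field]] <- as.list(out[[field]])
  }
  if (!is.null(out$params)) out$params <- strip(out$params)
  if (!is.null(out$fold_params)) out$fold_params <- lapply(out$fold_params, strip)
  out$.class <- class(x)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Read a report written by [write_report()]
#'
#' @param path JSON file.
#' @return the reconstructed `fit_result` or `crossval_report`.
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  cls <- raw$.class
  raw$.class <- NULL
  rebuild <- function(p) model_params(unlist(p$q), p$b, kernel = p$kernel)
  if (!is.null(raw$params)) raw$params <- rebuild(raw$params)
  if (!is.null(raw$fold_params)) {
    raw$fold_params <- lapply(raw$fold_params, rebuild)
  }
  structure(raw, class = cls)
}
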