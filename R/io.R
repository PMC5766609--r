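#' Read a two-receptor activity table from CSV
#'
#' Expected columns: `id, sequence, ec50_gcgr, sd_gcgr, ec50_glp1r,
#' sd_glp1r` (plus any extras, kept verbatim). Censored EC50 cells are
#' encoded `">bound"` (e.g. `">200"`); they are parsed into an explicit
#' censor flag with the bound as the value and are never imputed.
#'
#' @param path CSV file path.
#' @return A data frame with numeric `ec50_*`/`sd_*` columns and logical
#'   `censored_gcgr`, `censored_glp1r` flags.
#' @export
read_activity_csv <- function(path) {
  if (!file.exists(path)) stop("activity table not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", encoding = "UTF-8")
  need <- c("id", "sequence", "ec50_gcgr", "ec50_glp1r")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("activity table lacks column(s): ", paste(miss, collapse = ", "))
  parse_ec50 <- function(x, col) {
    cens <- grepl("^\\s*>", x)
    val <- suppressWarnings(as.numeric(sub("^\\s*>\\s*", "", x)))
    bad <- which(is.na(val) & nzchar(trimws(x)))
    if (length(bad))
      stop("malformed ", col, " at data line ", bad[1], ": '", x[bad[1]], "'")
    list(value = val, censored = cens)
  }
  g <- parse_ec50(tab$ec50_gcgr, "ec50_gcgr")
  l <- parse_ec50(tab$ec50_glp1r, "ec50_glp1r")
  tab$ec50_gcgr <- g$value; tab$censored_gcgr <- g$censored
  tab$ec50_glp1r <- l$value; tab$censored_glp1r <- l$censored
  for (col in intersect(c("sd_gcgr", "sd_glp1r"), names(tab)))
    tab[[col]] <- suppressWarnings(as.numeric(tab[[col]]))
  tab
}

#' Write a two-receptor activity table to CSV
#'
#' Inverse of [read_activity_csv()]: censored entries are re-encoded as
#' `">bound"`, so write-then-read round-trips losslessly.
#'
#' @param table Data frame from [read_activity_csv()] (or same shape).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_activity_csv <- function(table, path) {
  out <- table
  enc <- function(val, cens) ifelse(cens, paste0(">", trim_num(val)),
                                    trim_num(val))
  out$ec50_gcgr <- enc(table$ec50_gcgr, table$censored_gcgr)
  out$ec50_glp1r <- enc(table$ec50_glp1r, table$censored_glp1r)
  out$censored_gcgr <- NULL; out$censored_glp1r <- NULL
  for (col in intersect(c("sd_gcgr", "sd_glp1r"), names(out)))
    out[[col]] <- ifelse(is.na(out[[col]]), "", trim_num(out[[col]]))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

trim_num <- function(x) {
  ifelse(is.na(x), "", sub("0+$", "", sub("\\.$", "", format(x, trim = TRUE,
                                                             scientific = FALSE))))
}

#' Packaged activity-table fixtures
#'
#' `pdl_table2()` returns the packaged 35-peptide phage-derived activity
#' table; `pdl_table3()` the engineered-vs-parent comparison table (peptides
#' 11/36 and 16/37, with D-Ser and `γEγEC16` annotations). Both are verbatim
#' transcriptions of the published activity tables.
#'
#' @return A data frame (see [read_activity_csv()]).
#' @export
pdl_table2 <- function() {
  read_activity_csv(system.file("extdata", "table2_activity.csv",
                                package = "pdlkit", mustWork = TRUE))
}

#' @rdname pdl_table2
#' @export
pdl_table3 <- function() {
  read_activity_csv(system.file("extdata", "table3_activity.csv",
                                package = "pdlkit", mustWork = TRUE))
}

#' Read and write plain sequence FASTA
#'
#' Thin wrappers over Biostrings readers/writers. DNA is normalized to
#' uppercase (with a warning when lowercase input is encountered). Peptides
#' carrying D-residues or side-chain modifiers are not representable in
#' FASTA; use the activity CSV encoding for those.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_dna_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  seqs <- as.character(x)
  if (any(grepl("[acgt]", seqs))) {
    warning("lowercase DNA normalized to uppercase in ", path)
    seqs <- toupper(seqs)
  }
  if (!all(grepl("^[ACGTN]*$", seqs))) stop("non-DNA characters in ", path)
  seqs
}

#' @rdname read_dna_fasta
#' @export
read_peptide_fasta <- function(path) {
  seqs <- toupper(as.character(Biostrings::readBStringSet(path)))
  ok <- grepl(paste0("^[", paste(AA20, collapse = ""), "]*$"), seqs)
  if (!all(ok)) stop("non-standard residue codes in ", path)
  seqs
}

#' @rdname read_dna_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Serialize and restore selection pools
#'
#' Pools are written as TSV (mutation signature, count, latent potencies
#' where assigned) so selection runs can be inspected or resumed; a JSON
#' manifest records parameters and seeds.
#'
#' @param pool A `pool_state`.
#' @param path Output TSV path.
#' @return `path` (writers) or a `pool_state` (reader).
#' @export
write_pool_tsv <- function(pool, path) {
  stopifnot(inherits(pool, "pool_state"))
  v <- pool$variants
  v <- cbind(round = pool$round, v)
  utils::write.table(v, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pool_tsv
#' @param design The `doped_design` the pool was sampled from.
#' @export
read_pool_tsv <- function(path, design = NULL) {
  v <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE,
                         colClasses = c(sig = "character"))
  round <- if (nrow(v)) v$round[1] else 0L
  v$round <- NULL
  v$sig[is.na(v$sig)] <- ""
  new_pool_state(v, round = round, design = design)
}

#' Write a run manifest
#'
#' Records package version, configuration (echoed verbatim), seeds, and a
#' content hash so identical config + seed runs are verifiably identical.
#'
#' @param path Output JSON path.
#' @param config Configuration list to echo.
#' @param seeds Named or unnamed seed vector.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config = list(), seeds = integer(0)) {
  manifest <- list(
    package = "pdlkit",
    version = as.character(utils::packageVersion("pdlkit")),
    config = config,
    config_hash = unname(tools::md5sum(
      textConnection_hash(jsonlite::toJSON(config, auto_unbox = TRUE)))),
    seeds = as.list(seeds))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

## md5 of an in-memory string via a temp file (tools::md5sum is file-based)
textConnection_hash <- function(x) {
  tf <- tempfile()
  writeLines(as.character(x), tf)
  tf
}

#' Read a run configuration file
#'
#' YAML configuration with keys for the design (`parent`, `windows`,
#' `p_wt`, `n_alternatives`, `library_size`), simulation, classification
#' and output paths; all referenced files must exist at load.
#'
#' @param path YAML file.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  for (key in grep("_file$|_path$", names(cfg), value = TRUE))
    if (!file.exists(cfg[[key]]))
      stop("config references missing file: ", cfg[[key]])
  structure(cfg, class = c("run_config", class(cfg)))
}
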