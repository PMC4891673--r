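# Readers and writers for the package's plain-text dialects.
#
# Band matrix TSV: header `locus_id  <sample>_H  <sample>_M ...`, cells in
# {0, 1, NA}.  FASTA via Biostrings.  Reports as TSV plus JSON with a schema
# version, rows ordered deterministically.

REPORT_SCHEMA_VERSION <- "1.0"

#' Read an MSAP band matrix
#'
#' @param path TSV with a `locus_id` column and paired `<sample>_H` /
#'   `<sample>_M` presence columns (values 0, 1 or NA).
#' @return object of class `band_matrix`: list with `h` and `m` (loci x
#'   samples numeric matrices), `loci`, `samples`.
#' @export
read_band_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (names(df)[1] != "locus_id")
    stop("first column must be 'locus_id', got '", names(df)[1], "'")
  if (anyDuplicated(df$locus_id))
    stop("duplicate locus IDs: ",
         paste(unique(df$locus_id[duplicated(df$locus_id)]), collapse = ", "))
  cols <- names(df)[-1]
  hs <- grep("_H$", cols, value = TRUE)
  ms <- grep("_M$", cols, value = TRUE)
  samples_h <- sub("_H$", "", hs)
  samples_m <- sub("_M$", "", ms)
  if (!setequal(samples_h, samples_m) ||
      length(hs) + length(ms) != length(cols))
    stop("columns must be paired '<sample>_H'/'<sample>_M'")
  samples <- samples_h
  check_cell <- function(col, name) {
    x <- suppressWarnings(as.numeric(col))
    bad <- which((!is.na(col) & col != "NA" & is.na(x)) |
                 (!is.na(x) & !(x %in% c(0, 1))))
    if (length(bad))
      stop(sprintf("non-binary cell in column '%s', row %d (locus '%s'): '%s'",
                   name, bad[1], df$locus_id[bad[1]], col[bad[1]]))
    x
  }
  h <- sapply(samples, function(s) check_cell(df[[paste0(s, "_H")]],
                                              paste0(s, "_H")))
  m <- sapply(samples, function(s) check_cell(df[[paste0(s, "_M")]],
                                              paste0(s, "_M")))
  h <- matrix(h, ncol = length(samples),
              dimnames = list(df$locus_id, samples))
  m <- matrix(m, ncol = length(samples),
              dimnames = list(df$locus_id, samples))
  structure(list(h = h, m = m, loci = df$locus_id, samples = samples),
            class = "band_matrix")
}

#' @export
print.band_matrix <- function(x, ...) {
  cat(sprintf("band matrix: %d loci x %d samples (%s)\n",
              length(x$loci), length(x$samples),
              paste(utils::head(x$samples, 5), collapse = ", ")))
  invisible(x)
}

#' Write an MSAP band matrix
#'
#' @param bm a `band_matrix` (or a list with `h`/`m` matrices).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_band_matrix <- function(bm, path) {
  samples <- colnames(bm$h)
  out <- data.frame(locus_id = rownames(bm$h), check.names = FALSE)
  for (s in samples) {
    out[[paste0(s, "_H")]] <- bm$h[, s]
    out[[paste0(s, "_M")]] <- bm$m[, s]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Methylation states of every cell of a band matrix
#'
#' @param bm a `band_matrix`.
#' @return loci x samples character matrix over [MSAP_STATES] (`NA` where
#'   either lane is unscored).
#' @export
band_states <- function(bm) {
  st <- msap_state(as.vector(bm$h), as.vector(bm$m))
  matrix(st, nrow = nrow(bm$h), dimnames = dimnames(bm$h))
}

#' Convert state calls to a band matrix
#'
#' @param states loci x samples character state matrix.
#' @return a `band_matrix`.
#' @export
states_to_band_matrix <- function(states) {
  if (!is.matrix(states)) states <- as.matrix(states)
  calls <- state_bands(as.vector(states))
  structure(list(
    h = matrix(calls$h, nrow = nrow(states), dimnames = dimnames(states)),
    m = matrix(calls$m, nrow = nrow(states), dimnames = dimnames(states)),
    loci = rownames(states), samples = colnames(states)),
    class = "band_matrix")
}

#' Read a FASTA file of DNA sequences
#'
#' @param path FASTA path (wrapped or unwrapped).
#' @return named character vector of uppercase sequences.
#' @export
read_dna_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  out <- toupper(as.character(set))
  names(out) <- ids
  out
}

#' Write named sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dna_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a result table as TSV plus JSON
#'
#' Rows are ordered deterministically (first column, then second) and the
#' JSON carries a schema version, so rewriting the same results is
#' byte-identical.
#'
#' @param df data.frame of results.
#' @param stem output path without extension.
#' @return character vector of the two paths written, invisibly.
#' @export
write_report <- function(df, stem) {
  if (ncol(df) >= 2L) df <- df[order(df[[1]], df[[2]]), , drop = FALSE]
  else if (ncol(df) == 1L) df <- df[order(df[[1]]), , drop = FALSE]
  tsv <- paste0(stem, ".tsv")
  js <- paste0(stem, ".json")
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(schema_version = REPORT_SCHEMA_VERSION,
                            rows = df),
                       js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv, js))
}

#' Default run configuration
#'
#' All analysis thresholds live here; stage code takes them from the config
#' rather than hard-coding them.
#'
#' @param ... overrides of the defaults.
#' @return a named list of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    alpha = 0.05,          # significance level, level test and DE adjusted p
    lfc = 1,               # |log2 fold change| threshold for DE
    clone_identity = 0.9,  # bisulfite clone acceptance identity
    pseudocount = 0.5,     # cpm pseudocount for fold changes
    seed = 1,
    outdir = ".",
    stages = c("score", "patterns", "inherit", "bisulfite", "sirna"))
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  .validate_config(structure(cfg, class = "run_config"))
}

.validate_config <- function(cfg) {
  stopifnot(cfg$alpha > 0, cfg$alpha < 1, cfg$lfc >= 0,
            cfg$clone_identity >= 0, cfg$clone_identity <= 1,
            cfg$pseudocount >= 0)
  cfg
}

#' Read / write a run configuration file
#'
#' Plain `key = value` text; vectors comma-separated.  Round-trips
#' losslessly through [write_config()].
#'
#' @param path config file path.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, integer(1)) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, `[`, character(1), 2)
  parse_val <- function(v) {
    parts <- trimws(strsplit(v, ",")[[1]])
    num <- suppressWarnings(as.numeric(parts))
    if (!anyNA(num)) num else parts
  }
  do.call(default_config, stats::setNames(lapply(vals, parse_val), keys))
}

#' @rdname read_config
#' @param cfg a `run_config`.
#' @export
write_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(k)
    paste0(k, " = ", paste(cfg[[k]], collapse = ",")), character(1))
  writeLines(lines, path)
  invisible(path)
}
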