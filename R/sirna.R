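# siRNA differential expression and siRNA-to-DMF sequence matching.
#
# Counts from small-RNA libraries (two pooled biological replicates per
# condition) are compared between a reference and a later generation with a
# pooled exact binomial test: under the null the pooled count of a sequence
# splits between the two groups in proportion to their library sizes.
# Differential sequences (|log2FC| >= 1, BH-adjusted p < 0.05) are matched
# to differentially methylated fragment (DMF) sequences by exact substring
# search on both strands, the verifiable core of the RdDM locus question.

#' Counts per million
#'
#' @param counts numeric vector/matrix of raw counts.
#' @param library_sizes total reads per library (recycled across rows for a
#'   matrix); must be positive.
#' @return counts scaled to reads per million library reads.
#' @export
cpm <- function(counts, library_sizes) {
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  if (is.matrix(counts)) {
    if (length(library_sizes) != ncol(counts))
      stop("one library size per column required")
    sweep(counts, 2, library_sizes, "/") * 1e6
  } else counts / library_sizes * 1e6
}

#' Differential expression of siRNAs between two library groups
#'
#' For each sequence, counts are pooled within each group.  log2 fold change
#' is computed on pooled cpm with a pseudocount (default 0.5 cpm, applied to
#' the fold change only, not the test).  The p-value is a two-sided exact
#' binomial test of the group-A pooled count against the library-size
#' proportional null; Benjamini-Hochberg adjustment is applied over all
#' tested sequences.  Direction is `UP`/`DOWN` (in group A relative to B)
#' when `|log2FC| >= lfc` and adjusted p `< alpha`, else `NS`.
#'
#' @param counts data.frame with columns `sequence`, `length`, and one raw
#'   count column per library.
#' @param group_a,group_b character vectors of library column names.
#' @param library_sizes named numeric vector of total reads per library
#'   (defaults to column sums of `counts`).
#' @param pseudocount cpm pseudocount for the fold change.
#' @param lfc,alpha differential-expression thresholds.
#' @return data.frame: `sequence`, `length`, `cpm_a`, `cpm_b`,
#'   `log2_fold_change`, `p_value`, `adjusted_p`, `direction`.  Sequences
#'   with zero counts in every library are excluded.
#' @export
de_sirna <- function(counts, group_a, group_b, library_sizes = NULL,
                     pseudocount = 0.5, lfc = 1, alpha = 0.05) {
  stopifnot(is.data.frame(counts),
            all(c("sequence", "length") %in% names(counts)))
  libs <- c(group_a, group_b)
  missing_libs <- setdiff(libs, names(counts))
  if (length(missing_libs))
    stop("library column(s) absent: ", paste(missing_libs, collapse = ", "))
  if (length(group_a) < 1L || length(group_b) < 1L)
    stop("each group needs >= 1 library")
  mat <- as.matrix(counts[, libs, drop = FALSE])
  if (any(mat < 0) || anyNA(mat)) stop("counts must be non-negative")
  if (is.null(library_sizes)) library_sizes <- colSums(mat)
  if (is.null(names(library_sizes))) names(library_sizes) <- libs
  if (any(library_sizes[libs] <= 0)) stop("library sizes must be positive")
  size_a <- sum(library_sizes[group_a])
  size_b <- sum(library_sizes[group_b])
  pooled_a <- rowSums(mat[, group_a, drop = FALSE])
  pooled_b <- rowSums(mat[, group_b, drop = FALSE])
  keep <- pooled_a + pooled_b > 0
  cpm_a <- pooled_a / size_a * 1e6
  cpm_b <- pooled_b / size_b * 1e6
  l2fc <- log2((cpm_a + pseudocount) / (cpm_b + pseudocount))
  p0 <- size_a / (size_a + size_b)
  pv <- rep(NA_real_, nrow(mat))
  pv[keep] <- vapply(which(keep), function(i)
    stats::binom.test(pooled_a[i], pooled_a[i] + pooled_b[i], p0)$p.value,
    numeric(1))
  out <- data.frame(sequence = counts$sequence, length = counts$length,
                    cpm_a = cpm_a, cpm_b = cpm_b,
                    log2_fold_change = l2fc, p_value = pv,
                    stringsAsFactors = FALSE)[keep, ]
  out$adjusted_p <- stats::p.adjust(out$p_value, method = "BH")
  out$direction <- ifelse(out$adjusted_p < alpha & out$log2_fold_change >= lfc,
                          "UP",
                   ifelse(out$adjusted_p < alpha & out$log2_fold_change <= -lfc,
                          "DOWN", "NS"))
  rownames(out) <- NULL
  out
}

#' Reverse complement of DNA/RNA strings
#'
#' U is normalised to T first.
#' @param x character vector of sequences.
#' @return character vector of reverse complements (DNA alphabet).
#' @export
revcomp <- function(x) {
  x <- chartr("Uu", "Tt", x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Match siRNA sequences to DMF sequences
#'
#' Exact substring search (optionally with a mismatch tolerance) of each
#' siRNA, and of its reverse complement, against every DMF sequence.  U is
#' treated as T.  All occurrences are reported.
#'
#' @param sirnas character vector of siRNA sequences (names optional).
#' @param dmfs named character vector (or `DNAStringSet`) of DMF sequences.
#' @param max_mismatch allowed mismatches (default 0 = exact).
#' @return data.frame: `sirna`, `dmf`, `offset` (0-based start within the
#'   DMF), `strand` (`+`/`-`), `length`.
#' @export
match_to_dmfs <- function(sirnas, dmfs, max_mismatch = 0) {
  sirnas <- toupper(chartr("Uu", "Tt", as.character(sirnas)))
  dmf_names <- names(dmfs)
  dmfs <- toupper(as.character(dmfs))
  names(dmfs) <- dmf_names
  if (is.null(names(dmfs)) || any(!nzchar(names(dmfs))))
    stop("DMF sequences must be named")
  if (any(grepl("[^ACGT]", dmfs)))
    stop("DMF sequences must be over A, C, G, T")
  subjects <- lapply(dmfs, Biostrings::DNAString)
  hits <- list()
  for (s in unique(sirnas)) {
    for (strand in c("+", "-")) {
      q <- if (strand == "+") s else revcomp(s)
      for (d in names(dmfs)) {
        m <- Biostrings::matchPattern(q, subjects[[d]],
                                      max.mismatch = max_mismatch)
        if (length(m) > 0L)
          hits[[length(hits) + 1L]] <- data.frame(
            sirna = s, dmf = d,
            offset = Biostrings::start(m) - 1L, strand = strand,
            length = nchar(s), stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(sirna = character(), dmf = character(),
                      offset = integer(), strand = character(),
                      length = integer(), stringsAsFactors = FALSE)
  out[order(out$dmf, out$offset, out$sirna), , drop = FALSE]
}

#' Per-length summary of matched siRNAs
#'
#' Counts distinct matched siRNA sequences per length; the 24-nt class is
#' flagged as the size class acting in RNA-directed DNA methylation.
#'
#' @param matches output of [match_to_dmfs()].
#' @return data.frame `length`, `n_sirnas`, `rddm_class` (TRUE for 24 nt);
#'   zero rows for empty input.
#' @export
length_stratify <- function(matches) {
  if (nrow(matches) == 0L)
    return(data.frame(length = integer(), n_sirnas = integer(),
                      rddm_class = logical()))
  uniq <- unique(matches[, c("sirna", "length")])
  tab <- table(uniq$length)
  data.frame(length = as.integer(names(tab)),
             n_sirnas = as.integer(tab),
             rddm_class = as.integer(names(tab)) == 24L)
}
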