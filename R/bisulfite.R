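# Bisulfite clone analysis: context assignment, conversion-aware alignment,
# per-cytosine methylation calls and per-context summaries.
#
# Bisulfite treatment deaminates unmethylated cytosine to uracil (read as T)
# while 5-methylcytosine stays C.  A Sanger clone of a PCR amplicon of the
# treated top strand therefore reads C at methylated reference-C positions
# and T at unmethylated ones.  Plant methylation is summarised per sequence
# context: CG, CHG and CHH (H = A, C or T), assigned from the untreated
# reference sequence.

BS_CONTEXTS <- c("CG", "CHG", "CHH")

#' Assign CG/CHG/CHH contexts to every cytosine of a reference amplicon
#'
#' Contexts are read from the reference (never from clones): `CG` if the next
#' base is G, `CHG` if the pattern is C-H-G, `CHH` if C-H-H (H = A, C or T).
#' A cytosine within 2 bases of the 3' end whose context cannot be resolved
#' is flagged end-indeterminate (`context` NA) and excluded from calling.
#'
#' @param sequence reference DNA string (unconverted, top strand) over ACGT.
#' @param region_id amplicon label.
#' @return an object of class `amplicon`: list with `region_id`, `sequence`,
#'   and `cytosines`, a data.frame with `pos` (1-based), `context`
#'   (`NA` = indeterminate) and `indeterminate`.
#' @examples
#' assign_contexts("CCGG")$cytosines  # pos 1 CHG, pos 2 CG
#' @export
assign_contexts <- function(sequence, region_id = "region") {
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) < 3L) stop("sequence shorter than 3 bases")
  bases <- strsplit(sequence, "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop("non-ACGT character in reference sequence")
  cpos <- which(bases == "C")
  n <- length(bases)
  context <- character(length(cpos))
  for (k in seq_along(cpos)) {
    i <- cpos[k]
    b1 <- if (i + 1L <= n) bases[i + 1L] else NA_character_
    b2 <- if (i + 2L <= n) bases[i + 2L] else NA_character_
    context[k] <-
      if (is.na(b1)) NA_character_              # last base: CG vs CH* unknown
      else if (b1 == "G") "CG"
      else if (is.na(b2)) NA_character_         # C-H-? at the end
      else if (b2 == "G") "CHG"
      else "CHH"
  }
  structure(
    list(region_id = as.character(region_id), sequence = sequence,
         cytosines = data.frame(pos = cpos, context = context,
                                indeterminate = is.na(context))),
    class = "amplicon")
}

#' @export
print.amplicon <- function(x, ...) {
  tab <- table(factor(x$cytosines$context, levels = BS_CONTEXTS))
  cat(sprintf("amplicon '%s': %d bp, %d cytosines (CG %d, CHG %d, CHH %d, indeterminate %d)\n",
              x$region_id, nchar(x$sequence), nrow(x$cytosines),
              tab[["CG"]], tab[["CHG"]], tab[["CHH"]],
              sum(x$cytosines$indeterminate)))
  invisible(x)
}

# Conversion-aware substitution matrix: clone T is a free match to reference
# C (the bisulfite read of an unmethylated C); everything else standard.
.bs_submat <- function(match = 1, mismatch = -2) {
  ab <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(ab, ab))
  diag(m) <- match
  m["T", "C"] <- match  # pattern (clone) T vs subject (reference) C
  m["N", ] <- 0
  m[, "N"] <- 0
  m
}

#' Align one bisulfite clone to its reference amplicon and call cytosines
#'
#' Global pairwise alignment (affine gaps) with conversion-aware scoring: a
#' clone T opposite a reference C costs nothing, so fully converted
#' unmethylated clones align as perfect matches.  At every determinate
#' reference cytosine the aligned clone base is read as `METHYLATED` (C),
#' `UNMETHYLATED` (T) or `AMBIGUOUS` (gap, N, or any other base).  Clones
#' below the identity threshold under conversion-aware scoring are rejected.
#'
#' @param amplicon an [assign_contexts()] object.
#' @param clone clone DNA string (bisulfite read of the amplicon top strand).
#' @param min_identity clone acceptance threshold on conversion-aware
#'   identity (matching columns / reference length), default 0.9.
#' @return list with `accepted`, `identity`, and `calls`, a data.frame
#'   (`pos`, `context`, `call`); `calls` is `NULL` for rejected clones.
#' @export
align_clone <- function(amplicon, clone, min_identity = 0.9) {
  stopifnot(inherits(amplicon, "amplicon"))
  clone <- toupper(as.character(clone))
  if (!nzchar(clone)) stop("empty clone sequence")
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(clone),
    subject = Biostrings::DNAString(amplicon$sequence),
    substitutionMatrix = .bs_submat(), gapOpening = 10, gapExtension = 4,
    type = "global")
  pat <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  # map alignment columns to reference positions
  ref_pos <- cumsum(sub != "-")
  match_col <- sub != "-" & pat != "-" &
    (pat == sub | (sub == "C" & pat == "T"))
  # N columns are uninformative, not evidence against the clone
  n_col <- sum(sub != "-" & pat == "N")
  identity <- sum(match_col) / max(1L, nchar(amplicon$sequence) - n_col)
  if (identity < min_identity)
    return(list(accepted = FALSE, identity = identity, calls = NULL))
  det <- amplicon$cytosines[!amplicon$cytosines$indeterminate, ]
  call <- character(nrow(det))
  for (k in seq_len(nrow(det))) {
    col <- which(ref_pos == det$pos[k] & sub != "-")
    base <- if (length(col) == 1L) pat[col] else "-"
    call[k] <- if (base == "C") "METHYLATED"
               else if (base == "T") "UNMETHYLATED"
               else "AMBIGUOUS"
  }
  list(accepted = TRUE, identity = identity,
       calls = data.frame(pos = det$pos, context = det$context, call = call,
                          stringsAsFactors = FALSE))
}

#' Call all clones of a region
#'
#' @param amplicon an [assign_contexts()] object.
#' @param clones named character vector or `DNAStringSet` of clone reads.
#' @param min_identity passed to [align_clone()].
#' @return an object of class `clone_calls`: list with `region_id`, `calls`
#'   (long data.frame: `clone`, `pos`, `context`, `call`), `rejected`
#'   (named identities of rejected clones) and `n_clones` accepted.
#' @export
call_clones <- function(amplicon, clones, min_identity = 0.9) {
  stopifnot(inherits(amplicon, "amplicon"))
  clone_names <- names(clones)
  clones <- as.character(clones)
  names(clones) <- clone_names
  if (length(clones) == 0L) stop("no clones supplied")
  if (is.null(names(clones)) || any(!nzchar(names(clones))))
    names(clones) <- sprintf("clone%02d", seq_along(clones))
  res <- lapply(clones, align_clone, amplicon = amplicon,
                min_identity = min_identity)
  acc <- vapply(res, `[[`, logical(1), "accepted")
  calls <- do.call(rbind, lapply(names(clones)[acc], function(id) {
    cbind(clone = id, res[[id]]$calls, stringsAsFactors = FALSE)
  }))
  if (is.null(calls))
    calls <- data.frame(clone = character(), pos = integer(),
                        context = character(), call = character())
  structure(
    list(region_id = amplicon$region_id, calls = calls,
         rejected = vapply(res[!acc], `[[`, numeric(1), "identity"),
         n_clones = sum(acc)),
    class = "clone_calls")
}

#' Per-context methylation summary of a region
#'
#' Pools calls over clones: per context, percentage methylated among scored
#' (non-ambiguous) calls, plus the overall percentage.  A context with no
#' scored call reports `NA`.
#'
#' @param calls a [call_clones()] object.
#' @return data.frame with rows CG, CHG, CHH, overall: `context`,
#'   `methylated`, `total`, `pct` (half-up, 2 decimals).
#' @export
summarize_region <- function(calls) {
  stopifnot(inherits(calls, "clone_calls"))
  if (calls$n_clones == 0L) stop("no accepted clones")
  scored <- calls$calls[calls$calls$call != "AMBIGUOUS", ]
  row <- function(ctx, sub) {
    meth <- sum(sub$call == "METHYLATED")
    tot <- nrow(sub)
    data.frame(context = ctx, methylated = meth, total = tot,
               pct = if (tot > 0) round_half_up(100 * meth / tot, 2)
                     else NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(BS_CONTEXTS, function(ctx)
    row(ctx, scored[scored$context == ctx, ])))
  rbind(out, row("overall", scored))
}

#' Per-context difference between two region summaries
#'
#' @param a,b [summarize_region()] outputs for the same amplicon in two
#'   samples.
#' @return data.frame `context`, `pct_a`, `pct_b`, `diff` (= a - b,
#'   percentage points; `NA` propagates).
#' @export
compare_regions <- function(a, b) {
  stopifnot(identical(a$context, b$context))
  data.frame(context = a$context, pct_a = a$pct, pct_b = b$pct,
             diff = round_half_up(a$pct - b$pct, 2))
}

#' Bisulfite conversion efficiency estimate
#'
#' Treats designated contexts (default CHH, rarely methylated in plants) as
#' truly unmethylated, so every C call there is a conversion failure:
#' rate = T calls / scored calls in those contexts.
#'
#' @param calls a [call_clones()] object.
#' @param contexts contexts assumed unmethylated.
#' @return list with `rate`, `converted`, `total`.
#' @export
conversion_efficiency <- function(calls, contexts = "CHH") {
  stopifnot(inherits(calls, "clone_calls"))
  sub <- calls$calls[calls$calls$context %in% contexts &
                     calls$calls$call != "AMBIGUOUS", ]
  total <- nrow(sub)
  converted <- sum(sub$call == "UNMETHYLATED")
  list(rate = if (total > 0) converted / total else NA_real_,
       converted = converted, total = total)
}

#' Text lollipop matrix of clone calls
#'
#' One row per clone, one column per determinate cytosine: `*` methylated,
#' `o` unmethylated, `?` ambiguous.
#'
#' @param calls a [call_clones()] object.
#' @return character vector, one element per clone, named by clone.
#' @export
lollipop_text <- function(calls) {
  stopifnot(inherits(calls, "clone_calls"))
  sym <- c(METHYLATED = "*", UNMETHYLATED = "o", AMBIGUOUS = "?")
  vapply(split(calls$calls, calls$calls$clone), function(d) {
    paste(sym[d$call[order(d$pos)]], collapse = "")
  }, character(1))
}
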