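# Transgenerational inheritance of uniform DMF variant states.
#
# After the first selfed generation (GS1) fixes a variant methylation state
# at a uDMF locus, later selfed generations (GS2..GS5) are scored for the
# same locus.  The inheritance ratio of a generation is the fraction of its
# assayed individuals that still carry the GS1 variant state; a locus is
# STABLE when every generation retains it in all individuals, LOST when the
# variant is absent from every individual of the final generation, and
# REVERTING otherwise.

#' Inheritance ratio of a variant state in one generation panel
#'
#' @param states character vector of per-individual states at one locus
#'   (`NA` = unscored individual, excluded from the denominator).
#' @param variant_state the GS1 variant state to look for.  "Retained" means
#'   the state equals the variant exactly; any other state, including a third
#'   state, counts as not retained.
#' @return list with `retained`, `n`, `pct` (half-up, 2 decimals).
#' @examples
#' inheritance_ratio(c(rep("I", 13), "III", "III"), "I")$pct  # 86.67
#' @export
inheritance_ratio <- function(states, variant_state) {
  states <- .check_state(states)
  variant_state <- .check_state(variant_state, allow_na = FALSE)
  scored <- !is.na(states)
  n <- sum(scored)
  if (n == 0L) stop("no scored individuals")
  retained <- sum(states[scored] == variant_state)
  list(retained = retained, n = n, pct = round_half_up(100 * retained / n, 2))
}

#' Classify the stability of an inheritance series
#'
#' @param pcts numeric vector of per-generation retention percentages, in
#'   generation order (earliest first).
#' @param final_retained number of final-generation individuals carrying the
#'   variant; defaults to treating a final percentage of 0 as absence.
#' @return `"STABLE"` (every percentage is 100), `"LOST"` (variant absent
#'   from the final generation), else `"REVERTING"`.
#' @export
classify_stability <- function(pcts, final_retained = NULL) {
  if (length(pcts) == 0L || anyNA(pcts)) stop("empty or NA ratio series")
  if (is.null(final_retained))
    final_retained <- if (pcts[length(pcts)] == 0) 0L else NA_integer_
  if (all(pcts == 100)) return("STABLE")
  if (!is.na(final_retained) && final_retained == 0L) return("LOST")
  "REVERTING"
}

#' Track a set of uDMF loci across generation panels
#'
#' @param manifest data.frame with columns `locus`, `ref_state` (reference
#'   plant state) and `variant_state` (the GS1 state to track).
#' @param panels named list of generation panels, in generation order; each
#'   panel a loci x individuals character state matrix whose rownames cover
#'   the manifest loci.
#' @return data.frame with one row per locus: `locus`, `ref_state`,
#'   `variant_state`, one `pct_<generation>` column per panel, and `verdict`.
#'   Retained/n counts are kept in the `"ratios"` attribute (long format).
#' @export
track_inheritance <- function(manifest, panels) {
  stopifnot(is.data.frame(manifest),
            all(c("locus", "ref_state", "variant_state") %in% names(manifest)),
            is.list(panels), length(panels) >= 1L)
  if (is.null(names(panels)) || any(names(panels) == ""))
    names(panels) <- sprintf("G%d", seq_along(panels))
  long <- list()
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    locus <- manifest$locus[i]
    pcts <- numeric(0)
    final_retained <- NA_integer_
    for (g in names(panels)) {
      panel <- panels[[g]]
      if (!locus %in% rownames(panel))
        stop(sprintf("locus '%s' absent from panel '%s'", locus, g))
      r <- inheritance_ratio(panel[locus, ], manifest$variant_state[i])
      pcts[g] <- r$pct
      final_retained <- r$retained
      long[[length(long) + 1L]] <<- data.frame(
        locus = locus, generation = g, retained = r$retained, n = r$n,
        pct = r$pct, stringsAsFactors = FALSE)
    }
    out <- data.frame(locus = locus, ref_state = manifest$ref_state[i],
                      variant_state = manifest$variant_state[i],
                      stringsAsFactors = FALSE)
    for (g in names(panels)) out[[paste0("pct_", g)]] <- pcts[[g]]
    out$verdict <- classify_stability(pcts, final_retained)
    out
  })
  res <- do.call(rbind, rows)
  attr(res, "ratios") <- do.call(rbind, long)
  res
}

#' Summarise inheritance verdicts
#'
#' @param verdicts character vector of verdicts (`STABLE`/`REVERTING`/`LOST`),
#'   e.g. the `verdict` column of [track_inheritance()] or
#'   [read_inheritance_table()].
#' @param total_dmfs optionally, the total number of DMFs (uniform and
#'   distinctive) in the study, to express stably inherited loci as a
#'   fraction of all methylation changes.
#' @return list with `n`, `stable`, `reverting`, `lost`,
#'   `stable_pct_of_udmfs`, and (if `total_dmfs` given) `stable_pct_of_dmfs`;
#'   percentages half-up to 2 decimals.
#' @export
summarize_inheritance <- function(verdicts, total_dmfs = NULL) {
  if (length(verdicts) == 0L) stop("no verdicts")
  bad <- setdiff(unique(verdicts), c("STABLE", "REVERTING", "LOST"))
  if (length(bad)) stop("unknown verdict(s): ", paste(bad, collapse = ", "))
  n <- length(verdicts)
  stable <- sum(verdicts == "STABLE")
  out <- list(n = n, stable = stable,
              reverting = sum(verdicts == "REVERTING"),
              lost = sum(verdicts == "LOST"),
              stable_pct_of_udmfs = round_half_up(100 * stable / n, 2))
  if (!is.null(total_dmfs))
    out$stable_pct_of_dmfs <- round_half_up(100 * stable / total_dmfs, 2)
  out
}

#' Read a printed uDMF inheritance table
#'
#' Parses a TSV in the layout of a published inheritance table: one row per
#' uDMF locus, reference and variant band calls as `"(h, m)"` pairs, and one
#' column per generation transition holding either `"pct (retained/n)"` or a
#' bare percentage (in which case `retained/n` is reconstructed from the
#' panel size: `pct/100 * n`).  A parsed cell whose percentage disagrees
#' with its `retained/n` pair is an error.
#'
#' @param path TSV path.  Lines starting with `#` are comments.
#' @param panel_sizes integer vector, assayed individuals per generation
#'   column (recycled check for parenthetical cells; used to reconstruct
#'   counts for bare-percentage cells).
#' @return data.frame: `locus`, `ref_state`, `variant_state`, then per
#'   generation `pct_*`, `retained_*`, `n_*` columns, and `verdict`.
#' @export
read_inheritance_table <- function(path, panel_sizes = c(15L, 15L, 10L, 10L)) {
  raw <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("empty inheritance table: ", path)
  gen_cols <- names(raw)[-(1:3)]
  if (length(gen_cols) != length(panel_sizes))
    stop(sprintf("%d generation columns but %d panel sizes",
                 length(gen_cols), length(panel_sizes)))
  out <- data.frame(locus = raw[[1]],
                    ref_state = .parse_band_pair(raw[[2]]),
                    variant_state = .parse_band_pair(raw[[3]]),
                    stringsAsFactors = FALSE)
  final_retained <- NULL
  for (k in seq_along(gen_cols)) {
    cell <- .parse_ratio_cell(raw[[gen_cols[k]]], panel_sizes[k], gen_cols[k])
    out[[paste0("pct_", gen_cols[k])]] <- cell$pct
    out[[paste0("retained_", gen_cols[k])]] <- cell$retained
    out[[paste0("n_", gen_cols[k])]] <- cell$n
    final_retained <- cell$retained
  }
  pct_cols <- paste0("pct_", gen_cols)
  out$verdict <- vapply(seq_len(nrow(out)), function(i)
    classify_stability(as.numeric(out[i, pct_cols]), final_retained[i]),
    character(1))
  out
}

# "(0, 1)" -> state code via msap_state
.parse_band_pair <- function(x) {
  m <- regmatches(x, regexec("^\\s*\\(\\s*([01])\\s*,\\s*([01])\\s*\\)\\s*$", x))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) stop("malformed band pair: ", x[bad][1])
  h <- as.integer(vapply(m, `[`, character(1), 2))
  mm <- as.integer(vapply(m, `[`, character(1), 3))
  msap_state(h, mm)
}

# "86.67 (13/15)" or "100.00" -> pct / retained / n
.parse_ratio_cell <- function(x, panel_size, col) {
  x <- trimws(x)
  with_counts <- grepl("\\(", x)
  pct <- retained <- n <- numeric(length(x))
  m <- regmatches(x, regexec(
    "^([0-9.]+)\\s*\\(\\s*([0-9]+)\\s*/\\s*([0-9]+)\\s*\\)$", x))
  for (i in seq_along(x)) {
    if (with_counts[i]) {
      if (length(m[[i]]) != 4L)
        stop(sprintf("malformed cell '%s' in column %s", x[i], col))
      pct[i] <- as.numeric(m[[i]][2])
      retained[i] <- as.integer(m[[i]][3])
      n[i] <- as.integer(m[[i]][4])
      if (round_half_up(100 * retained[i] / n[i], 2) != pct[i])
        stop(sprintf(
          "inconsistent cell '%s' in column %s: %d/%d is not %.2f%%",
          x[i], col, retained[i], n[i], pct[i]))
    } else {
      pct[i] <- as.numeric(x[i])
      if (is.na(pct[i]))
        stop(sprintf("malformed cell '%s' in column %s", x[i], col))
      n[i] <- panel_size
      retained[i] <- round(pct[i] / 100 * n[i])
    }
  }
  list(pct = pct, retained = as.integer(retained), n = as.integer(n))
}
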