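# Population-level methylation pattern transitions and DMF partitioning.
#
# A DMF (differentially methylated fragment) is an MSAP locus whose state in
# at least one progeny individual differs from the reference plant.  DMFs
# changed identically in every individual are "uniform" (uDMF); the rest are
# "distinctive" (dDMF).

.check_population <- function(ref_states, population) {
  if (!is.matrix(population))
    population <- as.matrix(population)
  if (length(ref_states) != nrow(population))
    stop(sprintf("locus panel mismatch: reference has %d loci, population %d",
                 length(ref_states), nrow(population)))
  if (ncol(population) < 1L) stop("population needs >= 1 individual")
  if (is.null(rownames(population)))
    rownames(population) <- sprintf("locus%04d", seq_len(nrow(population)))
  if (is.null(colnames(population)))
    colnames(population) <- sprintf("ind%d", seq_len(ncol(population)))
  storage.mode(population) <- "character"
  .check_state(population)
  .check_state(ref_states)
  population
}

#' Per-individual transition records against a reference
#'
#' Classifies every (locus, individual) state against the reference state of
#' the locus.  Pairs with an unscored state on either side are dropped.
#'
#' @param ref_states character vector of reference states, one per locus.
#' @param population loci x individuals character matrix of states.
#' @return data.frame with columns `locus`, `individual`, `ref_state`,
#'   `sample_state`, `class`.
#' @export
transition_records <- function(ref_states, population) {
  population <- .check_population(ref_states, population)
  df <- data.frame(
    locus = rep(rownames(population), ncol(population)),
    individual = rep(colnames(population), each = nrow(population)),
    ref_state = rep(as.character(ref_states), ncol(population)),
    sample_state = as.vector(population),
    stringsAsFactors = FALSE)
  df <- df[!is.na(df$ref_state) & !is.na(df$sample_state), ]
  df$class <- classify_transition(df$ref_state, df$sample_state)
  rownames(df) <- NULL
  df
}

#' Per-individual transition-class frequency table
#'
#' For each individual, the percentage of its scored loci in each transition
#' class.  Denominator: all loci scored in both that individual and the
#' reference (the published convention divides by the total band count).
#'
#' @inheritParams transition_records
#' @return data.frame with one row per individual: `individual`, `n_scored`,
#'   one count and one `pct_*` column per class in [TRANSITION_CLASSES].
#' @export
population_pattern_table <- function(ref_states, population) {
  rec <- transition_records(ref_states, population)
  inds <- unique(rec$individual)
  rows <- lapply(inds, function(id) {
    r <- rec[rec$individual == id, ]
    n <- nrow(r)
    counts <- vapply(TRANSITION_CLASSES,
                     function(cl) sum(r$class == cl), integer(1))
    out <- data.frame(individual = id, n_scored = n, stringsAsFactors = FALSE)
    for (cl in TRANSITION_CLASSES) out[[tolower(cl)]] <- counts[[cl]]
    for (cl in TRANSITION_CLASSES)
      out[[paste0("pct_", tolower(cl))]] <- round_half_up(100 * counts[[cl]] / n, 2)
    out
  })
  do.call(rbind, rows)
}

#' Identify DMFs and partition them into uniform vs distinctive
#'
#' A locus is a DMF iff at least one scored individual's state differs from
#' the reference.  A DMF is uniform (`uDMF`) iff every scored individual
#' differs from the reference *and* all individuals share a single state;
#' otherwise it is distinctive (`dDMF`).  Loci with an unscored reference are
#' skipped.
#'
#' @inheritParams transition_records
#' @return data.frame with one row per DMF: `locus`, `ref_state`,
#'   `uniformity` (`"uDMF"`/`"dDMF"`), `variant_state` (the shared variant
#'   state for uDMFs, `NA` for dDMFs), `n_changed`, `n_scored`, and `states`
#'   (comma-separated per-individual states, in column order).
#' @export
identify_dmfs <- function(ref_states, population) {
  population <- .check_population(ref_states, population)
  ref_states <- as.character(ref_states)
  rows <- lapply(seq_len(nrow(population)), function(i) {
    ref <- ref_states[i]
    if (is.na(ref)) return(NULL)
    states <- population[i, ]
    scored <- !is.na(states)
    if (!any(scored)) return(NULL)
    differs <- states[scored] != ref
    if (!any(differs)) return(NULL)
    uniform <- all(differs) && length(unique(states[scored])) == 1L
    data.frame(
      locus = rownames(population)[i],
      ref_state = ref,
      uniformity = if (uniform) "uDMF" else "dDMF",
      variant_state = if (uniform) states[scored][1] else NA_character_,
      n_changed = sum(differs),
      n_scored = sum(scored),
      states = paste(ifelse(is.na(states), ".", states), collapse = ","),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(locus = character(), ref_state = character(),
                      uniformity = character(), variant_state = character(),
                      n_changed = integer(), n_scored = integer(),
                      states = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summarise a DMF partition
#'
#' @param dmfs output of [identify_dmfs()].
#' @return list with `n_dmf`, `n_udmf`, `n_ddmf`, `udmf_pct` (uniform DMFs as
#'   a percentage of all DMFs, rounded half-up to 2 decimals).
#' @export
summarize_dmfs <- function(dmfs) {
  n <- nrow(dmfs)
  nu <- sum(dmfs$uniformity == "uDMF")
  list(n_dmf = n, n_udmf = nu, n_ddmf = n - nu,
       udmf_pct = if (n > 0) round_half_up(100 * nu / n, 2) else NA_real_)
}
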