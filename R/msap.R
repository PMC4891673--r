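# Per-sample methylation-level statistics from MSAP state calls.

#' Build a per-sample methylation profile
#'
#' Counts the loci of one sample in each of the four MSAP states.  Unscored
#' loci (`NA`) are recorded but excluded from the state counts, so
#' `sum(counts) + n_unscored == n_loci`.
#'
#' @param states character vector of per-locus states over [MSAP_STATES]
#'   (`NA` = unscored), e.g. one column of [band_states()].
#' @param sample_id sample label.
#' @return an object of class `msap_profile`: list with `sample_id`,
#'   `counts` (named integer vector over I-IV), `n_loci`, `n_unscored`.
#' @examples
#' msap_profile(c("I", "I", "III", NA), "toy")
#' @export
msap_profile <- function(states, sample_id = "sample") {
  if (length(states) == 0L) stop("empty state column")
  states <- .check_state(states)
  counts <- vapply(MSAP_STATES, function(s) sum(states == s, na.rm = TRUE),
                   integer(1))
  structure(
    list(sample_id = as.character(sample_id), counts = counts,
         n_loci = length(states), n_unscored = sum(is.na(states))),
    class = "msap_profile")
}

#' Build a profile directly from printed band-type counts
#'
#' Convenience constructor when only the per-type counts are available
#' (e.g. a published summary table), not the per-locus calls.
#'
#' @param counts numeric vector of length 4, counts of types I-IV.
#' @inheritParams msap_profile
#' @return an `msap_profile`.
#' @export
msap_profile_from_counts <- function(counts, sample_id = "sample") {
  if (length(counts) != 4L || any(is.na(counts)) || any(counts < 0))
    stop("`counts` must be 4 non-negative type counts (I, II, III, IV)")
  counts <- as.integer(counts)
  names(counts) <- MSAP_STATES
  structure(
    list(sample_id = as.character(sample_id), counts = counts,
         n_loci = sum(counts), n_unscored = 0L),
    class = "msap_profile")
}

#' @export
print.msap_profile <- function(x, ...) {
  cat(sprintf("MSAP profile '%s': %d loci (%d unscored)\n",
              x$sample_id, x$n_loci, x$n_unscored))
  print(x$counts)
  invisible(x)
}

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; published MSAP tables use
#' conventional half-up rounding (45.675 -> 45.68).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # the 1e-9 guards against 1.005 * 100 representing as 100.49999...
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Total and fully methylated ratios of a profile
#'
#' Total methylated bands are types II + III + IV; fully methylated bands are
#' types III + IV.  Each ratio is the band count divided by all scored bands
#' (I + II + III + IV), times 100.  Reported percentages are rounded half-up
#' to 2 decimals; the exact values are kept in the `total_ratio_exact` /
#' `full_ratio_exact` fields for downstream computation.
#'
#' @param profile an [msap_profile()].
#' @return an object of class `msap_ratios`: list with
#'   `total_methylated_bands`, `total_ratio_pct`, `full_methylated_bands`,
#'   `full_ratio_pct`, plus unrounded `*_exact` fields and `n_scored`.
#' @examples
#' p <- msap_profile_from_counts(c(489, 140, 292, 5), "TTT")
#' methylation_ratios(p)$total_ratio_pct  # 47.19
#' @export
methylation_ratios <- function(profile) {
  stopifnot(inherits(profile, "msap_profile"))
  n <- sum(profile$counts)
  if (n == 0L) stop("no scored loci in profile ", profile$sample_id)
  total <- sum(profile$counts[c("II", "III", "IV")])
  full <- sum(profile$counts[c("III", "IV")])
  structure(
    list(sample_id = profile$sample_id,
         n_scored = n,
         total_methylated_bands = total,
         total_ratio_pct = round_half_up(100 * total / n, 2),
         total_ratio_exact = 100 * total / n,
         full_methylated_bands = full,
         full_ratio_pct = round_half_up(100 * full / n, 2),
         full_ratio_exact = 100 * full / n),
    class = "msap_ratios")
}

#' @export
print.msap_ratios <- function(x, ...) {
  cat(sprintf(
    "'%s': total methylated %d/%d (%.2f%%), fully methylated %d/%d (%.2f%%)\n",
    x$sample_id, x$total_methylated_bands, x$n_scored, x$total_ratio_pct,
    x$full_methylated_bands, x$n_scored, x$full_ratio_pct))
  invisible(x)
}

#' Compare the methylation levels of two samples
#'
#' Tests whether the fraction of methylated bands (types II + III + IV versus
#' type I) differs between two samples, on a 2 x 2 contingency table.  The
#' default is Fisher's exact test (no distributional assumption, exact at any
#' count); chi-square is available as an option.
#'
#' @param ref,other [msap_profile()]s on the same locus panel.
#' @param method `"fisher"` (default) or `"chisq"`.
#' @param alpha significance level for the `significant` flag.
#' @return list with `statistic` (odds ratio for Fisher, X-squared for
#'   chi-square), `p_value`, `significant`, `method` and the underlying
#'   `table`.
#' @examples
#' ttt <- msap_profile_from_counts(c(489, 140, 292, 5), "TTT")
#' gs1 <- msap_profile_from_counts(c(503, 135, 283, 5), "GS1-1")
#' compare_levels(ttt, gs1)$significant  # FALSE
#' @export
compare_levels <- function(ref, other, method = c("fisher", "chisq"),
                           alpha = 0.05) {
  stopifnot(inherits(ref, "msap_profile"), inherits(other, "msap_profile"))
  method <- match.arg(method)
  if (sum(ref$counts) == 0L || sum(other$counts) == 0L)
    stop("profile with zero scored loci")
  if (ref$n_loci != other$n_loci)
    stop(sprintf("locus panels differ: %d vs %d loci",
                 ref$n_loci, other$n_loci))
  tab <- rbind(
    methylated = c(sum(ref$counts[c("II", "III", "IV")]),
                   sum(other$counts[c("II", "III", "IV")])),
    unmethylated = c(ref$counts[["I"]], other$counts[["I"]]))
  colnames(tab) <- c(ref$sample_id, other$sample_id)
  res <- if (method == "fisher") {
    ft <- stats::fisher.test(tab)
    list(statistic = unname(ft$estimate), p_value = ft$p.value)
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab))
    list(statistic = unname(ct$statistic), p_value = ct$p.value)
  }
  c(res, list(significant = res$p_value < alpha, method = method,
              alpha = alpha, table = tab))
}

#' Consensus call over technical replicate matrices
#'
#' MSAP gels are typically run in technical replicates; this reduces
#' replicate presence/absence matrices to a consensus by per-cell majority
#' vote.  Ties (possible with an even number of scored replicates) and cells
#' unscored in every replicate become unscored (`NA`).
#'
#' @param replicates list of numeric matrices of identical dimension with
#'   values in `{0, 1, NA}`.
#' @return a single consensus matrix of the same dimension.
#' @export
consensus_calls <- function(replicates) {
  if (!is.list(replicates) || length(replicates) == 0L)
    stop("`replicates` must be a non-empty list of matrices")
  dims <- lapply(replicates, dim)
  if (length(unique(dims)) != 1L)
    stop("replicate matrices differ in dimension")
  for (r in replicates) .check_binary(r, "replicate matrix")
  arr <- simplify2array(replicates)
  ones <- apply(arr, c(1, 2), function(v) sum(v == 1, na.rm = TRUE))
  zeros <- apply(arr, c(1, 2), function(v) sum(v == 0, na.rm = TRUE))
  out <- matrix(NA_real_, nrow(replicates[[1]]), ncol(replicates[[1]]),
                dimnames = dimnames(replicates[[1]]))
  out[ones > zeros] <- 1
  out[zeros > ones] <- 0
  out
}
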