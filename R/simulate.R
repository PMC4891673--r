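# Synthetic-data generators with machine-readable ground truth.
#
# Defaults are calibrated to the study design the package targets: a
# reference plant plus 7 first-generation individuals scored at 926 MSAP
# loci with ~8% changed loci of which ~42% change uniformly; selfed-
# generation panels of 15/15/10/10 plants; >= 10 bisulfite clones per
# sample; 18-30 nt siRNA libraries of ~1e6 siRNA reads.
#
# A single seed governs each generator; internally every stage of a
# generator draws under its own deterministically derived sub-seed, so the
# draws of one stage do not shift those of another if a stage is revised.

.with_subseed <- function(seed, k, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed((seed + 1000003L * k) %% .Machine$integer.max)
  expr
}

# states strictly below / above a state in methylation load
.demeth_targets <- list(I = character(0), II = "I", III = "I",
                        IV = c("I", "II", "III"))
.meth_targets <- list(I = c("II", "III", "IV"), II = "IV", III = "IV",
                      IV = character(0))

#' Simulate MSAP band matrices with planted DMFs
#'
#' Draws reference states from the given frequencies, plants state changes
#' at the induced-change rate, makes a fraction of them uniform (identical
#' in every individual) and the rest distinctive (changed in a random
#' non-empty proper subset of individuals), and returns the full ground
#' truth.
#'
#' Change direction is modelled as two per-locus event rates: loci that can
#' lose methylation (states II-IV) demethylate at rate `r_d`, loci that can
#' gain it (states I-III) methylate at rate `r_m`, with `r_d` and `r_m`
#' solved from `change_rate` and `demeth_odds` so that the expected changed
#' fraction equals `change_rate` and the expected ratio of demethylation to
#' methylation events equals `demeth_odds`.  (A rate conditioned only on
#' which directions a state allows could never make demethylation dominate
#' when most loci start unmethylated.)
#'
#' @param n_loci,n_individuals panel dimensions.
#' @param state_freqs frequencies of states I-IV in the reference (sums
#'   to 1); default matches a 926-locus profile with 47% total methylation.
#' @param change_rate per-locus probability of a planted change.
#' @param uniform_frac fraction of changed loci altered uniformly.
#' @param demeth_odds expected planted demethylation : methylation event
#'   odds across the panel.
#' @param seed integer seed.
#' @return list with `ref_states`, `population` (loci x individuals state
#'   matrix), `truth` (data.frame: `locus`, `ref_state`, `variant_state`,
#'   `uniformity`, `individuals`), and `params`.
#' @export
sim_band_matrices <- function(n_loci = 926, n_individuals = 7,
                              state_freqs = c(I = 489, II = 140, III = 292,
                                              IV = 5) / 926,
                              change_rate = 76 / 926,
                              uniform_frac = 32 / 76,
                              demeth_odds = 1.6,
                              seed = 1) {
  stopifnot(n_loci >= 1, n_individuals >= 2,
            abs(sum(state_freqs) - 1) < 1e-8,
            change_rate >= 0, change_rate <= 1,
            uniform_frac >= 0, uniform_frac <= 1, demeth_odds >= 0)
  loci <- sprintf("locus%04d", seq_len(n_loci))
  inds <- sprintf("ind%d", seq_len(n_individuals))
  ref <- .with_subseed(seed, 1L,
    sample(MSAP_STATES, n_loci, replace = TRUE, prob = state_freqs))
  # direction-conditioned event rates (see description)
  f <- state_freqs / sum(state_freqs)
  names(f) <- MSAP_STATES
  demeth_capable <- sum(f[c("II", "III", "IV")])
  meth_capable <- sum(f[c("I", "II", "III")])
  share_d <- demeth_odds / (1 + demeth_odds)
  r_d <- if (demeth_capable > 0) change_rate * share_d / demeth_capable else 0
  r_m <- if (meth_capable > 0) change_rate * (1 - share_d) / meth_capable else 0
  if (r_d + r_m > 1)
    stop("change_rate/demeth_odds imply per-locus event rates above 1; ",
         "reduce change_rate or rebalance state_freqs")
  changed <- .with_subseed(seed, 2L, {
    u <- stats::runif(n_loci)
    can_d <- ref %in% c("II", "III", "IV")
    can_m <- ref %in% c("I", "II", "III")
    goes_down <- can_d & u < r_d
    goes_up <- can_m & !goes_down & u >= r_d & u < r_d + r_m
    list(idx = which(goes_down | goes_up),
         down = goes_down[goes_down | goes_up])
  })
  pop <- matrix(rep(ref, n_individuals), ncol = n_individuals,
                dimnames = list(loci, inds))
  truth <- NULL
  if (length(changed$idx)) {
    plant <- .with_subseed(seed, 3L, {
      lapply(seq_along(changed$idx), function(k) {
        i <- changed$idx[k]
        pool <- if (changed$down[k]) .demeth_targets[[ref[i]]]
                else .meth_targets[[ref[i]]]
        variant <- if (length(pool) == 1L) pool else sample(pool, 1L)
        uniform <- stats::runif(1) < uniform_frac
        who <- if (uniform) seq_len(n_individuals)
               else sort(sample(n_individuals,
                                sample(n_individuals - 1L, 1L)))
        list(i = i, variant = variant, uniform = uniform, who = who)
      })
    })
    truth <- do.call(rbind, lapply(plant, function(p) {
      pop[p$i, p$who] <<- p$variant
      data.frame(locus = loci[p$i], ref_state = ref[p$i],
                 variant_state = p$variant,
                 uniformity = if (p$uniform) "uDMF" else "dDMF",
                 individuals = paste(inds[p$who], collapse = ","),
                 stringsAsFactors = FALSE)
    }))
  }
  if (is.null(truth))
    truth <- data.frame(locus = character(), ref_state = character(),
                        variant_state = character(), uniformity = character(),
                        individuals = character(), stringsAsFactors = FALSE)
  names(ref) <- loci
  list(ref_states = ref, population = pop, truth = truth,
       params = list(n_loci = n_loci, n_individuals = n_individuals,
                     state_freqs = state_freqs, change_rate = change_rate,
                     uniform_frac = uniform_frac, demeth_odds = demeth_odds,
                     seed = seed))
}

#' Simulate selfed-generation panels for uDMF inheritance
#'
#' Each individual of each generation independently reverts each tracked
#' locus to the reference state with the per-generation reversion
#' probability, otherwise carries the variant state.  The truth verdict is
#' `STABLE` iff no reversion was sampled at that locus in any generation.
#'
#' @param manifest data.frame with `locus`, `ref_state`, `variant_state`.
#' @param panel_sizes named integer vector of individuals per generation;
#'   default the 15/15/10/10 design.
#' @param reversion per-individual per-generation reversion probability.
#' @param seed integer seed.
#' @return list with `panels` (named list of loci x individuals state
#'   matrices), `truth` (data.frame `locus`, `verdict`, `n_reversions`),
#'   and `params`.
#' @export
sim_generation_panels <- function(manifest,
                                  panel_sizes = c(GS2 = 15L, GS3 = 15L,
                                                  GS4 = 10L, GS5 = 10L),
                                  reversion = 0.05, seed = 1) {
  stopifnot(is.data.frame(manifest), nrow(manifest) >= 1L,
            all(c("locus", "ref_state", "variant_state") %in% names(manifest)),
            all(panel_sizes >= 1L), reversion >= 0, reversion <= 1)
  panels <- list()
  nrev <- integer(nrow(manifest))
  final_all_reverted <- logical(nrow(manifest))
  for (k in seq_along(panel_sizes)) {
    g <- names(panel_sizes)[k]
    n <- panel_sizes[[k]]
    rev_mat <- .with_subseed(seed, k, {
      matrix(stats::runif(nrow(manifest) * n) < reversion,
             nrow = nrow(manifest))
    })
    panel <- matrix(rep(manifest$variant_state, n), ncol = n,
                    dimnames = list(manifest$locus,
                                    sprintf("%s_%02d", g, seq_len(n))))
    panel[rev_mat] <- matrix(rep(manifest$ref_state, n),
                             ncol = n)[rev_mat]
    panels[[g]] <- panel
    nrev <- nrev + rowSums(rev_mat)
    if (k == length(panel_sizes)) final_all_reverted <- rowSums(rev_mat) == n
  }
  truth <- data.frame(
    locus = manifest$locus,
    verdict = ifelse(nrev == 0L, "STABLE",
              ifelse(final_all_reverted, "LOST", "REVERTING")),
    n_reversions = nrev, stringsAsFactors = FALSE)
  list(panels = panels, truth = truth,
       params = list(panel_sizes = panel_sizes, reversion = reversion,
                     seed = seed))
}

#' Simulate a bisulfite amplicon and clone reads
#'
#' Draws a random reference amplicon, then per clone and per reference
#' cytosine a Bernoulli methylation call with the per-context probability;
#' unmethylated cytosines convert to T with the conversion rate (methylated
#' cytosines always read C).  Cytosines with indeterminate context at the
#' 3' end are treated as CHH for simulation.
#'
#' @param amplicon_length reference length in bp.
#' @param p_cg,p_chg,p_chh per-context methylation probabilities.
#' @param conversion bisulfite conversion rate of unmethylated C.
#' @param n_clones clone reads to generate.
#' @param seed integer seed.
#' @param region_id amplicon label.
#' @return list with `amplicon` (an [assign_contexts()] object), `clones`
#'   (named character vector), `truth` (list: params plus `methylation`,
#'   the clones x cytosine-positions logical matrix of true methylation).
#' @export
sim_bisulfite_clones <- function(amplicon_length = 300, p_cg = 0.8,
                                 p_chg = 0.4, p_chh = 0.1,
                                 conversion = 0.99, n_clones = 10,
                                 seed = 1, region_id = "sim_region") {
  stopifnot(amplicon_length >= 10, n_clones >= 1,
            all(c(p_cg, p_chg, p_chh, conversion) >= 0),
            all(c(p_cg, p_chg, p_chh, conversion) <= 1))
  seq <- .with_subseed(seed, 1L,
    paste(sample(c("A", "C", "G", "T"), amplicon_length, replace = TRUE),
          collapse = ""))
  amp <- assign_contexts(seq, region_id)
  cyt <- amp$cytosines
  p <- c(CG = p_cg, CHG = p_chg, CHH = p_chh)[
    ifelse(is.na(cyt$context), "CHH", cyt$context)]
  bases <- strsplit(seq, "")[[1]]
  sim <- .with_subseed(seed, 2L, {
    meth <- matrix(stats::runif(n_clones * nrow(cyt)) < rep(p, each = n_clones),
                   nrow = n_clones)
    conv <- matrix(stats::runif(n_clones * nrow(cyt)) < conversion,
                   nrow = n_clones)
    list(meth = meth, conv = conv)
  })
  clones <- vapply(seq_len(n_clones), function(j) {
    b <- bases
    read_t <- !sim$meth[j, ] & sim$conv[j, ]
    b[cyt$pos[read_t]] <- "T"
    paste(b, collapse = "")
  }, character(1))
  names(clones) <- sprintf("%s_clone%02d", region_id, seq_len(n_clones))
  dimnames(sim$meth) <- list(names(clones), cyt$pos)
  list(amplicon = amp, clones = clones,
       truth = list(p_cg = p_cg, p_chg = p_chg, p_chh = p_chh,
                    conversion = conversion, methylation = sim$meth,
                    seed = seed))
}

#' Simulate an siRNA count table with spiked fold changes
#'
#' Baseline per-sequence abundances are log-normal; per-library counts are
#' negative binomial around the library-size-scaled abundance with the given
#' dispersion.  A spiked subset is scaled by `2^spiked_log2fc` in group A.
#' When DMF sequences are supplied, spiked sequences are drawn as exact
#' substrings of them (24 nt by default), so planted records both test
#' differential calling and siRNA-to-DMF matching.
#'
#' @param n_records distinct siRNA sequences.
#' @param n_spiked spiked (truly differential) records.
#' @param spiked_log2fc true log2 fold change (group A over B) of spikes.
#' @param mean_count mean pooled baseline count per record per library.
#' @param dispersion negative-binomial dispersion (0 = Poisson).
#' @param library_sizes named vector; names define the libraries.
#' @param group_a,group_b library names of the two groups.
#' @param dmf_seqs optional named character vector of DMF sequences to plant
#'   spikes into.
#' @param planted_length length of planted spike sequences (nt).
#' @param seed integer seed.
#' @return list with `counts` (data.frame `sequence`, `length`, one column
#'   per library), `library_sizes`, `truth` (data.frame `sequence`,
#'   `length`, `true_log2fc`, `spiked`, `dmf`, `offset`), `group_a`,
#'   `group_b`, and `params`.
#' @export
sim_sirna_counts <- function(n_records = 2000, n_spiked = 0,
                             spiked_log2fc = 3, mean_count = 50,
                             dispersion = 0.1,
                             library_sizes = c(trt_a = 1e6, trt_b = 1e6,
                                               ref_a = 1e6, ref_b = 1e6),
                             group_a = c("trt_a", "trt_b"),
                             group_b = c("ref_a", "ref_b"),
                             dmf_seqs = NULL, planted_length = 24,
                             seed = 1) {
  stopifnot(n_records >= 1, n_spiked >= 0, n_spiked <= n_records,
            all(library_sizes > 0), dispersion >= 0,
            all(c(group_a, group_b) %in% names(library_sizes)))
  lens <- 18:30
  # size-class weights peaked at the 21- and 24-nt classes typical of
  # plant small-RNA libraries
  len_w <- c(1, 1, 2, 8, 3, 2, 10, 3, 2, 1, 1, 1, 1)
  sequences <- .with_subseed(seed, 1L, {
    out <- character(n_records)
    seen <- new.env(hash = TRUE)
    ls_draw <- sample(lens, n_records, replace = TRUE, prob = len_w)
    for (i in seq_len(n_records)) {
      repeat {
        s <- paste(sample(c("A", "C", "G", "T"), ls_draw[i], replace = TRUE),
                   collapse = "")
        if (is.null(seen[[s]])) { seen[[s]] <- TRUE; break }
      }
      out[i] <- s
    }
    out
  })
  spiked <- seq_len(n_spiked)
  dmf_of <- rep(NA_character_, n_records)
  offset <- rep(NA_integer_, n_records)
  if (n_spiked > 0 && !is.null(dmf_seqs)) {
    stopifnot(!is.null(names(dmf_seqs)),
              all(nchar(dmf_seqs) >= planted_length))
    planted <- .with_subseed(seed, 2L, {
      taken <- new.env(hash = TRUE)
      for (s in sequences) taken[[s]] <- TRUE
      lapply(spiked, function(i) {
        d <- names(dmf_seqs)[((i - 1L) %% length(dmf_seqs)) + 1L]
        maxoff <- nchar(dmf_seqs[[d]]) - planted_length
        for (try in 1:100) {
          off <- sample.int(maxoff + 1L, 1L) - 1L
          s <- substr(dmf_seqs[[d]], off + 1L, off + planted_length)
          if (is.null(taken[[s]])) break
          if (try == 100L)
            stop("cannot plant a unique substring of DMF '", d,
                 "' (sequence too repetitive)")
        }
        taken[[s]] <- TRUE
        list(d = d, off = off, s = s)
      })
    })
    for (k in seq_along(planted)) {
      sequences[spiked[k]] <- planted[[k]]$s
      dmf_of[spiked[k]] <- planted[[k]]$d
      offset[spiked[k]] <- planted[[k]]$off
    }
  }
  true_l2fc <- rep(0, n_records)
  true_l2fc[spiked] <- spiked_log2fc
  libs <- names(library_sizes)
  counts <- .with_subseed(seed, 3L, {
    base <- stats::rlnorm(n_records, meanlog = log(mean_count), sdlog = 1)
    mat <- matrix(0L, n_records, length(libs), dimnames = list(NULL, libs))
    for (lib in libs) {
      mu <- base * library_sizes[[lib]] / mean(library_sizes)
      if (lib %in% group_a) mu <- mu * 2^true_l2fc
      mat[, lib] <- if (dispersion > 0)
        stats::rnbinom(n_records, mu = mu, size = 1 / dispersion)
      else stats::rpois(n_records, mu)
    }
    mat
  })
  df <- data.frame(sequence = sequences, length = nchar(sequences),
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(counts))
  truth <- data.frame(sequence = sequences, length = nchar(sequences),
                      true_log2fc = true_l2fc,
                      spiked = seq_len(n_records) %in% spiked,
                      dmf = dmf_of, offset = offset,
                      stringsAsFactors = FALSE)
  list(counts = df, library_sizes = library_sizes, truth = truth,
       group_a = group_a, group_b = group_b,
       params = list(n_records = n_records, n_spiked = n_spiked,
                     spiked_log2fc = spiked_log2fc, mean_count = mean_count,
                     dispersion = dispersion, planted_length = planted_length,
                     seed = seed))
}
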