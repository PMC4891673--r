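# End-to-end orchestration and a subcommand-style CLI.

.log <- function(level, fmt, ...) {
  message(sprintf("[%s] %s %s", level,
                  format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order on one coherent set of
#' inputs: MSAP scoring -> pattern transitions / DMF partition ->
#' inheritance tracking, plus the independent bisulfite and siRNA branches.
#' With `inputs = NULL` a full synthetic data set is generated from the
#' config seed, so the default invocation exercises every stage against
#' known truth.  Reports (TSV + JSON) and a run manifest (inputs' checksums,
#' thresholds, seed, package version) are written under `cfg$outdir`.
#'
#' @param cfg a [default_config()] object.
#' @param inputs optional named list: `ref_states`, `population` (state
#'   matrix), `manifest` + `panels` (inheritance), `amplicon` + `clones`
#'   (bisulfite), `counts` + `library_sizes` + `group_a`/`group_b` +
#'   `dmf_seqs` (siRNA).  Missing pieces are simulated.
#' @return named list of per-stage results, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(cfg = default_config(), inputs = NULL) {
  cfg <- .validate_config(cfg)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  simulated <- is.null(inputs)
  if (simulated) {
    .log("INFO", "no inputs given: simulating full data set (seed %d)",
         cfg$seed)
    band <- sim_band_matrices(seed = cfg$seed)
    udmf <- band$truth[band$truth$uniformity == "uDMF", ]
    inputs <- list(
      ref_states = band$ref_states, population = band$population,
      manifest = udmf[, c("locus", "ref_state", "variant_state")],
      band_truth = band$truth)
    gen <- sim_generation_panels(inputs$manifest, seed = cfg$seed)
    inputs$panels <- gen$panels
    bs <- sim_bisulfite_clones(seed = cfg$seed)
    inputs$amplicon <- bs$amplicon
    inputs$clones <- bs$clones
    dmfs <- .with_subseed(cfg$seed, 99L,
      c(dmf1 = paste(sample(c("A", "C", "G", "T"), 300, TRUE),
                     collapse = "")))
    sir <- sim_sirna_counts(n_records = 500, n_spiked = 17,
                            dmf_seqs = dmfs, seed = cfg$seed)
    inputs$counts <- sir$counts
    inputs$library_sizes <- sir$library_sizes
    inputs$group_a <- sir$group_a
    inputs$group_b <- sir$group_b
    inputs$dmf_seqs <- dmfs
  }
  stages <- cfg$stages
  if ("score" %in% stages) {
    .log("INFO", "stage score")
    profiles <- lapply(colnames(inputs$population), function(s)
      msap_profile(inputs$population[, s], s))
    ratios <- do.call(rbind, lapply(profiles, function(p) {
      r <- methylation_ratios(p)
      data.frame(sample = p$sample_id, n_scored = r$n_scored,
                 total_methylated_bands = r$total_methylated_bands,
                 total_ratio_pct = r$total_ratio_pct,
                 full_methylated_bands = r$full_methylated_bands,
                 full_ratio_pct = r$full_ratio_pct)
    }))
    write_report(ratios, file.path(cfg$outdir, "methylation_levels"))
    res$score <- ratios
  }
  if ("patterns" %in% stages) {
    if (is.null(inputs$ref_states))
      stop("patterns stage needs `ref_states`; run or supply scoring inputs")
    .log("INFO", "stage patterns")
    freq <- population_pattern_table(inputs$ref_states, inputs$population)
    dmfs <- identify_dmfs(inputs$ref_states, inputs$population)
    write_report(freq, file.path(cfg$outdir, "pattern_frequencies"))
    write_report(dmfs, file.path(cfg$outdir, "dmfs"))
    res$patterns <- list(frequencies = freq, dmfs = dmfs,
                         summary = summarize_dmfs(dmfs))
  }
  if ("inherit" %in% stages) {
    if (is.null(inputs$manifest) || is.null(inputs$panels))
      stop("inherit stage needs `manifest` and `panels`")
    .log("INFO", "stage inherit")
    series <- track_inheritance(inputs$manifest, inputs$panels)
    write_report(series, file.path(cfg$outdir, "inheritance"))
    res$inherit <- list(series = series,
                        summary = summarize_inheritance(series$verdict))
  }
  if ("bisulfite" %in% stages) {
    if (is.null(inputs$amplicon) || is.null(inputs$clones))
      stop("bisulfite stage needs `amplicon` and `clones`")
    .log("INFO", "stage bisulfite")
    calls <- call_clones(inputs$amplicon, inputs$clones,
                         min_identity = cfg$clone_identity)
    summ <- summarize_region(calls)
    write_report(calls$calls, file.path(cfg$outdir, "bisulfite_calls"))
    write_report(summ, file.path(cfg$outdir, "bisulfite_summary"))
    res$bisulfite <- list(calls = calls, summary = summ,
                          conversion = conversion_efficiency(calls))
  }
  if ("sirna" %in% stages) {
    if (is.null(inputs$counts))
      stop("sirna stage needs `counts` (+ library sizes and groups)")
    .log("INFO", "stage sirna")
    de <- de_sirna(inputs$counts, inputs$group_a, inputs$group_b,
                   inputs$library_sizes, pseudocount = cfg$pseudocount,
                   lfc = cfg$lfc, alpha = cfg$alpha)
    write_report(de, file.path(cfg$outdir, "sirna_de"))
    res$sirna <- list(de = de)
    if (!is.null(inputs$dmf_seqs)) {
      sig <- de$sequence[de$direction != "NS"]
      matches <- match_to_dmfs(sig, inputs$dmf_seqs)
      write_report(matches, file.path(cfg$outdir, "sirna_dmf_matches"))
      res$sirna$matches <- matches
      res$sirna$by_length <- length_stratify(matches)
    }
  }
  manifest <- list(
    package = "epigraft",
    version = as.character(utils::packageVersion("epigraft")),
    config = unclass(cfg)[setdiff(names(cfg), "outdir")],
    simulated_inputs = simulated,
    stages_run = intersect(c("score", "patterns", "inherit", "bisulfite",
                             "sirna"), stages),
    output_checksums = as.list(tools::md5sum(
      list.files(cfg$outdir, pattern = "\\.(tsv|json)$", full.names = TRUE))))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

#' Subcommand command-line interface
#'
#' Entry point for the `inst/scripts/epigraft` wrapper.  Subcommands:
#' `score`, `patterns`, `inherit`, `bisulfite`, `sirna-de`, `match`,
#' `simulate`, `run`.  Options are `--key value` pairs; `--config FILE`
#' loads a [read_config()] file first, then flags override.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return exit status (0 on success), invisibly.
#' @export
epigraft_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: epigraft <subcommand> [--key value ...]",
    "subcommands:",
    "  score      --bands FILE [--out DIR]      methylation levels per sample",
    "  patterns   --bands FILE --ref SAMPLE [--out DIR]",
    "  inherit    --table FILE [--out DIR]      parse a printed uDMF table",
    "  bisulfite  --ref FILE --clones FILE [--out DIR]",
    "  sirna-de   --counts FILE --group-a A,B --group-b C,D [--out DIR]",
    "  match      --sirnas FILE --dmfs FILE [--out DIR]",
    "  simulate   [--seed N] [--out DIR]        full synthetic data set",
    "  run        [--config FILE] [--seed N] [--out DIR]",
    sep = "\n")
  if (length(args) == 0L || args[1] %in% c("-h", "--help")) {
    cat(usage, "\n")
    return(invisible(0L))
  }
  sub <- args[1]
  opts <- .parse_flags(args[-1])
  out <- opts[["out"]] %||% "."
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  status <- 0L
  switch(sub,
    score = {
      bm <- read_band_matrix(.need(opts, "bands"))
      st <- band_states(bm)
      ratios <- do.call(rbind, lapply(colnames(st), function(s) {
        r <- methylation_ratios(msap_profile(st[, s], s))
        data.frame(sample = s, total_ratio_pct = r$total_ratio_pct,
                   full_ratio_pct = r$full_ratio_pct)
      }))
      write_report(ratios, file.path(out, "methylation_levels"))
    },
    patterns = {
      bm <- read_band_matrix(.need(opts, "bands"))
      st <- band_states(bm)
      ref <- .need(opts, "ref")
      if (!ref %in% colnames(st)) stop("reference sample not found: ", ref)
      pop <- st[, setdiff(colnames(st), ref), drop = FALSE]
      write_report(population_pattern_table(st[, ref], pop),
                   file.path(out, "pattern_frequencies"))
      write_report(identify_dmfs(st[, ref], pop), file.path(out, "dmfs"))
    },
    inherit = {
      tab <- read_inheritance_table(.need(opts, "table"))
      write_report(tab, file.path(out, "inheritance"))
    },
    bisulfite = {
      refs <- read_dna_fasta(.need(opts, "ref"))
      clones <- read_dna_fasta(.need(opts, "clones"))
      amp <- assign_contexts(refs[[1]], names(refs)[1])
      calls <- call_clones(amp, clones)
      write_report(summarize_region(calls),
                   file.path(out, "bisulfite_summary"))
    },
    "sirna-de" = {
      counts <- utils::read.delim(.need(opts, "counts"), check.names = FALSE)
      ga <- strsplit(.need(opts, "group-a"), ",")[[1]]
      gb <- strsplit(.need(opts, "group-b"), ",")[[1]]
      write_report(de_sirna(counts, ga, gb), file.path(out, "sirna_de"))
    },
    match = {
      sirnas <- read_dna_fasta(.need(opts, "sirnas"))
      dmfs <- read_dna_fasta(.need(opts, "dmfs"))
      write_report(match_to_dmfs(sirnas, dmfs),
                   file.path(out, "sirna_dmf_matches"))
    },
    simulate = {
      seed <- as.integer(opts[["seed"]] %||% 1)
      band <- sim_band_matrices(seed = seed)
      write_band_matrix(states_to_band_matrix(band$population),
                        file.path(out, "population_bands.tsv"))
      write_band_matrix(states_to_band_matrix(
        matrix(band$ref_states, ncol = 1,
               dimnames = list(names(band$ref_states), "reference"))),
        file.path(out, "reference_bands.tsv"))
      bs <- sim_bisulfite_clones(seed = seed)
      write_dna_fasta(stats::setNames(bs$amplicon$sequence,
                                      bs$amplicon$region_id),
                      file.path(out, "amplicon.fasta"))
      write_dna_fasta(bs$clones, file.path(out, "clones.fasta"))
      sir <- sim_sirna_counts(n_records = 500, n_spiked = 17, seed = seed)
      utils::write.table(sir$counts, file.path(out, "sirna_counts.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(
        list(band = band$truth, sirna = sir$truth),
        file.path(out, "truth.json"), auto_unbox = TRUE, pretty = TRUE,
        digits = NA)
    },
    run = {
      cfg <- if (!is.null(opts[["config"]])) read_config(opts[["config"]])
             else default_config()
      if (!is.null(opts[["seed"]])) cfg$seed <- as.integer(opts[["seed"]])
      cfg$outdir <- out
      run_pipeline(cfg)
    },
    {
      cat(usage, "\n")
      status <- 2L
    })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.parse_flags <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      stop("expected --flag, got: ", args[i])
    key <- substring(args[i], 3)
    if (i == length(args) || startsWith(args[i + 1L], "--"))
      stop("flag --", key, " needs a value")
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}

.need <- function(opts, key) {
  if (is.null(opts[[key]])) stop("missing required flag --", key)
  opts[[key]]
}
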