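test_that("band matrix TSV round-trips with validation", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "bands.tsv")
  writeLines(c("locus_id\ts1_H\ts1_M\ts2_H\ts2_M",
               "L1\t1\t1\t0\t1",
               "L2\t1\t0\tNA\t1",
               "L3\t0\t0\t1\t1"), path)
  bm <- read_band_matrix(path)
  expect_equal(bm$loci, c("L1", "L2", "L3"))
  expect_equal(bm$samples, c("s1", "s2"))
  st <- band_states(bm)
  expect_equal(unname(st[, "s1"]), c("I", "II", "IV"))
  expect_true(is.na(st["L2", "s2"]))  # NA lane -> unscored
  # unscored cells are excluded from profile counts
  p <- msap_profile(st[, "s2"], "s2")
  expect_equal(sum(p$counts), 2L)
  # write/read round trip preserves calls
  out <- file.path(dir, "bands2.tsv")
  write_band_matrix(bm, out)
  bm2 <- read_band_matrix(out)
  expect_equal(bm2$h, bm$h)
  expect_equal(bm2$m, bm$m)
  # states -> band matrix -> states round trip
  bm3 <- states_to_band_matrix(st)
  expect_equal(band_states(bm3), st)
})

test_that("malformed band matrices are rejected with context", {
  dir <- withr::local_tempdir()
  bad <- file.path(dir, "bad.tsv")
  writeLines(c("locus_id\ts1_H\ts1_M", "L1\t2\t1"), bad)
  expect_error(read_band_matrix(bad), "non-binary.*s1_H.*L1")
  writeLines(c("locus_id\ts1_H\ts1_M", "L1\t1\t1", "L1\t0\t0"), bad)
  expect_error(read_band_matrix(bad), "duplicate locus")
  writeLines(c("locus_id\ts1_H\ts2_M", "L1\t1\t1"), bad)
  expect_error(read_band_matrix(bad), "paired")
  writeLines(c("id\ts1_H\ts1_M", "L1\t1\t1"), bad)
  expect_error(read_band_matrix(bad), "locus_id")
})

test_that("FASTA IO validates and round-trips", {
  dir <- withr::local_tempdir()
  fa <- file.path(dir, "x.fasta")
  write_dna_fasta(c(r1 = "ACGTACGT", r2 = "TTTTCCCC"), fa)
  seqs <- read_dna_fasta(fa)
  expect_equal(length(seqs), 2L)
  expect_equal(seqs[["r1"]], "ACGTACGT")
  writeLines(c(">a", "ACGT", ">a", "TTTT"), fa)
  expect_error(read_dna_fasta(fa), "duplicate")
  writeLines(character(0), fa)
  expect_error(read_dna_fasta(fa), "empty")
})

test_that("reports are deterministic and carry a schema version", {
  dir <- withr::local_tempdir()
  df <- data.frame(locus = c("b", "a"), sample = c("x", "y"), value = 1:2)
  p1 <- file.path(dir, "r1")
  p2 <- file.path(dir, "r2")
  write_report(df, p1)
  write_report(df[2:1, ], p2)  # same rows, different input order
  expect_identical(readLines(paste0(p1, ".tsv")),
                   readLines(paste0(p2, ".tsv")))
  expect_identical(readLines(paste0(p1, ".json")),
                   readLines(paste0(p2, ".json")))
  js <- jsonlite::read_json(paste0(p1, ".json"))
  expect_equal(js$schema_version, REPORT_SCHEMA_VERSION)
})

test_that("config round-trips and validates thresholds", {
  dir <- withr::local_tempdir()
  cfg <- default_config(alpha = 0.01, seed = 9)
  path <- file.path(dir, "run.cfg")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(cfg2$alpha, 0.01)
  expect_equal(cfg2$seed, 9)
  expect_equal(cfg2$stages, cfg$stages)
  expect_error(default_config(alpha = 2))
  expect_error(default_config(nonsense = 1), "unknown config key")
})

test_that("pipeline runs end to end on simulated inputs, deterministically", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  res <- run_pipeline(default_config(seed = 5, outdir = dir1))
  expect_true(all(c("score", "patterns", "inherit", "bisulfite", "sirna")
                  %in% names(res)))
  expect_true(file.exists(file.path(dir1, "methylation_levels.tsv")))
  expect_true(file.exists(file.path(dir1, "run_manifest.json")))
  # recovery against the simulator truth built into the default run
  band <- sim_band_matrices(seed = 5)
  expect_setequal(res$patterns$dmfs$locus, band$truth$locus)
  # reruns with the same seed are identical
  res2 <- run_pipeline(default_config(seed = 5, outdir = dir2))
  for (f in c("methylation_levels.tsv", "dmfs.tsv", "inheritance.tsv",
              "bisulfite_summary.tsv", "sirna_de.tsv"))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)),
                     info = f)
  # disabling a stage removes its outputs; downstream errors are clear
  dir3 <- withr::local_tempdir()
  run_pipeline(default_config(seed = 5, outdir = dir3,
                              stages = c("score", "patterns")))
  expect_false(file.exists(file.path(dir3, "sirna_de.tsv")))
  expect_error(
    run_pipeline(default_config(stages = "inherit"),
                 inputs = list(ref_states = "I",
                               population = matrix("I", 1, 1))),
    "needs `manifest`")
})

test_that("CLI subcommands run against files", {
  dir <- withr::local_tempdir()
  simdir <- file.path(dir, "sim")
  expect_equal(suppressMessages(
    epigraft_cli(c("simulate", "--seed", "3", "--out", simdir))), 0L)
  expect_true(file.exists(file.path(simdir, "population_bands.tsv")))
  expect_true(file.exists(file.path(simdir, "truth.json")))
  outdir <- file.path(dir, "score")
  expect_equal(suppressMessages(epigraft_cli(
    c("score", "--bands", file.path(simdir, "population_bands.tsv"),
      "--out", outdir))), 0L)
  levels <- utils::read.delim(file.path(outdir, "methylation_levels.tsv"))
  expect_equal(nrow(levels), 7L)
  expect_equal(suppressMessages(epigraft_cli(
    c("inherit", "--table", inheritance_fixture(), "--out",
      file.path(dir, "inh")))), 0L)
  expect_error(epigraft_cli(c("score", "--out", dir)), "--bands")
  expect_equal(epigraft_cli(c("nope")), 2L)
})
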