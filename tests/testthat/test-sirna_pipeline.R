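test_that("cpm normalisation", {
  expect_equal(cpm(10, 1e6), 10)
  expect_equal(cpm(0, 1e6), 0)
  expect_equal(cpm(5, 2e6), 2.5)
  expect_error(cpm(5, 0), "positive")
  m <- cpm(matrix(c(10, 20, 10, 20), 2), c(1e6, 2e6))
  expect_equal(m[, 2], c(5, 10))
})

test_that("differential calls follow the pooled binomial + BH contract", {
  counts <- data.frame(
    sequence = c("AAAA", "CCCC", "GGGG"), length = rep(20L, 3),
    a1 = c(50, 100, 0), a2 = c(50, 0, 0),
    b1 = c(50, 15, 0), b2 = c(50, 10, 0))
  de <- de_sirna(counts, c("a1", "a2"), c("b1", "b2"),
                 library_sizes = c(a1 = 1e6, a2 = 1e6, b1 = 1e6, b2 = 1e6))
  # the all-zero record is excluded
  expect_equal(nrow(de), 2L)
  # equal cpm in both groups: log2FC 0, NS
  eq <- de[de$sequence == "AAAA", ]
  expect_equal(eq$log2_fold_change, 0)
  expect_equal(eq$direction, "NS")
  # pooled 100 vs 25 at equal sizes: log2FC = 2 (pseudocount-shifted)
  up <- de[de$sequence == "CCCC", ]
  expect_equal(up$log2_fold_change, log2(50.5 / 13), tolerance = 1e-12)
  expect_equal(up$p_value,
               binom.test(100, 125, 0.5)$p.value, tolerance = 1e-12)
  # direction antisymmetry: swapping groups flips UP <-> DOWN
  de_sw <- de_sirna(counts, c("b1", "b2"), c("a1", "a2"),
                    library_sizes = c(a1 = 1e6, a2 = 1e6, b1 = 1e6, b2 = 1e6))
  expect_equal(de_sw$log2_fold_change, -de$log2_fold_change)
  expect_error(de_sirna(counts, "a1", "nope"), "absent")
})

test_that("BH adjustment is monotone in p", {
  sim <- sim_sirna_counts(n_records = 400, n_spiked = 40, seed = 21)
  de <- de_sirna(sim$counts, sim$group_a, sim$group_b, sim$library_sizes)
  ord <- order(de$p_value)
  expect_true(all(diff(de$adjusted_p[ord]) >= -1e-12))
  # equal p => equal adjusted p
  expect_equal(length(unique(de$adjusted_p[de$p_value == 1])),
               if (any(de$p_value == 1)) 1L else 0L)
})

test_that("null calibration and planted-signal power", {
  # null: Poisson sampling, identical groups
  sim0 <- sim_sirna_counts(n_records = 2000, n_spiked = 0, dispersion = 0,
                           seed = 33)
  de0 <- de_sirna(sim0$counts, sim0$group_a, sim0$group_b,
                  sim0$library_sizes)
  expect_lte(mean(de0$p_value < 0.05), 0.075)
  expect_true(mean(de0$direction != "NS") <= 0.05)
  # power: |log2FC| = 3 spikes at mean count 200 are all called UP
  simp <- sim_sirna_counts(n_records = 500, n_spiked = 25,
                           spiked_log2fc = 3, mean_count = 200, seed = 34)
  dep <- de_sirna(simp$counts, simp$group_a, simp$group_b,
                  simp$library_sizes)
  spiked_seq <- simp$truth$sequence[simp$truth$spiked]
  expect_true(all(dep$direction[dep$sequence %in% spiked_seq] == "UP"))
})

test_that("substring matching is exact, two-stranded and verifiable", {
  dmf <- paste(rep(c("A", "C", "G", "T"), 75), collapse = "")  # 300-mer
  dmfs <- c(dmf1 = dmf)
  s <- substr(dmf, 11, 34)  # offset 10, 24-mer
  m <- match_to_dmfs(s, dmfs)
  expect_true(any(m$offset == 10 & m$strand == "+"))
  # reverse complement matches on the minus strand
  m2 <- match_to_dmfs(revcomp(s), dmfs)
  expect_true(any(m2$strand == "-"))
  # U is treated as T
  m3 <- match_to_dmfs(chartr("T", "U", s), dmfs)
  expect_true(nrow(m3) >= 1L)
  # every reported match verifies by direct substring comparison
  for (i in seq_len(nrow(m))) {
    q <- if (m$strand[i] == "+") m$sirna[i] else revcomp(m$sirna[i])
    expect_equal(substr(dmfs[[m$dmf[i]]], m$offset[i] + 1,
                        m$offset[i] + nchar(q)), q)
  }
  # random 24-mer vs random 300-mer: brute-force confirms no hit
  set.seed(77)
  rand24 <- paste(sample(c("A", "C", "G", "T"), 24, TRUE), collapse = "")
  rand300 <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  m4 <- match_to_dmfs(rand24, c(d = rand300))
  brute <- any(vapply(1:(300 - 24 + 1), function(o)
    substr(rand300, o, o + 23) %in% c(rand24, revcomp(rand24)), logical(1)))
  expect_equal(nrow(m4) > 0, brute)
  expect_equal(nrow(m4), 0L)
})

test_that("length stratification counts distinct matched sequences", {
  m <- data.frame(sirna = c("A", "B", "B", "C"), dmf = "d",
                  offset = 0:3, strand = "+",
                  length = c(21L, 24L, 24L, 24L))
  ls <- length_stratify(m)
  expect_equal(ls$n_sirnas[ls$length == 21], 1L)
  expect_equal(ls$n_sirnas[ls$length == 24], 2L)  # B counted once
  expect_true(ls$rddm_class[ls$length == 24])
  expect_equal(nrow(length_stratify(m[0, ])), 0L)
})

test_that("planted DMF substrings are recovered end to end", {
  set.seed(55)
  dmfs <- c(uDMF9 = paste(sample(c("A", "C", "G", "T"), 300, TRUE),
                          collapse = ""))
  sim <- sim_sirna_counts(n_records = 300, n_spiked = 17,
                          spiked_log2fc = -3, mean_count = 200,
                          dmf_seqs = dmfs, planted_length = 24, seed = 56)
  de <- de_sirna(sim$counts, sim$group_a, sim$group_b, sim$library_sizes)
  sig <- de$sequence[de$direction != "NS"]
  matches <- match_to_dmfs(sig, dmfs)
  ls <- length_stratify(matches)
  expect_gte(ls$n_sirnas[ls$length == 24], 17L)
  planted <- sim$truth[sim$truth$spiked, ]
  expect_true(all(planted$sequence %in% matches$sirna))
  # planted offsets are reported among the hits
  for (i in seq_len(nrow(planted))) {
    hit <- matches[matches$sirna == planted$sequence[i], ]
    expect_true(planted$offset[i] %in% hit$offset)
  }
})
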