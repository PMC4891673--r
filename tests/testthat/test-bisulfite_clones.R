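test_that("context assignment follows the reference only", {
  amp <- assign_contexts("ACGT")
  expect_equal(amp$cytosines$pos, 2L)
  expect_equal(amp$cytosines$context, "CG")
  # CCGG: first C is C-H(C)-G -> CHG, second is CG
  amp2 <- assign_contexts("CCGG")
  expect_equal(amp2$cytosines$context, c("CHG", "CG"))
  expect_equal(assign_contexts("CTTA")$cytosines$context, "CHH")
  # 3'-end cytosines with unresolvable context are flagged
  amp3 <- assign_contexts("AAACT")  # C at position 4: C-T-? -> indeterminate
  expect_true(amp3$cytosines$indeterminate)
  amp4 <- assign_contexts("AAAAC")  # terminal C
  expect_true(amp4$cytosines$indeterminate)
  amp5 <- assign_contexts("AACG")   # terminal CG still resolvable
  expect_equal(amp5$cytosines$context, "CG")
  expect_error(assign_contexts("ACGN"), "non-ACGT")
  expect_error(assign_contexts("AC"), "shorter")
})

test_that("clone alignment reads conversion-aware calls", {
  amp <- assign_contexts("ACGTACAT")
  # both Cs read as T: fully converted, unmethylated
  r <- align_clone(amp, "ATGTATAT")
  expect_true(r$accepted)
  expect_equal(r$calls$call, c("UNMETHYLATED", "UNMETHYLATED"))
  expect_equal(r$calls$context, c("CG", "CHH"))
  # identical clone: every C methylated
  r2 <- align_clone(amp, "ACGTACAT")
  expect_equal(r2$calls$call, rep("METHYLATED", 2))
  # N at a C position is ambiguous
  r3 <- align_clone(amp, "ANGTACAT")
  expect_equal(r3$calls$call[1], "AMBIGUOUS")
  # junk clone rejected below the identity threshold
  r4 <- align_clone(amp, "GGGGGGGG")
  expect_false(r4$accepted)
  expect_null(r4$calls)
  # a 1-bp deletion elsewhere still yields calls at the C positions
  r5 <- align_clone(assign_contexts("ACGTAAAAAACAT"), "ACGTAAAAACAT",
                    min_identity = 0.8)
  expect_true(r5$accepted)
})

test_that("region summaries pool clone calls by context", {
  amp <- assign_contexts("ACGT")
  cc <- call_clones(amp, c(c1 = "ACGT", c2 = "ATGT"))
  s <- summarize_region(cc)
  expect_equal(s$pct[s$context == "CG"], 50)
  expect_true(is.na(s$pct[s$context == "CHH"]))  # no CHH sites
  expect_equal(s$total[s$context == "overall"],
               sum(s$total[s$context != "overall"]))
  # all clones methylated everywhere -> 100% each scored context
  sim <- sim_bisulfite_clones(p_cg = 1, p_chg = 1, p_chh = 1,
                              n_clones = 10, seed = 2)
  s2 <- summarize_region(call_clones(sim$amplicon, sim$clones))
  expect_true(all(s2$pct == 100))
  # no methylation + perfect conversion -> exactly 0% everywhere
  sim3 <- sim_bisulfite_clones(p_cg = 0, p_chg = 0, p_chh = 0,
                               conversion = 1, n_clones = 10, seed = 2)
  s3 <- summarize_region(call_clones(sim3$amplicon, sim3$clones))
  expect_true(all(s3$pct == 0))
})

test_that("generator probabilities recovered within binomial CIs at 50 clones", {
  p_true <- c(CG = 0.8, CHG = 0.4, CHH = 0.1)
  sim <- sim_bisulfite_clones(p_cg = p_true[["CG"]], p_chg = p_true[["CHG"]],
                              p_chh = p_true[["CHH"]], conversion = 1,
                              n_clones = 50, seed = 12)
  s <- summarize_region(call_clones(sim$amplicon, sim$clones))
  for (ctx in names(p_true)) {
    row <- s[s$context == ctx, ]
    ci <- binom.test(row$methylated, row$total)$conf.int
    expect_gte(p_true[[ctx]], ci[1])
    expect_lte(p_true[[ctx]], ci[2])
    # direct counting oracle on the simulator's own truth matrix
    cyt <- sim$amplicon$cytosines
    det <- !cyt$indeterminate & cyt$context == ctx
    expect_equal(row$methylated,
                 sum(sim$truth$methylation[, as.character(cyt$pos[det])]))
  }
})

test_that("region differences and conversion efficiency", {
  amp <- assign_contexts("ACGT")
  a <- summarize_region(call_clones(amp, c(x = "ACGT", y = "ACGT")))
  b <- summarize_region(call_clones(amp, c(x = "ATGT", y = "ACGT")))
  d <- compare_regions(a, b)
  expect_equal(d$diff[d$context == "CG"], 50)
  expect_equal(compare_regions(a, a)$diff[1], 0)
  expect_true(is.na(d$diff[d$context == "CHH"]))
  # conversion estimate within CI of the generator rate at pCHH = 0
  sim <- sim_bisulfite_clones(p_chh = 0, conversion = 0.99, n_clones = 50,
                              seed = 9)
  ce <- conversion_efficiency(call_clones(sim$amplicon, sim$clones))
  ci <- binom.test(ce$converted, ce$total)$conf.int
  expect_gte(0.99, ci[1])
  expect_lte(0.99, ci[2])
  # fully converted, unmethylated clones -> rate 1; all-methylated -> 0
  sim1 <- sim_bisulfite_clones(p_cg = 0, p_chg = 0, p_chh = 0,
                               conversion = 1, n_clones = 5, seed = 2)
  expect_equal(conversion_efficiency(
    call_clones(sim1$amplicon, sim1$clones))$rate, 1)
  sim0 <- sim_bisulfite_clones(p_cg = 1, p_chg = 1, p_chh = 1,
                               n_clones = 5, seed = 2)
  expect_equal(conversion_efficiency(
    call_clones(sim0$amplicon, sim0$clones))$rate, 0)
})

test_that("lollipop text renders one row per clone", {
  amp <- assign_contexts("ACGTACAT")
  lp <- lollipop_text(call_clones(amp, c(a = "ACGTACAT", b = "ATGTATAT")))
  expect_equal(unname(lp["a"]), "**")
  expect_equal(unname(lp["b"]), "oo")
})
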