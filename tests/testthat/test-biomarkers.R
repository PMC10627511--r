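test_that("max_vaf takes the maximum over SNV/indel calls only", {
  expect_equal(max_vaf(calls_fixture(c(0.02, 0.10, 0.07))), 0.10)
  expect_equal(max_vaf(calls_fixture(0.33)), 0.33)
  # no SNV/indel call: NA, and copy numbers never leak into the maximum
  cnv_only <- calls_fixture(c(4, 0.5), classes = c("CNG", "CNL"))
  expect_true(is.na(max_vaf(cnv_only)))
})

test_that("ctdna_fraction follows 2/(1/MAF + 1) and is monotone", {
  expect_equal(ctdna_fraction(0.5), 2 / 3)
  expect_equal(ctdna_fraction(1), 1)
  # the published 0.05 marker cut-off corresponds to MAF = 1/39
  expect_equal(ctdna_fraction(1 / 39), 0.05)
  v <- sort(runif(50, 0.001, 1))
  expect_true(all(diff(ctdna_fraction(v)) > 0))
  # limit toward 0+ is 0
  expect_lt(ctdna_fraction(1e-10), 1e-9)
  expect_error(ctdna_fraction(0), "\\(0, 1\\]")
  expect_error(ctdna_fraction(1.2), "\\(0, 1\\]")
})

test_that("math_score matches a brute-force MAD/median oracle", {
  # frozen hand-computed case: median 0.2, raw MAD 0.1, scaled 0.14826
  expect_equal(math_score(c(0.1, 0.2, 0.3)), 74.13)
  # zero dispersion
  expect_equal(math_score(c(0.2, 0.2, 0.2)), 0)
  # scale invariance
  expect_equal(math_score(2 * c(0.1, 0.2, 0.3)), math_score(c(0.1, 0.2, 0.3)))
  set.seed(101)
  for (i in 1:1000) {
    v <- runif(sample(3:40, 1), 0.005, 0.6)
    expect_equal(math_score(v), math_oracle(v), tolerance = 1e-9)
  }
  expect_error(math_score(numeric(0)), "empty")
  expect_error(math_score(c(-0.2, 0, 0.2)), "median")
})

test_that("tmb counts non-synonymous SNV/indels per megabase and is additive", {
  ten <- calls_fixture(runif(10, 0.01, 0.3))
  expect_equal(tmb(ten, 2.0), 5.0)
  expect_equal(tmb(ten[0, ], 2.0), 0.0)
  # synonymous-like calls (is_nonsynonymous FALSE) are excluded
  mixed <- calls_fixture(runif(9, 0.01, 0.3),
                         classes = c(rep("missense", 6),
                                     rep("splice_site", 3)))
  expect_equal(tmb(mixed, 1.5), 4.0)
  # CNVs never count
  expect_equal(tmb(calls_fixture(c(5, 6), classes = c("CNG", "CNG")), 1), 0)
  # additive over disjoint call sets at fixed panel size
  a <- calls_fixture(runif(4, 0.01, 0.3))
  b <- calls_fixture(runif(7, 0.01, 0.3))
  expect_equal(tmb(dplyr::bind_rows(a, b), 1.5), tmb(a, 1.5) + tmb(b, 1.5))
  expect_error(tmb(ten, 0), "positive")
})

test_that("concordance rate matches its formula from counts or gene sets", {
  # the worked example: 37 + 37 discordant slots over 457 x 13
  res <- concordance_rate(457, 13, n_ctdna_specific = 37,
                          n_tissue_specific = 37)
  expect_equal(round(res$concordance_pct, 2), 98.75)
  # perfect concordance iff both specific counts are zero
  expect_equal(concordance_rate(10, 2, n_ctdna_specific = 0,
                                n_tissue_specific = 0)$concordance_pct, 100)
  # full discordance from sets: 5 plasma-only + 5 tissue-only over 10 x 1
  res2 <- concordance_rate(10, 1, plasma_genes = paste0("A", 1:5),
                           tissue_genes = paste0("B", 1:5))
  expect_equal(res2$concordance_pct, 0)
  expect_equal(res2$n_ctdna_specific, 5)
  # set-derived counts ignore shared genes
  res3 <- concordance_rate(100, 1, plasma_genes = c("X", "Y", "Z"),
                           tissue_genes = c("Y", "Z", "W"))
  expect_equal(res3$n_ctdna_specific, 1)
  expect_equal(res3$n_tissue_specific, 1)
  expect_error(concordance_rate(0, 13, n_ctdna_specific = 1,
                                n_tissue_specific = 1), "positive")
  # bounds: random set pairs always land in [0, 100]
  set.seed(5)
  for (i in 1:50) {
    pg <- sample(LETTERS, sample(0:10, 1))
    tg <- sample(LETTERS, sample(0:10, 1))
    cc <- concordance_rate(26, 1, plasma_genes = pg, tissue_genes = tg)
    expect_gte(cc$concordance_pct, 0)
    expect_lte(cc$concordance_pct, 100)
    expect_equal(cc$concordance_pct == 100,
                 cc$n_ctdna_specific + cc$n_tissue_specific == 0)
  }
})

test_that("per-sample biomarker table handles empty and CNV-only samples", {
  cohort <- small_cohort()
  bm <- sample_biomarkers(cohort, panel_megabases = 1.5)
  expect_equal(nrow(bm), nrow(cohort$samples))
  with_snv <- bm[bm$n_calls > 0 & !is.na(bm$max_vaf), ]
  expect_true(all(with_snv$ctdna_fraction ==
                    ctdna_fraction(with_snv$max_vaf)))
  expect_true(all(bm$tmb >= 0))
  # empty samples report NA markers but TMB 0
  empty <- bm[bm$n_calls == 0, ]
  if (nrow(empty) > 0) {
    expect_true(all(is.na(empty$max_vaf)))
    expect_true(all(empty$tmb == 0))
  }
})

test_that("cohort-level tissue-plasma concordance accumulates paired counts", {
  cohort <- small_cohort()
  res <- tissue_plasma_concordance(cohort, n_panel_genes = 60)
  expect_equal(res$n_comparisons, 5)
  expect_gt(res$concordance_pct, 80)
  expect_lte(res$concordance_pct, 100)
})
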