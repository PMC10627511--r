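test_that("gene-frequency filter is strict and counts patients once", {
  # 24 patients: a gene in 2 patients (8.3%) passes at 5%; 1 patient (4.2%)
  # does not; call multiplicity per patient does not matter
  pfs <- rexp(24, log(2) / 6) + 0.1
  cohort <- cohort_from_carriers(
    list(A = c(1, 2), B = 1, C = integer(0)),
    pfs = pfs, event = rep(TRUE, 24))
  # duplicate one of A's calls
  dup <- dplyr::bind_rows(cohort$calls, cohort$calls[1, ])
  cohort2 <- assemble_cohort(dup, cohort$clinical)
  cand <- gene_frequency_filter(cohort2, min_fraction = 0.05)
  expect_setequal(cand$gene, "A")
  expect_equal(cand$n_patients, 2)
  # strictness at the exact boundary: 2/40 = 5% is excluded
  pfs40 <- rexp(40, log(2) / 6) + 0.1
  cohort40 <- cohort_from_carriers(list(A = 1:2, B = 1:3), pfs = pfs40,
                                   event = rep(TRUE, 40))
  cand40 <- gene_frequency_filter(cohort40, min_fraction = 0.05)
  expect_setequal(cand40$gene, "B")
  # monotone: raising the threshold never adds candidates
  for (f in c(0.02, 0.05, 0.1, 0.2)) {
    lo <- gene_frequency_filter(cohort40, min_fraction = f)
    hi <- gene_frequency_filter(cohort40, min_fraction = f + 0.05)
    expect_true(all(paste(hi$gene, hi$alteration_type) %in%
                      paste(lo$gene, lo$alteration_type)))
  }
})

test_that("univariate screen recovers a strong planted gene and matches survival::coxph", {
  set.seed(31)
  n <- 70
  carriers <- sort(sample(n, 14))  # prevalence 20%
  rate <- ifelse(seq_len(n) %in% carriers, 3, 1) * log(2) / 9
  pfs <- rexp(n, rate)
  cohort <- cohort_from_carriers(list(RISK = carriers, NULLG = sample(n, 10)),
                                 pfs = pfs, event = rep(TRUE, n))
  screen <- univariate_cox_screen(
    cohort, tibble::tibble(gene = c("RISK", "NULLG"),
                           alteration_type = "SNV"))
  row <- screen$panel[screen$panel$gene == "RISK", ]
  expect_true(row$selected)
  expect_gt(row$hr, 1)
  # independent cross-check of the fitted HR against a direct coxph call
  x <- as.integer(seq_len(n) %in% carriers)
  ref <- survival::coxph(survival::Surv(pfs, rep(1, n)) ~ x, ties = "efron")
  expect_equal(row$hr, unname(exp(coef(ref))), tolerance = 1e-8)
  expect_equal(row$p_value,
               unname(pchisq(2 * diff(ref$loglik), 1, lower.tail = FALSE)),
               tolerance = 1e-8)
})

test_that("separation-prone candidates are flagged unstable, never selected", {
  set.seed(32)
  n <- 30
  pfs <- rexp(n, log(2) / 6)
  # carriers are exactly the earliest progressors: monotone likelihood
  carriers <- order(pfs)[1:5]
  cohort <- cohort_from_carriers(list(SEP = carriers), pfs = sort(pfs),
                                 event = rep(TRUE, n))
  # rebuild so carriers are the first 5 (shortest) times
  cohort <- cohort_from_carriers(list(SEP = 1:5),
                                 pfs = c(seq(0.01, 0.05, length.out = 5),
                                         rexp(n - 5, log(2) / 60) + 10),
                                 event = rep(TRUE, n))
  screen <- univariate_cox_screen(
    cohort, tibble::tibble(gene = "SEP", alteration_type = "SNV"))
  expect_true(screen$panel$unstable | !screen$panel$selected)
  # a candidate nobody carries is unstable too
  screen0 <- univariate_cox_screen(
    cohort, tibble::tibble(gene = "ABSENT", alteration_type = "SNV"))
  expect_true(screen0$panel$unstable)
  expect_false(screen0$panel$selected)
})

test_that("ctDNA status needs a gene and alteration-type match and is monotone in calls", {
  pfs <- rexp(12, log(2) / 6) + 0.1
  cohort <- cohort_from_carriers(
    list(MYC = 1:2, KMT2C = 3, OTHER = 5),
    types = list(MYC = "CNG", KMT2C = "CNG", OTHER = "missense"),
    pfs = pfs, event = rep(TRUE, 12))
  panel <- tibble::tibble(gene = c("MYC", "KMT2C"),
                          alteration_type = c("CNG", "SNV"))
  status <- classify_ctdna_status(cohort, panel)
  by_pat <- setNames(as.character(status$ctdna_status), status$patient_id)
  # MYC gain matches the panel's MYC (CNG): positive
  expect_equal(unname(by_pat[sprintf("Q%03d", 1)]), "positive")
  # KMT2C gain does NOT match the panel's KMT2C (SNV): negative
  expect_equal(unname(by_pat[sprintf("Q%03d", 3)]), "negative")
  # a sample with no panel alteration at all: negative
  expect_equal(unname(by_pat[sprintf("Q%03d", 5)]), "negative")
  expect_error(classify_ctdna_status(cohort, panel[0, ]), "empty")

  # monotonicity: adding calls never flips positive -> negative
  sim <- small_sim()
  cohort2 <- assemble_cohort(sim$calls, sim$clinical, sim$measurements,
                             sim$sample_manifest)
  pan <- tibble::tibble(gene = default_planted_panel()$gene,
                        alteration_type = default_planted_panel()$type)
  s_full <- classify_ctdna_status(cohort2, pan)
  thin <- sim$calls[seq(1, nrow(sim$calls), by = 2), ]
  cohort_thin <- assemble_cohort(thin, sim$clinical, sim$measurements,
                                 sim$sample_manifest)
  s_thin <- classify_ctdna_status(cohort_thin, pan)
  merged <- dplyr::inner_join(s_thin, s_full,
                              by = c("patient_id", "sample_id", "timepoint",
                                     "source"))
  expect_false(any(merged$ctdna_status.x == "positive" &
                     merged$ctdna_status.y == "negative"))
})

test_that("screen tidiers expose the panel table and summary", {
  cohort <- small_cohort()
  screen <- univariate_cox_screen(cohort, gene_frequency_filter(cohort))
  td <- tidy(screen)
  expect_true(all(c("gene", "alteration_type", "hr", "ci_low", "ci_high",
                    "p_value", "selected") %in% names(td)))
  # selected implies hr > 1, p < alpha, CI brackets the HR
  sel <- td[td$selected, ]
  expect_true(all(sel$hr > 1))
  expect_true(all(sel$p_value < 0.05))
  expect_true(all(sel$ci_low <= sel$hr & sel$hr <= sel$ci_high))
  gl <- glance(screen)
  expect_equal(gl$n_selected, sum(td$selected))
  expect_s3_class(autoplot(screen), "ggplot")
})
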