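test_that("KM medians match the closed-form exponential median and sample median", {
  surv <- simulate_survival(5000, rate = log(2) / 6, censor_rate = 0,
                            seed = 51)
  km <- km_median_and_logrank(surv, time = "time", event = "event")
  expect_equal(km$medians$median, 6, tolerance = 0.05)
  # with no censoring the KM median equals the sample median
  expect_equal(km$medians$median, median(surv$time), tolerance = 1e-8)
})

test_that("log-rank on duplicated data gives statistic 0; identical groups are null", {
  set.seed(52)
  t <- rexp(40, log(2) / 6); e <- rep(TRUE, 40)
  dup <- tibble::tibble(time = c(t, t), event = c(e, e),
                        group = rep(c("a", "b"), each = 40))
  km <- km_median_and_logrank(dup, group = "group")
  expect_equal(km$chisq, 0, tolerance = 1e-10)
  expect_equal(diff(km$medians$median), 0)
  # all censored before any event: median undefined
  cens <- tibble::tibble(time = runif(10, 1, 5), event = FALSE)
  km2 <- km_median_and_logrank(cens)
  expect_true(is.na(km2$medians$median))
})

test_that("KM survivor curve is a non-increasing step function in [0, 1]", {
  surv <- simulate_survival(300, rate = 0.2, censor_rate = 0.05, seed = 53)
  km <- km_median_and_logrank(surv)
  s <- km$fit$surv
  expect_true(all(diff(s) <= 1e-12))
  expect_true(all(s >= 0 & s <= 1))
})

test_that("multivariable Cox recovers planted effects and reproduces the univariate fit", {
  set.seed(54)
  n <- 300
  status <- rbinom(n, 1, 0.45)
  noise <- rbinom(n, 1, 0.5)
  t <- rexp(n, log(2) / 9 * ifelse(status == 1, 2.7, 1))
  d <- tibble::tibble(pfs_months = t, event = TRUE,
                      ctdna = factor(ifelse(status == 1, "pos", "neg")),
                      noise = noise)
  fit <- multivariable_cox(d, c("ctdna", "noise"))
  hr <- fit$terms$hr[grepl("ctdna", fit$terms$term)]
  expect_equal(hr, 2.7, tolerance = 0.35)
  hr_null <- fit$terms$hr[fit$terms$term == "noise"]
  expect_equal(hr_null, 1, tolerance = 0.35)
  # cross-module consistency: a single-covariate multivariable fit equals
  # the univariate screen's HR for that alteration
  cohort <- small_cohort(seed = 55)
  cand <- head(gene_frequency_filter(cohort), 1)
  screen <- univariate_cox_screen(cohort, cand)
  carriers <- unique(cohort$calls$patient_id[
    cohort$calls$gene == cand$gene & cohort$calls$timepoint == "baseline"])
  d2 <- dplyr::mutate(cohort$clinical,
                      carrier = as.integer(patient_id %in% carriers))
  fit2 <- multivariable_cox(d2, "carrier")
  expect_equal(fit2$terms$hr, screen$panel$hr, tolerance = 1e-8)
})

test_that("degenerate covariates flag the joint fit unstable", {
  set.seed(56)
  n <- 60
  t <- rexp(n, 0.2)
  e <- rbinom(n, 1, 0.8) == 1
  d <- tibble::tibble(pfs_months = t, event = e,
                      sep = as.integer(e),  # identical to the event flag
                      ok = rbinom(n, 1, 0.5))
  fit <- multivariable_cox(d, c("sep", "ok"))
  expect_true(fit$unstable)
  # listwise deletion is reported
  d$ok[1:5] <- NA
  fit2 <- multivariable_cox(d, c("ok"))
  expect_equal(fit2$n_dropped, 5)
})

test_that("response-group comparison contrasts PD against pooled others", {
  set.seed(57)
  resp <- rep(c("PD", "SD", "PR", "CR"), c(12, 31, 23, 4))
  x <- rnorm(70) + ifelse(resp == "PD", 1.2, 0)
  rc <- response_group_compare(x, resp)
  expect_lt(rc$pd_vs_others_p, 0.05)
  # matches a direct wilcox.test with the same options
  ref <- wilcox.test(x[resp == "PD"], x[resp != "PD"], exact = FALSE)
  expect_equal(rc$pd_vs_others_p, ref$p.value, tolerance = 1e-10)
  expect_equal(nrow(rc$pairwise), 6)
  # heavy ties still give finite p-values
  xt <- sample(c(0, 1), 70, replace = TRUE)
  rct <- response_group_compare(xt, resp)
  expect_true(is.finite(rct$pd_vs_others_p))
  # an empty group is excluded with a warning
  expect_warning(response_group_compare(x[resp != "CR"],
                                        resp[resp != "CR"]), "CR")
})

test_that("objective response rate is (CR + PR) / n", {
  resp <- rep(c("CR", "PR", "SD", "PD"), c(4, 23, 31, 12))
  expect_equal(round(100 * objective_response_rate(resp), 1), 38.6)
  expect_equal(objective_response_rate(rep("CR", 5)), 1)
  expect_equal(objective_response_rate(rep(c("SD", "PD"), 5)), 0)
  expect_error(objective_response_rate(character(0)), "no responses")
  expect_error(objective_response_rate("XX"), "unknown")
})
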