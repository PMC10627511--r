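test_that("default config mirrors the emulated cohort shape", {
  cfg <- cohort_config()
  expect_equal(cfg$n_patients, 70L)
  expect_equal(cfg$n_genes, 457L)
  expect_equal(cfg$n_dynamic, 38L)
  expect_equal(cfg$n_patients + cfg$n_dynamic + cfg$n_progression, 139L)
  expect_equal(cfg$baseline_hazard, log(2) / 9.05)
  pp <- cfg$planted_panel
  expect_equal(nrow(pp), 12)
  expect_true(all(pp$true_hr >= 1.89 & pp$true_hr <= 4.19))
  expect_true(all(pp$prevalence >= 0.057))
  # infeasible or invalid configs are rejected
  expect_error(cohort_config(planted_panel = dplyr::mutate(
    default_planted_panel(), prevalence = 0)), "infeasible")
  expect_error(cohort_config(n_dynamic = 80), "n_dynamic")
})

test_that("the default cohort has 70 baseline profiles, 38 trajectories, 139 samples", {
  sim <- simulate_cohort(cohort_config(), seed = 1)
  plasma <- sim$sample_manifest[sim$sample_manifest$source == "plasma", ]
  expect_equal(sum(plasma$timepoint == "baseline"), 70)
  expect_equal(sum(plasma$timepoint == "during_treatment"), 38)
  expect_equal(nrow(plasma), 139)
  expect_equal(sum(sim$sample_manifest$source == "tissue"), 13)
  # response marginals match the emulated cohort
  expect_equal(as.integer(table(sim$clinical$best_response)[c("PD", "SD",
                                                              "PR", "CR")]),
               c(12L, 31L, 23L, 4L))
  # marginal prevalence of a high-frequency planted gene is plausible
  bl <- sim$calls[sim$calls$timepoint == "baseline" &
                    sim$calls$source == "plasma", ]
  expect_gt(length(unique(bl$patient_id[bl$gene == "TP53"])), 30)
})

test_that("simulation is bit-identical under a fixed seed and varies across seeds", {
  s1 <- simulate_cohort(cohort_config(), seed = 7)
  s2 <- simulate_cohort(cohort_config(), seed = 7)
  expect_identical(s1$calls, s2$calls)
  expect_identical(s1$clinical, s2$clinical)
  expect_identical(s1$measurements, s2$measurements)
  s3 <- simulate_cohort(cohort_config(), seed = 8)
  expect_false(identical(s1$calls, s3$calls))
})

test_that("exponential survival simulation matches closed-form behavior", {
  surv <- simulate_survival(10000, rate = log(2) / 6.15, censor_rate = 0,
                            seed = 71)
  expect_equal(median(surv$time), 6.15, tolerance = 0.03)
  expect_true(all(surv$event))
  # heavy censoring censors nearly everything
  heavy <- simulate_survival(2000, rate = 0.1, censor_rate = 1000, seed = 72)
  expect_lt(mean(heavy$event), 0.01)
  expect_lt(median(heavy$time), 0.01)
  # determinism
  expect_identical(simulate_survival(50, 0.2, 0.05, seed = 73),
                   simulate_survival(50, 0.2, 0.05, seed = 73))
})

test_that("a planted gene separates carrier survival in the right direction", {
  cfg <- cohort_config(
    n_patients = 400, n_genes = 40, n_dynamic = 10, n_tissue = 5,
    planted_panel = tibble::tibble(gene = "MYC", type = "CNG",
                                   true_hr = 3.45, prevalence = 0.1),
    censor_rate = 0)
  sim <- simulate_cohort(cfg, seed = 74)
  bl <- sim$calls[sim$calls$timepoint == "baseline" &
                    sim$calls$source == "plasma", ]
  carriers <- unique(bl$patient_id[bl$gene == "MYC" &
                                     bl$alteration_class == "CNG"])
  med_c <- median(sim$clinical$pfs_months[
    sim$clinical$patient_id %in% carriers])
  med_n <- median(sim$clinical$pfs_months[
    !sim$clinical$patient_id %in% carriers])
  expect_lt(med_c, med_n)
  # carrier fraction near the configured prevalence (binomial sd ~0.015)
  expect_lt(abs(length(carriers) / 400 - 0.1), 0.045)
})

test_that("written tables are readable by the io layer and round-trip the cohort", {
  dir <- withr::local_tempdir()
  sim <- small_sim(seed = 75)
  write_cohort_tables(sim, dir)
  calls <- dplyr::bind_rows(
    read_mutation_table(file.path(dir, "variants.tsv"), "plasma"),
    read_cnv_table(file.path(dir, "cnv.tsv"), "plasma"),
    read_mutation_table(file.path(dir, "tissue_variants.tsv"), "tissue"),
    read_cnv_table(file.path(dir, "tissue_cnv.tsv"), "tissue"))
  clinical <- read_clinical_table(file.path(dir, "clinical.tsv"))
  meas <- read_measurement_table(file.path(dir, "measurements.tsv"))
  manifest <- readr::read_tsv(file.path(dir, "samples.tsv"),
                              show_col_types = FALSE)
  cohort <- assemble_cohort(calls, clinical, meas, manifest)
  expect_equal(nrow(cohort$samples), nrow(sim$sample_manifest))
  expect_equal(nrow(calls), nrow(sim$calls))
  expect_equal(sort(readLines(file.path(dir, "panel_genes.txt"))),
               sort(sim$panel_genes))
  # biomarkers computed from the files equal biomarkers from the in-memory sim
  direct <- assemble_cohort(sim$calls, sim$clinical, sim$measurements,
                            sim$sample_manifest)
  expect_equal(sample_biomarkers(cohort), sample_biomarkers(direct),
               tolerance = 1e-12)
})
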