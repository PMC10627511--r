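# Shared fixtures: small simulated cohorts and hand-built call tables.

small_sim <- function(seed = 11, n_patients = 24, n_genes = 60,
                      n_dynamic = 10, ...) {
  simulate_cohort(cohort_config(n_patients = n_patients, n_genes = n_genes,
                                n_dynamic = n_dynamic, n_tissue = 5, ...),
                  seed = seed)
}

small_cohort <- function(seed = 11, ...) {
  sim <- small_sim(seed = seed, ...)
  assemble_cohort(sim$calls, sim$clinical, sim$measurements,
                  sim$sample_manifest)
}

# A minimal hand-built calls tibble, one sample.
calls_fixture <- function(vafs = c(0.02, 0.10, 0.07),
                          classes = NULL, patient = "P01") {
  n <- length(vafs)
  if (is.null(classes)) classes <- rep("missense", n)
  tibble::tibble(
    patient_id = patient, sample_id = paste0(patient, "-B"),
    timepoint = factor("baseline",
                       levels = c("baseline", "during_treatment",
                                  "progression")),
    source = "plasma", gene = paste0("G", seq_len(n)),
    alteration_class = classes,
    vaf = ifelse(classes %in% c("CNG", "CNL"), NA_real_, vafs),
    copy_number = ifelse(classes %in% c("CNG", "CNL"), vafs, NA_real_),
    is_nonsynonymous = !classes %in% c("splice_site", "CNG", "CNL")
  )
}

# Build a bare cohort from an explicit per-patient carrier layout:
# `carriers` is a named list gene -> patient indices; survival supplied.
cohort_from_carriers <- function(carriers, pfs, event,
                                 types = NULL) {
  n <- length(pfs)
  patients <- sprintf("Q%03d", seq_len(n))
  rows <- list()
  for (g in names(carriers)) {
    idx <- carriers[[g]]
    ty <- if (is.null(types)) "missense" else types[[g]]
    if (length(idx) == 0) next
    rows[[g]] <- tibble::tibble(
      patient_id = patients[idx], sample_id = paste0(patients[idx], "-B"),
      timepoint = factor("baseline",
                         levels = c("baseline", "during_treatment",
                                    "progression")),
      source = "plasma", gene = g, alteration_class = ty,
      vaf = ifelse(ty %in% c("CNG", "CNL"), NA_real_, 0.1),
      copy_number = ifelse(ty %in% c("CNG", "CNL"), 4, NA_real_),
      is_nonsynonymous = !ty %in% c("splice_site", "CNG", "CNL")
    )
  }
  calls <- dplyr::bind_rows(rows)
  clinical <- tibble::tibble(patient_id = patients, pfs_months = pfs,
                             event = event,
                             best_response = factor("SD",
                                                    levels = c("PD", "SD",
                                                               "PR", "CR"),
                                                    ordered = TRUE))
  assemble_cohort(calls, clinical)
}

# Independent brute-force MATH oracle: no stats::mad.
math_oracle <- function(v) {
  med <- sort(v)[ceiling(length(v) / 2)]
  if (length(v) %% 2 == 0) {
    s <- sort(v)
    med <- (s[length(v) / 2] + s[length(v) / 2 + 1]) / 2
  }
  dev <- abs(v - med)
  s <- sort(dev)
  mad_raw <- if (length(v) %% 2 == 0) {
    (s[length(v) / 2] + s[length(v) / 2 + 1]) / 2
  } else {
    s[ceiling(length(v) / 2)]
  }
  100 * 1.4826 * mad_raw / med
}
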