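#' Configuration for a synthetic ctDNA cohort
#'
#' Defaults emulate a prospective metastatic triple-negative breast cancer
#' cohort profiled with a 457-gene plasma panel: 70 patients with baseline
#' samples, a 38-patient dynamic subset sampled at up to three timepoints
#' (139 plasma samples in total), 13 patients with paired baseline tumor
#' tissue, a 12-entry planted prognostic panel with hazard ratios between
#' 1.89 and 4.19 (a carrier's event rate is the exponential baseline
#' hazard times the largest planted hazard ratio carried),
#' ordinal treatment response coupled to ctDNA burden, and tumor-size /
#' serum-marker channels. The panel-negative baseline hazard corresponds to
#' a median progression-free survival of 9.05 months, which puts the cohort
#' marginal median near 6.15 months under the default planted panel.
#'
#' @param n_patients Number of patients (default 70).
#' @param n_genes Panel size (default 457).
#' @param n_dynamic Patients with a during-treatment sample (default 38).
#' @param n_progression Of the dynamic subset, patients with a progression
#'   sample as well (default 31, so 70 + 38 + 31 = 139 samples).
#' @param n_tissue Patients with a paired baseline tissue profile
#'   (default 13).
#' @param planted_panel Tibble `gene`, `type` (`"SNV"`/`"CNG"`/`"CNL"`),
#'   `true_hr`, `prevalence` of the prognostic alterations planted under
#'   proportional hazards. Default: [default_planted_panel()].
#' @param baseline_hazard Exponential event rate for a patient with no
#'   planted alteration (default `log(2)/9.05` per month).
#' @param censor_rate Independent exponential censoring rate (default
#'   `log(2)/24`; 0 disables censoring).
#' @param vaf_shape1,vaf_shape2 Beta parameters of per-mutation VAFs
#'   (default Beta(1.5, 30), mean ~0.048).
#' @param response_probs Marginal probabilities of best response
#'   PD/SD/PR/CR (default 12/31/23/4 out of 70). Worse response goes with
#'   higher ctDNA burden.
#' @param carriage_loading Gaussian-copula loading of planted-gene
#'   carriage on the latent per-patient tumor-burden propensity, in
#'   `[0, 1)`; 0 gives independent carriage. The default 0.8 makes the
#'   planted alterations co-occur so that about 46% of patients carry at
#'   least one — the ctDNA-positive rate the emulated cohort reports.
#' @param tumor_size_noise_sd Log-scale noise of tumor size around its
#'   monotone link to ctDNA burden (default 0.55, targeting a Spearman
#'   correlation near 0.3 between tumor size and ctDNA fraction).
#' @param tissue_discordance_mean Expected per-patient count of
#'   plasma-only and (separately) tissue-only mutated genes (default 37/13,
#'   giving an expected concordance near 98.75% at the default panel size).
#' @param panel_megabases Panel footprint in megabases used downstream for
#'   TMB (default 1.5).
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 70, n_genes = 457, n_dynamic = 38,
                          n_progression = NULL, n_tissue = 13,
                          planted_panel = default_planted_panel(),
                          baseline_hazard = log(2) / 9.05,
                          censor_rate = log(2) / 24,
                          vaf_shape1 = 1.5, vaf_shape2 = 30,
                          response_probs = c(PD = 12, SD = 31, PR = 23,
                                             CR = 4) / 70,
                          carriage_loading = 0.8,
                          tumor_size_noise_sd = 0.55,
                          tissue_discordance_mean = 37 / 13,
                          panel_megabases = 1.5) {
  if (is.null(n_progression)) {
    n_progression <- min(n_dynamic, max(0L, round(n_dynamic * 31 / 38)))
  }
  stopifnot(n_patients >= 1, n_genes >= 1,
            n_dynamic <= n_patients, n_progression <= n_dynamic,
            n_tissue <= n_patients,
            vaf_shape1 > 0, vaf_shape2 > 0,
            carriage_loading >= 0, carriage_loading < 1,
            baseline_hazard > 0, censor_rate >= 0,
            tumor_size_noise_sd >= 0, panel_megabases > 0)
  stopifnot(all(c("gene", "type", "true_hr", "prevalence") %in%
                  names(planted_panel)))
  if (any(planted_panel$true_hr <= 0)) abort("planted true_hr must be positive")
  if (any(planted_panel$prevalence <= 0 & planted_panel$true_hr != 1)) {
    abort("a planted effect with zero prevalence is infeasible")
  }
  if (any(planted_panel$prevalence <= 0 | planted_panel$prevalence >= 1)) {
    abort("planted prevalences must lie in (0, 1)")
  }
  if (abs(sum(response_probs) - 1) > 1e-8) {
    abort("response_probs must sum to 1")
  }
  if (nrow(planted_panel) > n_genes) abort("more planted genes than panel genes")
  structure(
    list(n_patients = as.integer(n_patients), n_genes = as.integer(n_genes),
         n_dynamic = as.integer(n_dynamic),
         n_progression = as.integer(n_progression),
         n_tissue = as.integer(n_tissue),
         planted_panel = tibble::as_tibble(planted_panel),
         baseline_hazard = baseline_hazard, censor_rate = censor_rate,
         vaf_shape1 = vaf_shape1, vaf_shape2 = vaf_shape2,
         carriage_loading = carriage_loading,
         response_probs = response_probs,
         tumor_size_noise_sd = tumor_size_noise_sd,
         tissue_discordance_mean = tissue_discordance_mean,
         panel_megabases = panel_megabases),
    class = "cohort_config"
  )
}

#' Default planted prognostic panel
#'
#' Twelve (gene, alteration-type) pairs — eleven copy-number gains and one
#' SNV — with hazard ratios spanning 1.89 to 4.19, mirroring the size, type
#' mix and effect range of a published 12-gene ctDNA prognostic panel in
#' metastatic triple-negative breast cancer. Prevalences use the cohort
#' frequencies printed for the genes where one is available and plausible
#' values of at least 6% elsewhere.
#'
#' @return A tibble `gene`, `type`, `true_hr`, `prevalence`.
#' @export
default_planted_panel <- function() {
  tibble::tribble(
    ~gene,    ~type,  ~true_hr, ~prevalence,
    "HLA-B",  "CNG",  1.89,     0.33,
    "BTG2",   "CNG",  2.23,     0.19,
    "MCL1",   "CNG",  2.31,     0.13,
    "H3F3A",  "CNG",  2.36,     0.10,
    "MYC",    "CNG",  3.45,     0.14,
    "KMT2C",  "SNV",  2.75,     0.09,
    "KYAT3",  "CNG",  3.66,     0.09,
    "ARID4B", "CNG",  4.04,     0.07,
    "CD22",   "CNG",  3.66,     0.07,
    "TGFB1",  "CNG",  3.94,     0.09,
    "SGK1",   "CNG",  3.37,     0.07,
    "RSPO2",  "CNG",  4.19,     0.07
  )
}

#' Synthetic gene panel symbol list
#'
#' The planted panel genes, a set of genes recurrently mutated in
#' triple-negative breast cancer, and synthetic filler symbols up to the
#' requested panel size.
#'
#' @param n_genes Panel size (default 457).
#' @return Character vector of `n_genes` unique symbols.
#' @export
default_panel_genes <- function(n_genes = 457) {
  named <- unique(c(
    default_planted_panel()$gene,
    "TP53", "PIK3CA", "ARID1A", "CIC", "KMT2D", "NOTCH4", "PBRM1", "PTEN",
    "DNMT3A", "HLA-C", "HLA-A", "HLA-DRB1", "SPPL3", "C8orf34", "HLA-DQA1",
    "HLA-E", "LTBP1"
  ))
  if (n_genes <= length(named)) return(named[seq_len(n_genes)])
  c(named, sprintf("SYN%03d", seq_len(n_genes - length(named))))
}

# Background (non-planted) alteration frequencies: printed cohort
# frequencies for the named genes, sparse random frequencies for fillers.
background_frequencies <- function(genes, planted) {
  snv_named <- c(TP53 = 0.69, PIK3CA = 0.24, ARID1A = 0.09, CIC = 0.07,
                 KMT2D = 0.07, NOTCH4 = 0.07, PBRM1 = 0.07, PTEN = 0.07,
                 DNMT3A = 0.06)
  cng_named <- c(`HLA-C` = 0.50, `HLA-A` = 0.33, `HLA-DRB1` = 0.23,
                 SPPL3 = 0.21, C8orf34 = 0.16, `HLA-DQA1` = 0.16,
                 `HLA-E` = 0.16, LTBP1 = 0.16)
  filler <- setdiff(genes, c(planted$gene, names(snv_named), names(cng_named)))
  out <- dplyr::bind_rows(
    tibble::tibble(gene = names(snv_named), type = "SNV",
                   prevalence = unname(snv_named)),
    tibble::tibble(gene = names(cng_named), type = "CNG",
                   prevalence = unname(cng_named)),
    tibble::tibble(gene = filler, type = "SNV",
                   prevalence = runif(length(filler), 0.002, 0.03)),
    # a sparse copy-number-loss background so CNL calls occur
    tibble::tibble(gene = sample(filler, min(20, length(filler))),
                   type = "CNL",
                   prevalence = runif(min(20, length(filler)), 0.01, 0.05))
  )
  dplyr::anti_join(out, planted, by = c("gene", "type"))
}

#' Simulate exponential survival with independent censoring
#'
#' Event times are exponential with the given rate; censoring times are
#' exponential with `censor_rate` (none when 0). The observed time is the
#' minimum, the event flag marks events observed before censoring.
#'
#' @param n Number of subjects.
#' @param rate Event hazard rate (> 0).
#' @param censor_rate Censoring hazard rate (>= 0).
#' @param seed Optional integer seed; when given, output is reproducible.
#' @return A tibble `time`, `event`.
#' @export
simulate_survival <- function(n, rate, censor_rate = 0, seed = NULL) {
  stopifnot(rate > 0, censor_rate >= 0)
  if (!is.null(seed)) set.seed(seed)
  t_event <- rexp(n, rate)
  t_cens <- if (censor_rate > 0) rexp(n, censor_rate) else rep(Inf, n)
  tibble::tibble(time = pmin(t_event, t_cens), event = t_event <= t_cens)
}

#' Simulate a full synthetic ctDNA cohort
#'
#' Draws a cohort under the structure described in [cohort_config()]:
#' per-patient baseline alteration profiles (planted prognostic pairs plus
#' background alterations), progression-free survival from a
#' proportional-hazards model in which each planted alteration multiplies
#' the exponential baseline hazard by its hazard ratio, ordinal best
#' response assigned by ranking a noisy latent ctDNA burden (worse response
#' at higher burden, marginals fixed by `response_probs`), tumor size
#' linked monotonically to burden with log-normal noise, serum markers
#' CEA/CA125/CA153 as uncoupled log-normal channels, three-timepoint
#' dynamics for the dynamic subset (VAFs and copy numbers shrink on
#' treatment in responders and rebound at progression), and paired baseline
#' tissue profiles sharing most of the plasma gene set.
#'
#' Output is deterministic given `seed`.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed.
#' @return A list of class `cohort_sim`: `calls` (plasma and tissue,
#'   SNV/indel and CNV rows), `clinical`, `measurements`,
#'   `sample_manifest` (every sequenced sample, including any with no
#'   somatic call), `panel_genes`, and `truth` (planted panel, subset
#'   memberships, generator parameters).
#' @examples
#' sim <- simulate_cohort(cohort_config(n_patients = 20, n_genes = 60,
#'                                      n_dynamic = 8), seed = 42)
#' dplyr::count(sim$calls, timepoint, source)
#' @export
simulate_cohort <- function(config = cohort_config(), seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(seed)
  n <- config$n_patients
  patients <- sprintf("P%03d", seq_len(n))
  genes <- default_panel_genes(config$n_genes)
  planted <- config$planted_panel
  background <- background_frequencies(genes, planted)
  background <- background[background$gene %in% genes, ]

  effects <- dplyr::bind_rows(
    dplyr::mutate(planted, planted = TRUE),
    dplyr::mutate(background, true_hr = 1, planted = FALSE)
  )

  # Latent per-patient tumor-burden propensity. Carriage of the planted
  # prognostic genes follows a Gaussian-copula threshold model loaded on
  # the propensity (marginal prevalences preserved exactly), so planted
  # alterations co-occur within high-burden patients as prognostic panels
  # do in real cohorts. Background passenger alterations are independent.
  u <- rnorm(n)
  a <- config$carriage_loading
  carrier <- matrix(FALSE, n, nrow(effects))
  for (k in seq_len(nrow(effects))) {
    p_k <- effects$prevalence[k]
    if (effects$planted[k]) {
      carrier[, k] <- a * u + sqrt(1 - a^2) * rnorm(n) > qnorm(1 - p_k)
    } else {
      carrier[, k] <- rbinom(n, 1, p_k) == 1
    }
  }

  # Proportional-hazards survival: the per-patient hazard multiplier is
  # the largest planted hazard ratio carried (dominant-lesion model; 1
  # when no planted alteration is carried). A patient free of panel
  # alterations keeps the baseline median.
  hr_mult <- vapply(seq_len(n), function(i) {
    carried <- effects$true_hr[carrier[i, ] & effects$planted]
    if (length(carried) == 0) 1 else max(carried, 1)
  }, double(1))
  rate_i <- config$baseline_hazard * hr_mult
  t_event <- rexp(n, rate_i)
  t_cens <- if (config$censor_rate > 0) rexp(n, config$censor_rate) else
    rep(Inf, n)
  pfs <- pmax(pmin(t_event, t_cens), 0.03)
  event <- t_event <= t_cens

  # baseline plasma calls; per-mutation VAFs scale mildly with the burden
  # propensity so ctDNA fraction, response and survival cohere
  vaf_mult <- exp(0.35 * u)
  baseline_calls <- draw_calls(patients, carrier, effects, config,
                               timepoint = "baseline", suffix = "B",
                               vaf_mult = vaf_mult)

  # latent ctDNA burden drives response, tumor size
  burden <- vapply(patients, function(p) {
    v <- baseline_calls$vaf[baseline_calls$patient_id == p &
                              !is.na(baseline_calls$vaf)]
    n_cnv <- sum(baseline_calls$patient_id == p & is.na(baseline_calls$vaf))
    base <- if (length(v) > 0) ctdna_fraction(max(v)) else 0
    base + 0.01 * n_cnv
  }, double(1))
  latent <- log(pmax(burden, 1e-4)) + rnorm(n, 0, 0.8)
  counts <- marginal_counts(n, config$response_probs)
  response <- rep(NA_character_, n)
  ord <- order(latent, decreasing = TRUE)  # highest burden -> PD
  response[ord] <- rep(c("PD", "SD", "PR", "CR"), counts)

  clinical <- draw_clinical(patients, pfs, event, response)

  dynamic <- sort(sample(patients, config$n_dynamic))
  progression <- sort(sample(dynamic, config$n_progression))
  tissue <- sort(sample(patients, config$n_tissue))

  dyn_calls <- draw_dynamic_calls(baseline_calls, dynamic, progression,
                                  clinical)
  tissue_calls <- draw_tissue_calls(baseline_calls, tissue, genes, config)
  calls <- dplyr::bind_rows(baseline_calls, dyn_calls, tissue_calls) |>
    dplyr::arrange(.data$patient_id, .data$timepoint, .data$source,
                   .data$gene)

  measurements <- draw_measurements(patients, burden, response, dynamic,
                                    progression, config)
  clinical <- attach_elevation_flags(clinical, measurements)

  manifest <- dplyr::bind_rows(
    tibble::tibble(patient_id = patients,
                   sample_id = paste0(patients, "-B"),
                   timepoint = "baseline", source = "plasma"),
    tibble::tibble(patient_id = dynamic,
                   sample_id = paste0(dynamic, "-D"),
                   timepoint = "during_treatment", source = "plasma"),
    tibble::tibble(patient_id = progression,
                   sample_id = paste0(progression, "-P"),
                   timepoint = "progression", source = "plasma"),
    tibble::tibble(patient_id = tissue,
                   sample_id = paste0(tissue, "-T"),
                   timepoint = "baseline", source = "tissue")
  ) |>
    dplyr::mutate(timepoint = factor(.data$timepoint,
                                     levels = timepoint_levels())) |>
    dplyr::arrange(.data$patient_id, .data$timepoint, .data$source)

  structure(
    list(calls = calls, clinical = clinical, measurements = measurements,
         sample_manifest = manifest, panel_genes = genes,
         truth = list(planted_panel = planted, dynamic_patients = dynamic,
                      progression_patients = progression,
                      tissue_patients = tissue, burden = setNames(burden, patients),
                      seed = seed, config = config)),
    class = "cohort_sim"
  )
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("<cohort_sim> %d patients, %d calls, seed %d\n",
              nrow(x$clinical), nrow(x$calls), x$truth$seed))
  print(dplyr::count(x$calls, .data$timepoint, .data$source))
  invisible(x)
}

#' Write the simulated tables to tab-delimited files
#'
#' Writes `variants.tsv` and `cnv.tsv` (plasma), `tissue_variants.tsv` and
#' `tissue_cnv.tsv` (when tissue profiles exist), `samples.tsv` (the sample
#' manifest), `clinical.tsv`, `measurements.tsv`, `panel_genes.txt`, and
#' `truth.json` (the planted effects, for recovery tests) into `dir`.
#' These are the files the reader functions consume.
#'
#' @param sim A `cohort_sim`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_tables <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  snv <- dplyr::filter(sim$calls, .data$alteration_class %in% snv_classes())
  cnv <- dplyr::filter(sim$calls, .data$alteration_class %in% cnv_classes())
  for (src in unique(sim$calls$source)) {
    prefix <- if (src == "plasma") "" else "tissue_"
    s <- dplyr::filter(snv, .data$source == src) |>
      dplyr::select("patient_id", "sample_id", "timepoint", "gene",
                    "alteration_class", "vaf", "is_nonsynonymous") |>
      dplyr::mutate(timepoint = as.character(.data$timepoint))
    readr::write_tsv(s, file.path(dir, paste0(prefix, "variants.tsv")))
    cc <- dplyr::filter(cnv, .data$source == src) |>
      dplyr::select("patient_id", "sample_id", "timepoint", "gene",
                    "copy_number") |>
      dplyr::mutate(timepoint = as.character(.data$timepoint))
    readr::write_tsv(cc, file.path(dir, paste0(prefix, "cnv.tsv")))
  }
  readr::write_tsv(
    dplyr::mutate(sim$sample_manifest,
                  timepoint = as.character(.data$timepoint)),
    file.path(dir, "samples.tsv"))
  readr::write_tsv(sim$clinical, file.path(dir, "clinical.tsv"))
  readr::write_tsv(
    dplyr::mutate(sim$measurements,
                  timepoint = as.character(.data$timepoint)),
    file.path(dir, "measurements.tsv"))
  writeLines(sim$panel_genes, file.path(dir, "panel_genes.txt"))
  jsonlite::write_json(
    list(planted_panel = sim$truth$planted_panel,
         dynamic_patients = sim$truth$dynamic_patients,
         progression_patients = sim$truth$progression_patients,
         tissue_patients = sim$truth$tissue_patients,
         seed = sim$truth$seed),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# internal generator pieces --------------------------------------------------

marginal_counts <- function(n, probs) {
  counts <- floor(n * probs)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(n * probs - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

draw_calls <- function(patients, carrier, effects, config, timepoint,
                       suffix, vaf_mult = NULL) {
  if (is.null(vaf_mult)) vaf_mult <- rep(1, length(patients))
  idx <- which(carrier, arr.ind = TRUE)
  if (nrow(idx) == 0) return(empty_calls())
  pat <- patients[idx[, 1]]
  mult <- vaf_mult[idx[, 1]]
  type <- effects$type[idx[, 2]]
  gene <- effects$gene[idx[, 2]]
  k <- length(pat)
  # printed SNV class mix: 301 missense, 45 frameshift, 16 in-frame,
  # 13 splice-site, 31 stop-gain
  class_probs <- c(301, 45, 16, 13, 31) / 406
  cls <- character(k); vaf <- rep(NA_real_, k); cn <- rep(NA_real_, k)
  is_snv <- type == "SNV"
  cls[is_snv] <- sample(snv_classes(), sum(is_snv), replace = TRUE,
                        prob = class_probs)
  vaf[is_snv] <- pmin(pmax(rbeta(sum(is_snv), config$vaf_shape1,
                                 config$vaf_shape2) * mult[is_snv],
                           0.002), 0.98)
  cls[type == "CNG"] <- "CNG"
  cn[type == "CNG"] <- 3 + rgamma(sum(type == "CNG"), shape = 2, rate = 1.2)
  cls[type == "CNL"] <- "CNL"
  cn[type == "CNL"] <- runif(sum(type == "CNL"), 0.2, 0.95)
  new_calls(
    patient_id = pat,
    sample_id = paste0(pat, "-", suffix),
    timepoint = factor(timepoint, levels = timepoint_levels()),
    source = "plasma",
    gene = gene,
    alteration_class = cls,
    vaf = vaf,
    copy_number = cn,
    is_nonsynonymous = cls %in% c("missense", "frameshift_indel",
                                  "inframe_indel", "stop_gain")
  )
}

# Treatment dynamics: VAFs shrink on treatment in responders (more in
# CR/PR), copy numbers regress toward diploid, both rebound at progression.
# Calls falling below detection (VAF < 0.005) or into the neutral
# copy-number band disappear from the sample.
draw_dynamic_calls <- function(baseline_calls, dynamic, progression,
                               clinical) {
  shrink <- c(CR = 0.08, PR = 0.35, SD = 0.75, PD = 1.2)
  out <- list()
  for (p in dynamic) {
    base <- baseline_calls[baseline_calls$patient_id == p, ]
    resp <- as.character(clinical$best_response[clinical$patient_id == p])
    f_d <- shrink[[resp]] * rlnorm(nrow(base), 0, 0.25)
    during <- rescale_calls(base, f_d, suffix = "D",
                            timepoint = "during_treatment")
    out[[length(out) + 1]] <- during
    if (p %in% progression) {
      f_p <- runif(nrow(base), 1.0, 1.6)
      out[[length(out) + 1]] <- rescale_calls(base, f_p, suffix = "P",
                                              timepoint = "progression")
    }
  }
  if (length(out) == 0) return(empty_calls())
  dplyr::bind_rows(out)
}

rescale_calls <- function(base, factor_, suffix, timepoint) {
  vaf <- pmin(base$vaf * factor_, 0.98)
  cn <- ifelse(base$alteration_class == "CNG",
               2 + (base$copy_number - 2) * factor_,
               2 - (2 - base$copy_number) * factor_)
  cn <- pmax(cn, 0)
  keep_snv <- base$alteration_class %in% snv_classes() & !is.na(vaf) &
    vaf >= 0.005
  keep_cnv <- base$alteration_class %in% cnv_classes() & !is.na(cn) &
    (cn > 3 | cn < 1)
  keep <- keep_snv | keep_cnv
  if (!any(keep)) return(empty_calls())
  new_calls(
    patient_id = base$patient_id[keep],
    sample_id = paste0(base$patient_id[keep], "-", suffix),
    timepoint = factor(timepoint, levels = timepoint_levels()),
    source = "plasma",
    gene = base$gene[keep],
    alteration_class = base$alteration_class[keep],
    vaf = vaf[keep],
    copy_number = ifelse(base$alteration_class[keep] %in% cnv_classes(),
                         cn[keep], NA_real_),
    is_nonsynonymous = base$is_nonsynonymous[keep]
  )
}

# Paired tumor tissue: plasma baseline gene set minus a few plasma-only
# genes, plus a few tissue-only genes; tissue VAFs run higher than plasma.
draw_tissue_calls <- function(baseline_calls, tissue, genes, config) {
  out <- list()
  for (p in tissue) {
    base <- baseline_calls[baseline_calls$patient_id == p, ]
    plasma_genes <- unique(base$gene)
    n_drop <- min(rpois(1, config$tissue_discordance_mean),
                  length(plasma_genes))
    drop <- if (n_drop > 0) sample(plasma_genes, n_drop) else character()
    shared <- base[!base$gene %in% drop, ]
    n_add <- rpois(1, config$tissue_discordance_mean)
    pool <- setdiff(genes, plasma_genes)
    add <- if (n_add > 0) sample(pool, min(n_add, length(pool))) else character()
    k <- length(add)
    added <- new_calls(
      patient_id = rep(p, k), sample_id = rep(paste0(p, "-T"), k),
      timepoint = factor(rep("baseline", k), levels = timepoint_levels()),
      source = rep("tissue", k), gene = add,
      alteration_class = rep("missense", k),
      vaf = pmax(rbeta(k, 1.5, 7.5), 0.002),  # tissue VAFs ~3x plasma
      copy_number = rep(NA_real_, k),
      is_nonsynonymous = rep(TRUE, k)
    )
    shared$sample_id <- paste0(p, "-T")
    shared$source <- "tissue"
    shared$vaf <- pmin(shared$vaf * runif(nrow(shared), 2, 4.5), 0.98)
    out[[length(out) + 1]] <- dplyr::bind_rows(shared, added)
  }
  if (length(out) == 0) return(empty_calls())
  dplyr::bind_rows(out)
}

draw_clinical <- function(patients, pfs, event, response) {
  n <- length(patients)
  tibble::tibble(
    patient_id = patients,
    pfs_months = round(pfs, 3),
    event = event,
    best_response = response,
    age_group = sample(c("le50", "gt50"), n, TRUE, prob = c(45, 25)),
    histology = sample(c("IDC", "other"), n, TRUE, prob = c(58, 12)),
    grade = sample(c("I-II", "III"), n, TRUE, prob = c(12, 39)),
    dfi_group = sample(c("le12", "gt12"), n, TRUE, prob = c(23, 47)),
    t_stage = sample(1:3, n, TRUE),
    n_stage = sample(1:3, n, TRUE),
    ki67_group = sample(c("lt30", "ge30"), n, TRUE),
    metastasis_site = sample(c("visceral", "non_visceral"), n, TRUE,
                             prob = c(56, 14))
  )
}

# CEA/CA125/CA153: patient-level log-normal intercepts, per-timepoint
# noise, deliberately uncoupled from ctDNA burden; tumor size follows a
# monotone power link to burden with log-normal noise and shrinks/rebounds
# with response over the treatment course.
draw_measurements <- function(patients, burden, response, dynamic,
                              progression, config) {
  n <- length(patients)
  size_factor <- c(CR = 0.25, PR = 0.55, SD = 0.9, PD = 1.3)
  base_size <- exp(log(42) + 0.35 * (log(pmax(burden, 0.002)) - log(0.04)) +
                     rnorm(n, 0, config$tumor_size_noise_sd))
  base_size <- pmax(base_size, 5)
  cea0 <- rlnorm(n, log(3), 0.8)
  ca125_0 <- rlnorm(n, log(20), 0.9)
  ca153_0 <- rlnorm(n, log(22), 0.8)
  rows <- list(tibble::tibble(
    patient_id = patients, timepoint = "baseline",
    tumor_size_mm = round(base_size, 1),
    cea = round(cea0 * rlnorm(n, 0, 0.2), 2),
    ca125 = round(ca125_0 * rlnorm(n, 0, 0.2), 2),
    ca153 = round(ca153_0 * rlnorm(n, 0, 0.2), 2)
  ))
  idx_d <- match(dynamic, patients)
  fd <- size_factor[response[idx_d]] * rlnorm(length(idx_d), 0, 0.15)
  size_d <- pmax(base_size[idx_d] * fd, 2)
  rows[[2]] <- tibble::tibble(
    patient_id = dynamic, timepoint = "during_treatment",
    tumor_size_mm = round(size_d, 1),
    cea = round(cea0[idx_d] * rlnorm(length(idx_d), 0, 0.3), 2),
    ca125 = round(ca125_0[idx_d] * rlnorm(length(idx_d), 0, 0.3), 2),
    ca153 = round(ca153_0[idx_d] * rlnorm(length(idx_d), 0, 0.3), 2)
  )
  idx_p <- match(progression, patients)
  size_p <- pmax(size_d[match(progression, dynamic)] *
                   runif(length(idx_p), 1.2, 1.8), 5)
  rows[[3]] <- tibble::tibble(
    patient_id = progression, timepoint = "progression",
    tumor_size_mm = round(size_p, 1),
    cea = round(cea0[idx_p] * rlnorm(length(idx_p), 0, 0.3), 2),
    ca125 = round(ca125_0[idx_p] * rlnorm(length(idx_p), 0, 0.3), 2),
    ca153 = round(ca153_0[idx_p] * rlnorm(length(idx_p), 0, 0.3), 2)
  )
  dplyr::bind_rows(rows) |>
    dplyr::mutate(timepoint = factor(.data$timepoint,
                                     levels = timepoint_levels())) |>
    dplyr::arrange(.data$patient_id, .data$timepoint)
}

# Serum elevation flags use the usual clinical upper reference limits.
attach_elevation_flags <- function(clinical, measurements) {
  base <- dplyr::filter(measurements, .data$timepoint == "baseline")
  idx <- match(clinical$patient_id, base$patient_id)
  clinical$cea_elevated <- base$cea[idx] > 5
  clinical$ca125_elevated <- base$ca125[idx] > 35
  clinical$ca153_elevated <- base$ca153[idx] > 30
  clinical
}
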