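#' Read a somatic variant call table
#'
#' Reads a flat, MAF-like tab-delimited table of gene-level SNV/indel calls,
#' one row per call. Required columns: `patient_id`, `sample_id`,
#' `timepoint`, `gene`, `alteration_class`, `vaf`. An optional
#' `is_nonsynonymous` logical column marks calls that count toward tumor
#' mutational burden; when absent it is inferred from the alteration class
#' (missense, frameshift/in-frame indel and stop-gain calls count;
#' splice-site calls do not).
#'
#' VAFs are accepted either as fractions (`0.125`) or as percentages
#' (`"12.5%"`); both are normalized to fractions in `[0, 1]`.
#'
#' @param path Path to a tab-delimited file.
#' @param source `"plasma"` or `"tissue"`; recorded on every call.
#' @return A tibble of mutation calls with columns `patient_id`, `sample_id`,
#'   `timepoint` (factor: baseline, during_treatment, progression), `source`,
#'   `gene`, `alteration_class`, `vaf`, `copy_number` (all `NA` here),
#'   `is_nonsynonymous`.
#' @seealso [read_cnv_table()], [assemble_cohort()]
#' @export
read_mutation_table <- function(path, source = c("plasma", "tissue")) {
  source <- match.arg(source)
  raw <- read_tsv_checked(path, c("patient_id", "sample_id", "timepoint",
                                  "gene", "alteration_class", "vaf"))
  bad_class <- setdiff(unique(raw$alteration_class), snv_classes())
  if (length(bad_class) > 0) {
    abort(sprintf(
      "unknown alteration_class value(s) in %s: %s (expected one of %s)",
      path, paste(bad_class, collapse = ", "),
      paste(snv_classes(), collapse = ", ")))
  }
  vaf <- parse_vaf(raw$vaf)
  bad_vaf <- which(!is.na(vaf) & (vaf < 0 | vaf > 1))
  if (length(bad_vaf) > 0) {
    abort(sprintf("VAF outside [0, 1] at row(s) %s of %s",
                  paste(head(bad_vaf, 5), collapse = ", "), path))
  }
  nonsyn <- if ("is_nonsynonymous" %in% names(raw)) {
    as.logical(raw$is_nonsynonymous)
  } else {
    raw$alteration_class %in% c("missense", "frameshift_indel",
                                "inframe_indel", "stop_gain")
  }
  new_calls(
    patient_id = trimws(raw$patient_id),
    sample_id = trimws(raw$sample_id),
    timepoint = parse_timepoint(raw$timepoint),
    source = source,
    gene = trimws(raw$gene),
    alteration_class = raw$alteration_class,
    vaf = vaf,
    copy_number = NA_real_,
    is_nonsynonymous = nonsyn
  )
}

#' Read a gene-level copy-number table and call gains/losses
#'
#' Reads a tab-delimited table of per-gene copy-number estimates (required
#' columns `patient_id`, `sample_id`, `timepoint`, `gene`, `copy_number`),
#' classifies each row with [classify_cnv()], and returns the gain/loss rows
#' as mutation calls (`alteration_class` `"CNG"`/`"CNL"`). Copy-neutral rows
#' are dropped: a neutral gene is not an alteration.
#'
#' @inheritParams read_mutation_table
#' @param gain_threshold,loss_threshold Strict thresholds passed to
#'   [classify_cnv()]; defaults 3 and 1 copies.
#' @return A tibble of CNV calls in the same shape as
#'   [read_mutation_table()] output (`vaf` is `NA`, `copy_number` filled).
#' @export
read_cnv_table <- function(path, source = c("plasma", "tissue"),
                           gain_threshold = 3, loss_threshold = 1) {
  source <- match.arg(source)
  raw <- read_tsv_checked(path, c("patient_id", "sample_id", "timepoint",
                                  "gene", "copy_number"))
  cn <- as.numeric(raw$copy_number)
  state <- classify_cnv(cn, gain_threshold, loss_threshold)
  keep <- state != "neutral"
  new_calls(
    patient_id = trimws(raw$patient_id)[keep],
    sample_id = trimws(raw$sample_id)[keep],
    timepoint = parse_timepoint(raw$timepoint[keep]),
    source = source,
    gene = trimws(raw$gene)[keep],
    alteration_class = ifelse(state[keep] == "gain", "CNG", "CNL"),
    vaf = NA_real_,
    copy_number = cn[keep],
    is_nonsynonymous = FALSE
  )
}

#' Read the per-patient clinical table
#'
#' Required columns: `patient_id`, `pfs_months` (positive), `event` (0/1 or
#' logical: progression or death observed), `best_response` (PD/SD/PR/CR).
#' Any further columns (age group, histology, grade, disease-free interval,
#' T/N stage, serum-marker elevation flags, Ki-67 group, metastasis site,
#' TMB group, ...) are carried through untouched as covariates.
#'
#' @param path Path to a tab-delimited file.
#' @return A tibble, `best_response` as an ordered factor PD < SD < PR < CR.
#' @export
read_clinical_table <- function(path) {
  raw <- read_tsv_checked(path, c("patient_id", "pfs_months", "event",
                                  "best_response"))
  raw$patient_id <- trimws(raw$patient_id)
  raw$pfs_months <- as.numeric(raw$pfs_months)
  if (any(is.na(raw$pfs_months) | raw$pfs_months <= 0)) {
    abort(sprintf("pfs_months must be positive in %s", path))
  }
  raw$event <- as.logical(as.integer(raw$event))
  bad <- setdiff(unique(raw$best_response), response_levels())
  if (length(bad) > 0) {
    abort(sprintf("unknown best_response value(s) in %s: %s",
                  path, paste(bad, collapse = ", ")))
  }
  raw$best_response <- factor(raw$best_response, levels = response_levels(),
                              ordered = TRUE)
  raw
}

#' Read the per-timepoint measurement table
#'
#' Longitudinal clinical channels: tumor size on imaging and the serum
#' markers CEA, CA125 and CA153, one row per (patient, timepoint).
#' Required columns: `patient_id`, `timepoint`, `tumor_size_mm`, `cea`,
#' `ca125`, `ca153`.
#'
#' @param path Path to a tab-delimited file.
#' @return A tibble with `timepoint` as a factor.
#' @export
read_measurement_table <- function(path) {
  raw <- read_tsv_checked(path, c("patient_id", "timepoint", "tumor_size_mm",
                                  "cea", "ca125", "ca153"))
  raw$patient_id <- trimws(raw$patient_id)
  raw$timepoint <- parse_timepoint(raw$timepoint)
  for (col in c("tumor_size_mm", "cea", "ca125", "ca153")) {
    raw[[col]] <- as.numeric(raw[[col]])
  }
  raw
}

#' Write mutation calls back to a tab-delimited file
#'
#' Inverse of [read_mutation_table()] / [read_cnv_table()]: SNV/indel calls
#' round-trip exactly through [read_mutation_table()].
#'
#' @param calls A calls tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutation_table <- function(calls, path) {
  out <- dplyr::mutate(calls, timepoint = as.character(.data$timepoint))
  readr::write_tsv(out, path)
  invisible(path)
}

#' Assemble a cohort from calls and clinical tables
#'
#' Groups mutation calls into per-(patient, timepoint, source) sample
#' profiles and binds them to the clinical table. Every call's `patient_id`
#' must appear in the clinical table; orphans are an error.
#'
#' @param calls A calls tibble (rows from [read_mutation_table()] and/or
#'   [read_cnv_table()]; may be empty).
#' @param clinical A per-patient clinical tibble ([read_clinical_table()]).
#' @param measurements Optional per-timepoint measurement tibble
#'   ([read_measurement_table()]).
#' @param sample_manifest Optional tibble of sequenced samples
#'   (`patient_id`, `sample_id`, `timepoint`, `source`). When given, every
#'   manifest sample gets a profile even with zero somatic calls — a
#'   sequenced sample without alterations is a (ctDNA-negative) sample, not
#'   a missing one. Without it, profiles are derived from the calls alone.
#' @return A `ctdna_cohort` object: a list with elements `calls`,
#'   `clinical`, `measurements`, and `samples` (one row per profile, with a
#'   nested `calls` list-column).
#' @examples
#' sim <- simulate_cohort(cohort_config(n_patients = 12, n_genes = 40,
#'                                      n_dynamic = 6), seed = 1)
#' cohort <- assemble_cohort(sim$calls, sim$clinical, sim$measurements,
#'                           sim$sample_manifest)
#' cohort
#' @export
assemble_cohort <- function(calls, clinical, measurements = NULL,
                            sample_manifest = NULL) {
  if (nrow(calls) > 0) {
    orphans <- setdiff(unique(calls$patient_id), clinical$patient_id)
    if (length(orphans) > 0) {
      abort(sprintf("calls reference patient_id(s) absent from clinical: %s",
                    paste(orphans, collapse = ", ")))
    }
  }
  samples <- calls |>
    dplyr::group_by(.data$patient_id, .data$sample_id, .data$timepoint,
                    .data$source) |>
    tidyr::nest(calls = !c("patient_id", "sample_id", "timepoint", "source")) |>
    dplyr::ungroup()
  if (!is.null(sample_manifest)) {
    manifest <- dplyr::mutate(
      sample_manifest,
      timepoint = factor(as.character(.data$timepoint),
                         levels = timepoint_levels()))
    extra <- dplyr::anti_join(
      manifest, samples,
      by = c("patient_id", "sample_id", "timepoint", "source"))
    if (nrow(extra) > 0) {
      no_id <- c("patient_id", "sample_id", "timepoint", "source")
      extra$calls <- rep(list(empty_calls()[, setdiff(names(empty_calls()),
                                                      no_id)]),
                         nrow(extra))
      samples <- dplyr::bind_rows(samples, extra)
    }
  }
  samples <- dplyr::arrange(samples, .data$patient_id, .data$timepoint,
                            .data$source)
  structure(
    list(calls = calls, clinical = clinical,
         measurements = measurements, samples = samples),
    class = "ctdna_cohort"
  )
}

#' @export
print.ctdna_cohort <- function(x, ...) {
  n_pat <- nrow(x$clinical)
  n_samp <- nrow(x$samples)
  cat(sprintf("<ctdna_cohort> %d patients, %d samples, %d calls\n",
              n_pat, n_samp, nrow(x$calls)))
  tab <- table(source = x$samples$source, timepoint = x$samples$timepoint)
  print(tab)
  invisible(x)
}

#' Baseline plasma sample profiles of a cohort
#'
#' @param cohort A `ctdna_cohort`.
#' @return The `samples` rows with `timepoint == "baseline"` and
#'   `source == "plasma"`.
#' @export
baseline_samples <- function(cohort) {
  dplyr::filter(cohort$samples,
                .data$timepoint == "baseline", .data$source == "plasma")
}

#' Read a gene panel list
#'
#' One HGNC-style symbol per line; blank lines ignored. Symbols are matched
#' case-sensitively after whitespace trimming throughout the package.
#'
#' @param path Path to the list file.
#' @return Character vector of gene symbols.
#' @export
read_panel_genes <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' Read an analysis configuration from YAML
#'
#' Recognized keys: `panel_megabases` (panel footprint for TMB),
#' `gain_threshold`, `loss_threshold`, `min_fraction` (gene-frequency
#' filter), `minprop` (cut-point scan), `seed`. Missing keys fall back to
#' package defaults.
#'
#' @param path Path to a YAML file, or `NULL` for all defaults.
#' @return A named list of settings.
#' @export
read_analysis_config <- function(path = NULL) {
  defaults <- list(panel_megabases = 1.5, gain_threshold = 3,
                   loss_threshold = 1, min_fraction = 0.05,
                   minprop = 0.1, seed = 1L)
  if (is.null(path)) return(defaults)
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("reading YAML config requires the 'yaml' package")
  }
  user <- yaml::read_yaml(path)
  utils::modifyList(defaults, user[intersect(names(user), names(defaults))])
}

# internal helpers -----------------------------------------------------------

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(out))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  out
}

# Accept "0.125", "12.5%" and "12.5 %" dialects; percent implies /100.
parse_vaf <- function(x) {
  x <- trimws(as.character(x))
  pct <- grepl("%$", x)
  num <- suppressWarnings(as.numeric(sub("%$", "", x)))
  bad <- !is.na(x) & nzchar(x) & is.na(num)
  if (any(bad)) {
    abort(sprintf("unparseable VAF value(s): %s",
                  paste(unique(x[bad]), collapse = ", ")))
  }
  ifelse(pct, num / 100, num)
}

parse_timepoint <- function(x) {
  x <- trimws(as.character(x))
  bad <- setdiff(unique(x), timepoint_levels())
  if (length(bad) > 0) {
    abort(sprintf("unknown timepoint value(s): %s (expected %s)",
                  paste(bad, collapse = ", "),
                  paste(timepoint_levels(), collapse = ", ")))
  }
  factor(x, levels = timepoint_levels())
}

new_calls <- function(...) {
  tibble::tibble(...)
}

empty_calls <- function() {
  new_calls(
    patient_id = character(), sample_id = character(),
    timepoint = factor(character(), levels = timepoint_levels()),
    source = character(), gene = character(),
    alteration_class = character(), vaf = double(),
    copy_number = double(), is_nonsynonymous = logical()
  )
}
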