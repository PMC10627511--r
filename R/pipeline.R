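#' Run the full ctDNA cohort analysis end to end
#'
#' Simulates (or accepts) a cohort and runs every analysis stage in order:
#' per-sample biomarkers; gene-frequency filter and univariate Cox screen;
#' ctDNA+/- classification against the selected panel; baseline survival
#' stratification by ctDNA status; maximally selected cut-points for TMB,
#' MATH score and ctDNA fraction with the induced Kaplan-Meier
#' comparisons; the multivariable Cox model of ctDNA status plus clinical
#' covariates; response-group marker comparisons; and longitudinal
#' monitoring (trajectories, persistence grouping with its survival
#' comparison, and the marker / tumor-size Spearman matrix).
#'
#' With a fixed seed the run is fully deterministic: the result tables, and
#' the TSV files written when `out_dir` is given, are identical across
#' runs.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed for the simulation.
#' @param out_dir Optional directory; when given, the input tables and
#'   every result table are written there as TSVs.
#' @param min_fraction Gene-frequency filter threshold (default 0.05).
#' @param minprop Cut-point scan group-minimum (default 0.1).
#' @return A list of class `ctdna_analysis` with elements `sim`, `cohort`,
#'   `biomarkers`, `candidates`, `screen`, `panel`, `status`,
#'   `km_ctdna_baseline`, `cutpoints`, `km_markers`, `cox`,
#'   `response_tests`, `trajectories`, `persistence`, `km_persistence`,
#'   `correlations`.
#' @export
run_cohort_analysis <- function(config = cohort_config(), seed = 1,
                                out_dir = NULL, min_fraction = 0.05,
                                minprop = 0.1) {
  sim <- simulate_cohort(config, seed)
  cohort <- assemble_cohort(sim$calls, sim$clinical, sim$measurements,
                            sim$sample_manifest)
  mb <- config$panel_megabases

  markers <- sample_biomarkers(cohort, panel_megabases = mb)
  candidates <- gene_frequency_filter(cohort, min_fraction = min_fraction)
  screen <- univariate_cox_screen(cohort, candidates)
  panel <- selected_panel(screen)
  if (nrow(panel) == 0) {
    abort("screen selected no genes; cannot classify ctDNA status")
  }
  status <- classify_ctdna_status(cohort, panel)

  base_status <- status |>
    dplyr::filter(.data$timepoint == "baseline") |>
    dplyr::select("patient_id", "ctdna_status")
  clin <- dplyr::left_join(cohort$clinical, base_status, by = "patient_id")
  km_ctdna <- km_median_and_logrank(clin, time = "pfs_months",
                                    event = "event", group = "ctdna_status")

  base_markers <- markers |>
    dplyr::filter(.data$timepoint == "baseline", .data$source == "plasma") |>
    dplyr::left_join(
      dplyr::select(clin, "patient_id", "pfs_months", "event",
                    "best_response"),
      by = "patient_id")
  marker_cols <- c("tmb", "math_score", "ctdna_fraction")
  cutpoints <- list()
  km_markers <- list()
  for (m in marker_cols) {
    ok <- !is.na(base_markers[[m]])
    cp <- maximally_selected_cutpoint(base_markers[[m]][ok],
                                      base_markers$pfs_months[ok],
                                      base_markers$event[ok],
                                      minprop = minprop)
    cutpoints[[m]] <- cp
    grp <- dichotomize(base_markers[[m]][ok], cp$cutpoint)
    km_markers[[m]] <- km_median_and_logrank(
      tibble::tibble(time = base_markers$pfs_months[ok],
                     event = base_markers$event[ok], group = grp),
      group = "group")
  }

  covariates <- c("ctdna_status", "age_group", "histology", "grade",
                  "dfi_group", "t_stage", "n_stage", "cea_elevated",
                  "ca125_elevated", "ca153_elevated", "ki67_group",
                  "metastasis_site")
  cox <- multivariable_cox(clin, covariates)

  response_tests <- purrr::map(
    setNames(marker_cols, marker_cols),
    function(m) {
      ok <- !is.na(base_markers[[m]])
      response_group_compare(base_markers[[m]][ok],
                             base_markers$best_response[ok])
    })

  trajectories <- build_trajectories(cohort, panel, panel_megabases = mb)
  persistence <- suppressWarnings(group_by_persistence(trajectories))
  km_persistence <- NULL
  if (nrow(persistence) > 0 && nlevels(droplevels(persistence$group)) == 2) {
    pers_clin <- dplyr::inner_join(
      dplyr::select(persistence, "patient_id", "group"),
      cohort$clinical, by = "patient_id")
    km_persistence <- km_median_and_logrank(pers_clin, time = "pfs_months",
                                            event = "event", group = "group")
  }
  correlations <- marker_size_correlation(trajectories)

  out <- structure(
    list(sim = sim, cohort = cohort, biomarkers = markers,
         candidates = candidates, screen = screen, panel = panel,
         status = status, km_ctdna_baseline = km_ctdna,
         cutpoints = cutpoints, km_markers = km_markers, cox = cox,
         response_tests = response_tests, trajectories = trajectories,
         persistence = persistence, km_persistence = km_persistence,
         correlations = correlations),
    class = "ctdna_analysis")
  if (!is.null(out_dir)) write_analysis_tables(out, out_dir)
  out
}

#' @export
print.ctdna_analysis <- function(x, ...) {
  cat(sprintf("<ctdna_analysis> %d patients, %d plasma samples\n",
              nrow(x$cohort$clinical),
              sum(x$cohort$samples$source == "plasma")))
  cat(sprintf("screen: %d candidates, %d selected\n",
              nrow(x$screen$panel), nrow(x$panel)))
  cat(sprintf("baseline ctDNA+ fraction: %.2f\n",
              mean(dplyr::filter(x$status, .data$timepoint == "baseline")$
                     ctdna_status == "positive")))
  cuts <- vapply(x$cutpoints, function(cp) cp$cutpoint, double(1))
  cat("marker cut-points:",
      paste(sprintf("%s = %.4g", names(cuts), cuts), collapse = ", "), "\n")
  invisible(x)
}

write_analysis_tables <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort_tables(x$sim, dir)
  wt <- function(df, name) {
    df <- dplyr::mutate(df, dplyr::across(
      dplyr::where(is.factor), as.character))
    readr::write_tsv(df, file.path(dir, name))
  }
  wt(x$biomarkers, "biomarkers.tsv")
  wt(x$screen$panel, "screen.tsv")
  wt(x$status, "ctdna_status.tsv")
  cuts <- purrr::imap_dfr(x$cutpoints, function(cp, m) {
    tibble::tibble(marker = m, cutpoint = cp$cutpoint,
                   statistic = cp$statistic)
  })
  wt(cuts, "cutpoints.tsv")
  wt(dplyr::bind_rows(
    dplyr::mutate(x$km_ctdna_baseline$medians, comparison = "ctdna_status"),
    purrr::imap_dfr(x$km_markers, function(km, m) {
      dplyr::mutate(km$medians, comparison = m)
    })), "km_medians.tsv")
  wt(x$cox$terms, "cox_table.tsv")
  wt(x$trajectories, "trajectories.tsv")
  wt(x$persistence, "persistence.tsv")
  wt(tidy(x$correlations), "correlations.tsv")
  invisible(dir)
}
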