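#' Build per-patient longitudinal marker trajectories
#'
#' Joins the per-sample ctDNA biomarkers, the panel-based ctDNA status and
#' the clinical measurement channels (tumor size, CEA, CA125, CA153) into
#' one row per (patient, timepoint) for plasma samples, ordered by
#' timepoint. A patient is `persistent_positive` when ctDNA-positive at
#' every timepoint observed for them.
#'
#' @param cohort A `ctdna_cohort` with a `measurements` table.
#' @param panel A selected panel tibble or `gene_screen` (see
#'   [classify_ctdna_status()]).
#' @param panel_megabases Panel footprint for TMB (default 1.5 Mb).
#' @return A tibble with columns `patient_id`, `timepoint`, `ctdna_status`,
#'   `max_vaf`, `ctdna_fraction`, `math_score`, `tmb`, `tumor_size_mm`,
#'   `cea`, `ca125`, `ca153`, `n_timepoints`, `persistent_positive`.
#' @export
build_trajectories <- function(cohort, panel, panel_megabases = 1.5) {
  markers <- sample_biomarkers(cohort, panel_megabases) |>
    dplyr::filter(.data$source == "plasma")
  status <- classify_ctdna_status(cohort, panel) |>
    dplyr::select("patient_id", "timepoint", "ctdna_status")
  traj <- markers |>
    dplyr::left_join(status, by = c("patient_id", "timepoint")) |>
    dplyr::select("patient_id", "timepoint", "ctdna_status", "max_vaf",
                  "ctdna_fraction", "math_score", "tmb")
  if (!is.null(cohort$measurements)) {
    traj <- dplyr::left_join(traj, cohort$measurements,
                             by = c("patient_id", "timepoint"))
  } else {
    traj$tumor_size_mm <- NA_real_
    traj$cea <- NA_real_; traj$ca125 <- NA_real_; traj$ca153 <- NA_real_
  }
  traj |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::mutate(
      n_timepoints = dplyr::n(),
      persistent_positive = all(.data$ctdna_status == "positive")
    ) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$patient_id, .data$timepoint)
}

#' Partition patients by persistent ctDNA positivity
#'
#' Patients positive at every observed timepoint form the `all_positive`
#' group; patients negative at least once form `other`. Patients with fewer
#' than `min_timepoints` observed timepoints are excluded with a warning —
#' a single sample cannot show persistence.
#'
#' @param trajectories A trajectory tibble from [build_trajectories()].
#' @param min_timepoints Minimum observed timepoints to be eligible
#'   (default 2).
#' @return A tibble with one row per eligible patient: `patient_id`,
#'   `n_timepoints`, `persistent_positive`, `group` (factor
#'   `all_positive`/`other`).
#' @export
group_by_persistence <- function(trajectories, min_timepoints = 2) {
  per_patient <- trajectories |>
    dplyr::distinct(.data$patient_id, .data$n_timepoints,
                    .data$persistent_positive)
  excluded <- dplyr::filter(per_patient, .data$n_timepoints < min_timepoints)
  if (nrow(excluded) > 0) {
    warn(sprintf("%d patient(s) with fewer than %d timepoints excluded",
                 nrow(excluded), min_timepoints))
  }
  per_patient |>
    dplyr::filter(.data$n_timepoints >= min_timepoints) |>
    dplyr::mutate(group = factor(
      ifelse(.data$persistent_positive, "all_positive", "other"),
      levels = c("all_positive", "other")))
}

#' Spearman correlation matrix of tumor size, serum markers and ctDNA markers
#'
#' Pools all (patient, timepoint) observations and computes pairwise
#' Spearman rank correlations (with two-sided p-values from the
#' t-approximation, ties handled by mid-ranks) among tumor size, the serum
#' markers CEA/CA125/CA153 and the ctDNA markers TMB, MATH score and ctDNA
#' fraction. Pairs with fewer than 3 complete observations yield `NA`.
#' Repeated measures per patient are pooled without a clustering
#' correction.
#'
#' @param trajectories A trajectory tibble from [build_trajectories()].
#' @param variables Character vector of columns to correlate.
#' @return A list of class `marker_correlation`: matrices `rho`, `p_value`,
#'   `n_pairs`.
#' @export
marker_size_correlation <- function(trajectories,
                                    variables = c("tumor_size_mm", "cea",
                                                  "ca125", "ca153", "tmb",
                                                  "math_score",
                                                  "ctdna_fraction")) {
  missing_cols <- setdiff(variables, names(trajectories))
  if (length(missing_cols) > 0) {
    abort(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  k <- length(variables)
  rho <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  p <- rho
  npairs <- matrix(0L, k, k, dimnames = list(variables, variables))
  for (i in seq_len(k)) {
    for (j in seq_len(i)) {
      x <- trajectories[[variables[i]]]
      y <- trajectories[[variables[j]]]
      ok <- !is.na(x) & !is.na(y)
      npairs[i, j] <- npairs[j, i] <- sum(ok)
      if (sum(ok) >= 3) {
        ct <- suppressWarnings(
          cor.test(x[ok], y[ok], method = "spearman", exact = FALSE))
        rho[i, j] <- rho[j, i] <- unname(ct$estimate)
        p[i, j] <- p[j, i] <- ct$p.value
      }
    }
    rho[i, i] <- 1
    p[i, i] <- 0
  }
  structure(list(rho = rho, p_value = p, n_pairs = npairs),
            class = "marker_correlation")
}

#' @export
print.marker_correlation <- function(x, ...) {
  cat("<marker_correlation> Spearman rho:\n")
  print(round(x$rho, 3))
  invisible(x)
}

#' @rdname marker_size_correlation
#' @param x A `marker_correlation`.
#' @param ... Unused.
#' @method tidy marker_correlation
#' @export
tidy.marker_correlation <- function(x, ...) {
  vars <- rownames(x$rho)
  combos <- utils::combn(vars, 2)
  purrr::map_dfr(seq_len(ncol(combos)), function(k) {
    a <- combos[1, k]; b <- combos[2, k]
    tibble::tibble(var1 = a, var2 = b, rho = x$rho[a, b],
                   p_value = x$p_value[a, b], n = x$n_pairs[a, b])
  })
}

#' Correlation heatmap of the marker matrix
#'
#' @param object A `marker_correlation`.
#' @param ... Unused.
#' @return A ggplot tile map of Spearman rho.
#' @method autoplot marker_correlation
#' @export
autoplot.marker_correlation <- function(object, ...) {
  vars <- rownames(object$rho)
  df <- expand.grid(var1 = vars, var2 = vars, stringsAsFactors = FALSE)
  df$rho <- mapply(function(a, b) object$rho[a, b], df$var1, df$var2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$var1, y = .data$var2,
                                   fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white",
                                  high = "steelblue", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman\nrho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
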