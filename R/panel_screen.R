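#' Gene-frequency filter for screening candidates
#'
#' Lists the (gene, alteration type) pairs altered at baseline in strictly
#' more than `min_fraction` of patients. A patient counts once per pair no
#' matter how many calls they carry; SNV/indel classes collapse to type
#' `"SNV"`, copy-number calls keep `"CNG"`/`"CNL"`. With the default 5%
#' threshold on a 70-patient cohort, 4 carriers (5.7%) pass and 3 (4.3%) do
#' not.
#'
#' @param cohort A `ctdna_cohort` with at least one baseline plasma sample.
#' @param min_fraction Strict patient-fraction threshold (default 0.05).
#' @return A tibble `gene`, `alteration_type`, `n_patients`, `frequency`,
#'   sorted by descending frequency.
#' @export
gene_frequency_filter <- function(cohort, min_fraction = 0.05) {
  base <- dplyr::filter(cohort$calls, .data$timepoint == "baseline",
                        .data$source == "plasma")
  n_pat <- nrow(cohort$clinical)
  if (n_pat == 0 || length(unique(base$patient_id)) == 0) {
    abort("cohort has no baseline plasma calls to screen")
  }
  base |>
    dplyr::mutate(alteration_type = alteration_type_of(.data$alteration_class)) |>
    dplyr::distinct(.data$patient_id, .data$gene, .data$alteration_type) |>
    dplyr::count(.data$gene, .data$alteration_type, name = "n_patients") |>
    dplyr::mutate(frequency = .data$n_patients / n_pat) |>
    dplyr::filter(.data$frequency > min_fraction) |>
    dplyr::arrange(dplyr::desc(.data$frequency), .data$gene)
}

#' Univariate Cox screen of candidate gene alterations
#'
#' Fits one Cox proportional-hazards model per candidate (gene, alteration
#' type) pair with the binary predictor "pair altered in the patient's
#' baseline plasma sample" against progression-free survival. A pair is
#' selected into the prognostic panel when its hazard ratio exceeds 1 and
#' its two-sided p-value is below `alpha`. Fits use Efron tie handling and
#' Wald 95% confidence intervals; the selection p-value is the
#' likelihood-ratio p, which stays close to its nominal level down to the
#' handful-of-carriers candidates the >5% frequency filter admits, where
#' the Wald p (also reported, as `p_wald`) becomes anti-conservative.
#' Non-convergent fits (e.g. monotone likelihood under perfect separation)
#' are flagged `unstable` and never selected.
#'
#' @param cohort A `ctdna_cohort` whose clinical table has `pfs_months` and
#'   `event`.
#' @param candidates A tibble with columns `gene` and `alteration_type`,
#'   typically from [gene_frequency_filter()].
#' @param alpha Selection significance level (default 0.05).
#' @return A `gene_screen` object wrapping a tibble with one row per
#'   candidate: `gene`, `alteration_type`, `n_carriers`, `hr`, `ci_low`,
#'   `ci_high`, `p_value`, `unstable`, `selected`. Use [tidy()] /
#'   [glance()] / [autoplot()] on it.
#' @export
univariate_cox_screen <- function(cohort, candidates, alpha = 0.05) {
  stopifnot(all(c("gene", "alteration_type") %in% names(candidates)))
  carriers <- baseline_carrier_matrix(cohort, candidates)
  clin <- cohort$clinical
  surv <- survival::Surv(clin$pfs_months, as.integer(clin$event))
  rows <- purrr::map2_dfr(candidates$gene, candidates$alteration_type,
                          function(g, ty) {
    key <- paste(g, ty, sep = "\r")
    x <- as.integer(clin$patient_id %in% carriers[[key]])
    fit_univariate_cox(g, ty, x, surv)
  })
  rows <- dplyr::mutate(
    rows,
    selected = !.data$unstable & .data$hr > 1 & .data$p_value < alpha
  )
  structure(list(panel = rows, alpha = alpha, n_patients = nrow(clin)),
            class = "gene_screen")
}

fit_univariate_cox <- function(gene, type, x, surv) {
  out <- tibble::tibble(gene = gene, alteration_type = type,
                        n_carriers = sum(x), hr = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        p_value = NA_real_, p_wald = NA_real_,
                        unstable = FALSE)
  if (sum(x) == 0 || sum(x) == length(x)) {
    out$unstable <- TRUE
    return(out)
  }
  fit <- withCallingHandlers(
    survival::coxph(surv ~ x, ties = "efron"),
    warning = function(w) {
      out$unstable <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  s <- summary(fit)
  beta <- s$coefficients[1, "coef"]
  se <- s$coefficients[1, "se(coef)"]
  # monotone-likelihood escape: coefficient walked to +/- infinity
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 15 || se > 50) {
    out$unstable <- TRUE
  }
  out$hr <- unname(exp(beta))
  out$ci_low <- unname(exp(beta - 1.96 * se))
  out$ci_high <- unname(exp(beta + 1.96 * se))
  out$p_value <- stats::pchisq(2 * (fit$loglik[2] - fit$loglik[1]), df = 1,
                               lower.tail = FALSE)
  out$p_wald <- unname(s$coefficients[1, "Pr(>|z|)"])
  out
}

# For each candidate pair, the set of patients carrying it at baseline in
# plasma. Keyed "gene\rtype" to survive odd gene symbols.
baseline_carrier_matrix <- function(cohort, candidates) {
  base <- dplyr::filter(cohort$calls, .data$timepoint == "baseline",
                        .data$source == "plasma") |>
    dplyr::mutate(alteration_type = alteration_type_of(.data$alteration_class))
  keys <- paste(candidates$gene, candidates$alteration_type, sep = "\r")
  carriers <- lapply(seq_along(keys), function(i) {
    unique(base$patient_id[base$gene == candidates$gene[i] &
                             base$alteration_type == candidates$alteration_type[i]])
  })
  setNames(carriers, keys)
}

#' The selected prognostic gene panel of a screen
#'
#' @param screen A `gene_screen`.
#' @return The selected rows of the screen table (a `GenePanel`).
#' @export
selected_panel <- function(screen) {
  dplyr::filter(screen$panel, .data$selected)
}

#' @export
print.gene_screen <- function(x, ...) {
  cat(sprintf("<gene_screen> %d candidates, %d selected (alpha = %g, n = %d)\n",
              nrow(x$panel), sum(x$panel$selected), x$alpha, x$n_patients))
  print(selected_panel(x))
  invisible(x)
}

#' @rdname univariate_cox_screen
#' @param x A `gene_screen`.
#' @param ... Unused.
#' @method tidy gene_screen
#' @export
tidy.gene_screen <- function(x, ...) {
  x$panel
}

#' @rdname univariate_cox_screen
#' @method glance gene_screen
#' @export
glance.gene_screen <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x$panel),
    n_selected = sum(x$panel$selected),
    n_unstable = sum(x$panel$unstable),
    alpha = x$alpha,
    n_patients = x$n_patients
  )
}

#' Forest plot of a gene screen
#'
#' Hazard ratios with 95% Wald intervals per candidate, selected pairs
#' highlighted, on a log scale.
#'
#' @param object A `gene_screen`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gene_screen
#' @export
autoplot.gene_screen <- function(object, ...) {
  df <- dplyr::filter(object$panel, !.data$unstable) |>
    dplyr::mutate(label = paste0(.data$gene, " (", .data$alteration_type, ")"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hr,
                                   y = stats::reorder(.data$label, .data$hr),
                                   color = .data$selected)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, color = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard ratio (95% CI)", y = NULL,
                  color = "Selected") +
    ggplot2::theme_minimal()
}

#' Classify samples as ctDNA-positive or ctDNA-negative
#'
#' A plasma sample is ctDNA-positive when it carries at least one alteration
#' matching a selected panel entry on both gene symbol and alteration type
#' (an SNV/indel call matches a panel `"SNV"` entry; a copy-number gain
#' matches `"CNG"`; a loss matches `"CNL"`). Adding calls can only turn a
#' negative sample positive, never the reverse.
#'
#' @param cohort A `ctdna_cohort`.
#' @param panel A panel tibble with columns `gene` and `alteration_type`
#'   (e.g. [selected_panel()] output), or a `gene_screen` whose selected
#'   rows are used. Must be non-empty.
#' @return A tibble with one row per plasma sample: identifiers plus
#'   `ctdna_status` (factor `negative`/`positive`).
#' @export
classify_ctdna_status <- function(cohort, panel) {
  if (inherits(panel, "gene_screen")) panel <- selected_panel(panel)
  if (nrow(panel) == 0) abort("panel is empty; cannot classify ctDNA status")
  panel_keys <- paste(panel$gene, panel$alteration_type, sep = "\r")
  samples <- dplyr::filter(cohort$samples, .data$source == "plasma")
  status <- purrr::map_chr(samples$calls, function(calls) {
    keys <- paste(calls$gene, alteration_type_of(calls$alteration_class),
                  sep = "\r")
    if (any(keys %in% panel_keys)) "positive" else "negative"
  })
  samples |>
    dplyr::select(!"calls") |>
    dplyr::mutate(ctdna_status = factor(status,
                                        levels = c("negative", "positive")))
}
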