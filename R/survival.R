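#' Kaplan-Meier medians and log-rank comparison across groups
#'
#' Estimates the Kaplan-Meier survivor curve per group and reports each
#' group's median survival (the first time the estimate drops to 0.5 or
#' below; `NA` when never reached) together with the two-sided log-rank
#' p-value across groups.
#'
#' @param data A data frame.
#' @param time,event,group Column names (strings) of the follow-up time,
#'   event indicator and group label. `group` may be omitted for a single
#'   pooled curve (no test then).
#' @return A list of class `km_compare`: `medians` (tibble with `group`,
#'   `n`, `events`, `median`), `chisq`, `p_value`, and the underlying
#'   `survfit` object.
#' @export
km_median_and_logrank <- function(data, time = "time", event = "event",
                                  group = NULL) {
  t <- data[[time]]; e <- as.integer(as.logical(data[[event]]))
  if (length(t) == 0) abort("no subjects")
  if (is.null(group)) {
    g <- factor(rep("all", length(t)))
  } else {
    g <- factor(data[[group]])
  }
  if (any(table(g) == 0)) abort("a group has zero subjects")
  fit <- survival::survfit(survival::Surv(t, e) ~ g)
  smry <- summary(fit)$table
  if (is.null(dim(smry))) smry <- t(as.matrix(smry))  # single stratum
  medians <- tibble::tibble(
    group = sub("^g=", "", rownames(smry) %||% levels(g)),
    n = unname(smry[, "records"]),
    events = unname(smry[, "events"]),
    median = unname(smry[, "median"])
  )
  chisq <- NA_real_; p <- NA_real_
  if (nlevels(droplevels(g)) > 1) {
    sd <- survival::survdiff(survival::Surv(t, e) ~ g)
    chisq <- sd$chisq
    p <- stats::pchisq(sd$chisq, df = length(sd$n) - 1, lower.tail = FALSE)
  }
  structure(list(medians = medians, chisq = chisq, p_value = p, fit = fit),
            class = "km_compare")
}

#' @export
print.km_compare <- function(x, ...) {
  cat("<km_compare>\n")
  print(x$medians)
  if (!is.na(x$p_value)) {
    cat(sprintf("log-rank chi-square = %.3f, p = %.4g\n", x$chisq, x$p_value))
  }
  invisible(x)
}

#' @rdname km_median_and_logrank
#' @param x A `km_compare`.
#' @param ... Unused.
#' @method tidy km_compare
#' @export
tidy.km_compare <- function(x, ...) {
  x$medians
}

#' @rdname km_median_and_logrank
#' @method glance km_compare
#' @export
glance.km_compare <- function(x, ...) {
  tibble::tibble(n_groups = nrow(x$medians), chisq = x$chisq,
                 p_value = x$p_value)
}

#' Kaplan-Meier step plot of a group comparison
#'
#' @param object A `km_compare`.
#' @param ... Unused.
#' @return A ggplot of the stepped survivor curves.
#' @method autoplot km_compare
#' @export
autoplot.km_compare <- function(object, ...) {
  fit <- object$fit
  strata <- if (is.null(fit$strata)) {
    rep(object$medians$group[1], length(fit$time))
  } else {
    rep(sub("^g=", "", names(fit$strata)), fit$strata)
  }
  df <- tibble::tibble(time = fit$time, surv = fit$surv, group = strata) |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ dplyr::bind_rows(
      tibble::tibble(time = 0, surv = 1), .x)) |>
    dplyr::ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                   color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Survival probability", color = NULL) +
    ggplot2::theme_minimal()
}

#' Multivariable Cox proportional-hazards model
#'
#' One joint Cox fit of progression-free survival on a set of clinical
#' covariates (ctDNA status among them), reporting a hazard ratio, 95% Wald
#' interval and Wald p-value per model term. Rows with a missing value in
#' any covariate are dropped (listwise deletion) and the count of dropped
#' patients is recorded. Convergence problems (e.g. a covariate separating
#' the events perfectly, or collinear covariates) flag the fit unstable
#' rather than failing.
#'
#' @param data A data frame with one row per patient.
#' @param covariates Character vector of covariate column names.
#' @param time,event Column names of follow-up time and event indicator.
#' @return A list of class `cox_table`: `terms` (tibble `term`, `hr`,
#'   `ci_low`, `ci_high`, `p_value`), `n`, `n_dropped`, `unstable`, and the
#'   `coxph` fit.
#' @export
multivariable_cox <- function(data, covariates, time = "pfs_months",
                              event = "event") {
  stopifnot(length(covariates) >= 1)
  missing_cols <- setdiff(c(covariates, time, event), names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  use <- data[, c(time, event, covariates)]
  complete <- complete.cases(use)
  n_dropped <- sum(!complete)
  use <- use[complete, ]
  if (nrow(use) < length(covariates) + 2) abort("too few complete cases")
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time, ", as.integer(as.logical(", event, "))) ~ ",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  unstable <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = use, ties = "efron"),
    warning = function(w) {
      unstable <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  s <- summary(fit)
  co <- s$coefficients
  if (any(!is.finite(co[, "coef"])) || any(co[, "se(coef)"] > 50)) {
    unstable <- TRUE
  }
  terms <- tibble::tibble(
    term = rownames(co),
    hr = unname(exp(co[, "coef"])),
    ci_low = unname(exp(co[, "coef"] - 1.96 * co[, "se(coef)"])),
    ci_high = unname(exp(co[, "coef"] + 1.96 * co[, "se(coef)"])),
    p_value = unname(co[, "Pr(>|z|)"])
  )
  structure(list(terms = terms, n = nrow(use), n_dropped = n_dropped,
                 unstable = unstable, fit = fit),
            class = "cox_table")
}

#' @export
print.cox_table <- function(x, ...) {
  cat(sprintf("<cox_table> n = %d (%d dropped)%s\n", x$n, x$n_dropped,
              if (x$unstable) " [UNSTABLE FIT]" else ""))
  print(x$terms)
  invisible(x)
}

#' @rdname multivariable_cox
#' @param x A `cox_table`.
#' @param ... Unused.
#' @method tidy cox_table
#' @export
tidy.cox_table <- function(x, ...) {
  x$terms
}

#' @rdname multivariable_cox
#' @method glance cox_table
#' @export
glance.cox_table <- function(x, ...) {
  tibble::tibble(n = x$n, n_dropped = x$n_dropped, unstable = x$unstable,
                 concordance = unname(x$fit$concordance["concordance"]))
}

#' Compare a marker across treatment-response groups
#'
#' The primary contrast is progressive disease (PD) against all other
#' response groups pooled, by a two-sided Wilcoxon rank-sum test with the
#' normal approximation and tie correction; all pairwise group contrasts
#' are reported alongside. Empty groups are dropped with a warning.
#'
#' @param values Numeric marker values.
#' @param responses Factor or character of PD/SD/PR/CR labels, same length.
#' @return A list of class `response_compare`: `pd_vs_others_p`,
#'   `pairwise` (tibble `group1`, `group2`, `n1`, `n2`, `p_value`), and
#'   `group_sizes`.
#' @export
response_group_compare <- function(values, responses) {
  stopifnot(length(values) == length(responses))
  keep <- !is.na(values) & !is.na(responses)
  values <- values[keep]
  responses <- factor(as.character(responses[keep]),
                      levels = response_levels())
  sizes <- table(responses)
  empty <- names(sizes)[sizes == 0]
  if (length(empty) > 0) {
    warn(sprintf("empty response group(s) excluded: %s",
                 paste(empty, collapse = ", ")))
    responses <- droplevels(responses)
  }
  if (nlevels(responses) < 2) abort("need at least two non-empty groups")
  pd_p <- if ("PD" %in% levels(responses)) {
    wilcox_p(values[responses == "PD"], values[responses != "PD"])
  } else {
    NA_real_
  }
  combos <- utils::combn(levels(responses), 2)
  pairwise <- purrr::map_dfr(seq_len(ncol(combos)), function(k) {
    a <- combos[1, k]; b <- combos[2, k]
    tibble::tibble(group1 = a, group2 = b,
                   n1 = sum(responses == a), n2 = sum(responses == b),
                   p_value = wilcox_p(values[responses == a],
                                      values[responses == b]))
  })
  structure(list(pd_vs_others_p = pd_p, pairwise = pairwise,
                 group_sizes = sizes),
            class = "response_compare")
}

wilcox_p <- function(x, y) {
  suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = FALSE,
                correct = TRUE)$p.value
  )
}

#' @export
print.response_compare <- function(x, ...) {
  cat(sprintf("<response_compare> PD vs others: p = %.4g\n", x$pd_vs_others_p))
  print(x$pairwise)
  invisible(x)
}

#' @rdname response_group_compare
#' @param x A `response_compare`.
#' @param ... Unused.
#' @method tidy response_compare
#' @export
tidy.response_compare <- function(x, ...) {
  x$pairwise
}

#' Objective response rate
#'
#' The fraction of patients whose best response is complete or partial
#' response: (CR + PR) / n.
#'
#' @param responses Factor or character of PD/SD/PR/CR best responses.
#' @return The response rate as a fraction in `[0, 1]`.
#' @examples
#' objective_response_rate(rep(c("CR", "PR", "SD", "PD"), c(4, 23, 31, 12)))
#' @export
objective_response_rate <- function(responses) {
  responses <- as.character(responses)
  if (length(responses) == 0) abort("no responses")
  bad <- setdiff(unique(responses), response_levels())
  if (length(bad) > 0) {
    abort(sprintf("unknown response value(s): %s", paste(bad, collapse = ", ")))
  }
  mean(responses %in% c("CR", "PR"))
}
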