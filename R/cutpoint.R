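#' Maximally selected log-rank cut-point for a continuous marker
#'
#' Scans every admissible threshold of a continuous marker and returns the
#' one maximizing the absolute standardized log-rank statistic between the
#' two induced survival groups (`value >= cut` vs `value < cut`). A
#' threshold is admissible when it leaves at least a `minprop` fraction of
#' subjects on each side. Ties in the statistic break toward the smallest
#' cut value. This is the "optimal cut-off" procedure commonly used to
#' dichotomize prognostic markers such as TMB, MATH score or ctDNA fraction;
#' the selected statistic is optimized over many looks, so its naive
#' log-rank p-value is anti-conservative and none is reported here.
#'
#' @param values Numeric marker values, one per subject.
#' @param time Positive follow-up times.
#' @param event Logical (or 0/1) event indicators.
#' @param minprop Minimum group fraction on each side (default 0.1, in
#'   (0, 0.5)).
#' @return A list of class `ctdna_cutpoint`: `cutpoint`, `statistic` (the
#'   maximal |Z|), and `candidates`, a tibble of every admissible cut with
#'   its group size and standardized statistic.
#' @examples
#' set.seed(7)
#' x <- runif(120, 0, 10)
#' t <- rexp(120, rate = ifelse(x >= 5, 0.3, 0.1))
#' maximally_selected_cutpoint(x, t, rep(TRUE, 120))
#' @export
maximally_selected_cutpoint <- function(values, time, event, minprop = 0.1) {
  stopifnot(length(values) == length(time), length(time) == length(event))
  if (minprop <= 0 || minprop >= 0.5) abort("minprop must lie in (0, 0.5)")
  keep <- !(is.na(values) | is.na(time) | is.na(event))
  values <- values[keep]; time <- time[keep]; event <- as.logical(event[keep])
  n <- length(values)
  if (length(unique(values)) < 2) {
    abort("no cut-point: fewer than 2 distinct marker values")
  }
  cand <- sort(unique(values))
  n_high <- vapply(cand, function(c) sum(values >= c), integer(1))
  ok <- n_high >= minprop * n & (n - n_high) >= minprop * n
  cand <- cand[ok]
  if (length(cand) == 0) {
    abort("no admissible cut-point at this minprop")
  }
  z <- vapply(cand, function(c) logrank_z(time, event, values >= c), double(1))
  nh <- n_high[ok]
  candidates <- tibble::tibble(cutpoint = cand, n_high = nh,
                               n_low = n - nh, statistic = abs(z))
  best <- which.max(candidates$statistic)  # which.max takes the first: smallest cut
  structure(list(cutpoint = candidates$cutpoint[best],
                 statistic = candidates$statistic[best],
                 candidates = candidates),
            class = "ctdna_cutpoint")
}

#' @export
print.ctdna_cutpoint <- function(x, ...) {
  cat(sprintf("<ctdna_cutpoint> cut = %g, max |standardized log-rank| = %.3f (%d candidates)\n",
              x$cutpoint, x$statistic, nrow(x$candidates)))
  invisible(x)
}

#' @rdname maximally_selected_cutpoint
#' @param x A `ctdna_cutpoint`.
#' @param ... Unused.
#' @method tidy ctdna_cutpoint
#' @export
tidy.ctdna_cutpoint <- function(x, ...) {
  x$candidates
}

#' Profile plot of the cut-point scan
#'
#' @param object A `ctdna_cutpoint`.
#' @param ... Unused.
#' @return A ggplot of |Z| against the candidate cuts, the maximum marked.
#' @method autoplot ctdna_cutpoint
#' @export
autoplot.ctdna_cutpoint <- function(object, ...) {
  ggplot2::ggplot(object$candidates,
                  ggplot2::aes(x = .data$cutpoint, y = .data$statistic)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$cutpoint, linetype = 2,
                        color = "firebrick") +
    ggplot2::labs(x = "Candidate cut-point",
                  y = "|standardized log-rank statistic|") +
    ggplot2::theme_minimal()
}

#' Dichotomize marker values at a cut-point
#'
#' The high group is closed on the cut: `high` iff `value >= cutpoint`,
#' matching the usual ">= cut" labelling of marker-high survival strata.
#'
#' @param values Numeric vector.
#' @param cutpoint The threshold.
#' @return A factor with levels `low`, `high` (`NA` stays `NA`).
#' @export
dichotomize <- function(values, cutpoint) {
  factor(ifelse(values >= cutpoint, "high", "low"), levels = c("low", "high"))
}

# Standardized two-group log-rank statistic Z = U/sqrt(V): U accumulates
# observed-minus-expected events in the high group over distinct event
# times, V the hypergeometric variance. Z = 0 when V = 0 (no usable event).
logrank_z <- function(time, event, high) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; high <- high[ord]
  n <- length(time)
  u <- 0; v <- 0
  i <- 1
  n_risk <- n
  n1_risk <- sum(high)
  while (i <= n) {
    j <- i
    while (j < n && time[j + 1] == time[i]) j <- j + 1
    d <- sum(event[i:j])
    if (d > 0) {
      d1 <- sum(event[i:j] & high[i:j])
      u <- u + d1 - d * n1_risk / n_risk
      if (n_risk > 1) {
        v <- v + d * (n1_risk / n_risk) * (1 - n1_risk / n_risk) *
          (n_risk - d) / (n_risk - 1)
      }
    }
    n_risk <- n_risk - (j - i + 1)
    n1_risk <- n1_risk - sum(high[i:j])
    i <- j + 1
  }
  if (v <= 0) return(0)
  u / sqrt(v)
}
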