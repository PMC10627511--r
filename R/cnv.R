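#' Classify gene-level copy number into gain / loss / neutral
#'
#' A gene is a copy-number gain when its estimate is strictly above
#' `gain_threshold` (default 3 copies) and a loss when strictly below
#' `loss_threshold` (default 1 copy); the boundary values themselves are
#' neutral. The classification is per sample-gene: across samples a gene may
#' carry both gains and losses.
#'
#' @param copy_number Numeric vector of non-negative copy-number estimates.
#' @param gain_threshold,loss_threshold Strict thresholds;
#'   `loss_threshold < gain_threshold` is required.
#' @return A factor with ordered levels `loss < neutral < gain`.
#' @examples
#' classify_cnv(c(0.8, 1, 2.4, 3, 3.5))
#' @export
classify_cnv <- function(copy_number, gain_threshold = 3, loss_threshold = 1) {
  if (loss_threshold >= gain_threshold) {
    abort("loss_threshold must be below gain_threshold")
  }
  copy_number <- as.numeric(copy_number)
  if (any(copy_number < 0, na.rm = TRUE)) {
    abort("copy_number must be non-negative")
  }
  state <- dplyr::case_when(
    copy_number > gain_threshold ~ "gain",
    copy_number < loss_threshold ~ "loss",
    !is.na(copy_number) ~ "neutral"
  )
  factor(state, levels = c("loss", "neutral", "gain"), ordered = TRUE)
}
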