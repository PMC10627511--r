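#' Maximum variant allele frequency of a sample
#'
#' The max-VAF of a sample is the highest somatic VAF among its SNV/indel
#' calls; copy-number calls carry no allele frequency and are ignored.
#'
#' @param calls A calls tibble for one sample (or any set of calls).
#' @return The maximum VAF, or `NA` when the sample has no SNV/indel call.
#' @export
max_vaf <- function(calls) {
  v <- snv_vafs(calls)
  if (length(v) == 0) return(NA_real_)
  max(v)
}

#' ctDNA fraction from a mutant allele fraction
#'
#' Converts a sample-level mutant allele fraction (MAF) into the estimated
#' tumor-derived fraction of cell-free DNA, assuming a diploid background
#' and one mutant copy per tumor genome:
#' \deqn{\mathrm{ctDNA} = \frac{2}{1/\mathrm{MAF} + 1}.}
#' The map is strictly increasing with range (0, 1]; `maf = 0.5` gives 2/3
#' and `maf = 1` gives 1.
#'
#' @param maf Numeric vector of allele fractions in (0, 1]. `NA` passes
#'   through as `NA`.
#' @return The ctDNA fraction(s).
#' @export
ctdna_fraction <- function(maf) {
  maf <- as.numeric(maf)
  bad <- !is.na(maf) & (maf <= 0 | maf > 1)
  if (any(bad)) abort("maf must lie in (0, 1]")
  2 / (1 / maf + 1)
}

#' Mutant-allele tumor heterogeneity (MATH) score
#'
#' The MATH score is the percentage ratio of the width to the center of the
#' per-mutation VAF distribution of a sample: width is the median absolute
#' deviation scaled by 1.4826 (so that it estimates the standard deviation
#' under normality), center is the median:
#' \deqn{\mathrm{MATH} = 100 \times \frac{1.4826\,
#'   \mathrm{median}(|v_i - \tilde v|)}{\tilde v}.}
#' The score is invariant to rescaling all VAFs by a positive constant.
#' Only SNV/indel VAFs enter; copy numbers are never mixed in.
#'
#' @param vafs Numeric vector of VAFs (`NA` dropped).
#' @return The MATH score (non-negative).
#' @examples
#' math_score(c(0.1, 0.2, 0.3))
#' @export
math_score <- function(vafs) {
  v <- as.numeric(vafs)
  v <- v[!is.na(v)]
  if (length(v) == 0) abort("MATH score is undefined for an empty VAF vector")
  m <- median(v)
  if (m <= 0) abort("MATH score is undefined when the median VAF is not positive")
  100 * mad(v, constant = 1.4826) / m
}

#' Tumor mutational burden of a sample
#'
#' Non-synonymous somatic SNV/indel mutations per megabase of panel
#' territory. Copy-number calls never count.
#'
#' @param calls A calls tibble for one sample.
#' @param panel_megabases Sequenced panel footprint in megabases (> 0).
#' @return Mutations per megabase.
#' @export
tmb <- function(calls, panel_megabases) {
  if (!is.numeric(panel_megabases) || panel_megabases <= 0) {
    abort("panel_megabases must be positive")
  }
  n <- sum(calls$alteration_class %in% snv_classes() &
             calls$is_nonsynonymous, na.rm = TRUE)
  n / panel_megabases
}

#' Per-sample ctDNA biomarker table
#'
#' Computes max-VAF, ctDNA fraction (from the sample's max-VAF), MATH score
#' and TMB for every sample profile in a cohort. Samples with no SNV/indel
#' call get `NA` markers (TMB is 0 for an empty sample, not `NA`); a MATH
#' score needs at least one VAF with a positive median.
#'
#' @param cohort A `ctdna_cohort`.
#' @param panel_megabases Panel footprint for TMB (default 1.5 Mb).
#' @return A tibble with one row per sample: `patient_id`, `sample_id`,
#'   `timepoint`, `source`, `n_calls`, `max_vaf`, `ctdna_fraction`,
#'   `math_score`, `tmb`.
#' @examples
#' sim <- simulate_cohort(cohort_config(n_patients = 10, n_genes = 40,
#'                                      n_dynamic = 4), seed = 1)
#' cohort <- assemble_cohort(sim$calls, sim$clinical)
#' sample_biomarkers(cohort)
#' @export
sample_biomarkers <- function(cohort, panel_megabases = 1.5) {
  purrr::pmap_dfr(cohort$samples, function(patient_id, sample_id, timepoint,
                                           source, calls) {
    calls <- dplyr::mutate(calls, patient_id = patient_id)
    mv <- max_vaf(calls)
    vafs <- snv_vafs(calls)
    ms <- if (length(vafs) > 0 && median(vafs) > 0) math_score(vafs) else NA_real_
    tibble::tibble(
      patient_id = patient_id, sample_id = sample_id,
      timepoint = timepoint, source = source,
      n_calls = nrow(calls),
      max_vaf = mv,
      ctdna_fraction = if (is.na(mv)) NA_real_ else ctdna_fraction(mv),
      math_score = ms,
      tmb = tmb(calls, panel_megabases)
    )
  })
}

#' Tissue-plasma concordance rate
#'
#' Concordance between gene-level alterations seen in plasma ctDNA and in
#' paired tumor tissue, across a set of paired comparisons over a fixed gene
#' panel:
#' \deqn{\mathrm{concordance} = \left(1 - \frac{n_{\mathrm{ctDNA~only}} +
#'   n_{\mathrm{tissue~only}}}{n_{\mathrm{panel}} \times
#'   n_{\mathrm{comparisons}}}\right) \times 100\%.}
#'
#' Either pass the plasma-only / tissue-only mutated-gene counts directly,
#' or pass the two mutated-gene sets and let the counts be derived by set
#' difference.
#'
#' @param n_panel_genes Number of genes on the panel (> 0).
#' @param n_comparisons Number of paired plasma-tissue comparisons (> 0).
#' @param plasma_genes,tissue_genes Optional character vectors of mutated
#'   genes on each side, used to derive the specific counts.
#' @param n_ctdna_specific,n_tissue_specific Counts of genes mutated only in
#'   plasma / only in tissue (ignored when the gene sets are given).
#' @return A one-row tibble: `n_panel_genes`, `n_comparisons`,
#'   `n_ctdna_specific`, `n_tissue_specific`, `concordance_pct` (full
#'   precision; round to 2 decimals for display).
#' @examples
#' concordance_rate(457, 13, n_ctdna_specific = 37, n_tissue_specific = 37)
#' @export
concordance_rate <- function(n_panel_genes, n_comparisons,
                             plasma_genes = NULL, tissue_genes = NULL,
                             n_ctdna_specific = NULL,
                             n_tissue_specific = NULL) {
  if (n_panel_genes <= 0 || n_comparisons <= 0) {
    abort("n_panel_genes and n_comparisons must be positive")
  }
  if (!is.null(plasma_genes) || !is.null(tissue_genes)) {
    plasma_genes <- unique(plasma_genes)
    tissue_genes <- unique(tissue_genes)
    n_ctdna_specific <- length(setdiff(plasma_genes, tissue_genes))
    n_tissue_specific <- length(setdiff(tissue_genes, plasma_genes))
  }
  if (is.null(n_ctdna_specific) || is.null(n_tissue_specific)) {
    abort("supply either the gene sets or both specific counts")
  }
  slots <- n_panel_genes * n_comparisons
  discordant <- n_ctdna_specific + n_tissue_specific
  if (discordant > slots) {
    abort("specific counts exceed panel genes x comparisons")
  }
  tibble::tibble(
    n_panel_genes = n_panel_genes,
    n_comparisons = n_comparisons,
    n_ctdna_specific = n_ctdna_specific,
    n_tissue_specific = n_tissue_specific,
    concordance_pct = (1 - discordant / slots) * 100
  )
}

#' Cohort-level tissue-plasma concordance
#'
#' For every patient with both a baseline plasma and a baseline tissue
#' profile, compares the mutated-gene sets and accumulates plasma-specific
#' and tissue-specific counts over all paired comparisons, then applies
#' [concordance_rate()].
#'
#' @param cohort A `ctdna_cohort` containing tissue profiles.
#' @param n_panel_genes Panel size (default 457).
#' @return A one-row tibble as from [concordance_rate()].
#' @export
tissue_plasma_concordance <- function(cohort, n_panel_genes = 457) {
  base <- dplyr::filter(cohort$calls, .data$timepoint == "baseline")
  paired <- intersect(
    unique(base$patient_id[base$source == "plasma"]),
    unique(base$patient_id[base$source == "tissue"])
  )
  if (length(paired) == 0) abort("no patients with paired plasma and tissue")
  n_cs <- 0L
  n_ts <- 0L
  for (p in paired) {
    pg <- unique(base$gene[base$patient_id == p & base$source == "plasma"])
    tg <- unique(base$gene[base$patient_id == p & base$source == "tissue"])
    n_cs <- n_cs + length(setdiff(pg, tg))
    n_ts <- n_ts + length(setdiff(tg, pg))
  }
  concordance_rate(n_panel_genes, length(paired),
                   n_ctdna_specific = n_cs, n_tissue_specific = n_ts)
}

snv_vafs <- function(calls) {
  v <- calls$vaf[calls$alteration_class %in% snv_classes()]
  v[!is.na(v)]
}
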