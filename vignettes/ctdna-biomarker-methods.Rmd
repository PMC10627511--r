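---
title: "ctDNA biomarkers and survival stratification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ctDNA biomarkers and survival stratification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(ctdnamark)
library(dplyr)
```

## The problem

In metastatic triple-negative breast cancer (mTNBC), circulating tumor DNA
(ctDNA) sampled from plasma offers a minimally invasive window on the
tumor's mutational landscape. ctdnamark implements the analysis pipeline
such a study runs once variant calling is done: gene-level somatic call
tables go in; out come per-sample ctDNA markers, a prognosis-relevant
mutated-gene panel, a ctDNA-positive/negative classification, survival
stratifications at optimal marker cut-points, and longitudinal monitoring
summaries. Everything upstream of the call tables (alignment, UMI handling,
variant and copy-number calling) is out of scope, as are wet-lab protocols.

Because the patient-level data of such studies are access-controlled, the
package ships a synthetic-cohort generator that reproduces the statistical
structure the analyses assume; every stage is exercised and tested against
it.

## Per-sample markers

For a plasma sample with SNV/indel variant allele frequencies (VAFs)
$v_1, \dots, v_m$:

* **max-VAF** is $\max_i v_i$ — the highest somatic allele fraction
  detected in the cell-free DNA. Copy-number calls carry no allele
  fraction and never enter.
* **ctDNA fraction** converts a mutant allele fraction into the estimated
  tumor-derived proportion of cfDNA under a diploid background with one
  mutant copy per tumor genome:
  $\mathrm{ctDNA} = 2/(1/\mathrm{MAF} + 1)$.
  The map is strictly increasing on $(0, 1]$ with
  $\mathrm{ctDNA}(0.5) = 2/3$ and $\mathrm{ctDNA}(1) = 1$. Which
  sample-level MAF feeds the formula is a genuine choice; the package
  uses the sample's max-VAF, the only sample-level MAF summary with an
  unambiguous definition, and exposes the conversion as a plain function
  so any other summary can be used.
* **MATH score** (mutant-allele tumor heterogeneity) is the percentage
  ratio of the width to the center of the VAF distribution,
  $100 \times 1.4826\,\mathrm{MAD}/\mathrm{median}$, where MAD is the raw
  median absolute deviation and 1.4826 the usual consistency constant
  that makes the scaled MAD estimate the standard deviation under
  normality. The score is invariant to rescaling all VAFs by a positive
  constant and needs at least one VAF with a positive median.
* **TMB** is the count of non-synonymous SNV/indel calls divided by the
  sequenced panel footprint in megabases. The footprint is not derivable
  from a call table, so it is a required configuration value; the
  synthetic default is 1.5 Mb, a typical footprint for a panel of several
  hundred genes.

Copy-number calls are classified per sample-gene with strict thresholds:
gain above 3 copies, loss below 1, the boundary values themselves neutral.
A gene may be a gain in one sample and a loss in another; no cohort-level
state is ever assigned.

**Tissue–plasma concordance** over a panel of $G$ genes and $K$ paired
comparisons counts the genes mutated only in plasma ($a$) or only in
tissue ($b$) across the pairs:
$\big(1 - (a + b)/(G \cdot K)\big) \times 100\%$. With the published
counts — 37 and 37 discordant genes over $457 \times 13$ slots — the rate
is 98.75%.

## Panel screening and ctDNA status

Candidates are (gene, alteration-type) pairs altered at baseline in
strictly more than 5% of patients — on 70 patients, 4 carriers (5.7%)
pass, 3 (4.3%) do not. A patient counts once per pair regardless of call
multiplicity; SNV and indel classes collapse to one "SNV" type while
copy-number gains and losses stay distinct, because panel membership is
annotated per alteration type. The denominator is the number of enrolled
patients, and screening uses baseline plasma samples only; later
timepoints are classified against the frozen baseline-derived panel.

Each candidate gets a univariate Cox proportional-hazards fit of
progression-free survival (PFS) on the binary carrier indicator (Efron tie
handling). A pair is selected when its hazard ratio exceeds 1 and its
two-sided p-value is below 0.05. Two numerical choices deserve note:

* **Selection p-value.** The Wald p-value is the usual default, but for
  the 4–23-carrier candidates this filter admits at $n = 70$ it is
  visibly anti-conservative: in direct null simulations the
  "HR > 1 and p < 0.05" Wald rule fires at 3.3–6.1% instead of the
  nominal one-sided 2.5%, while the likelihood-ratio p stays at 2.7–3.7%.
  Selection therefore uses the likelihood-ratio p; Wald 95% confidence
  intervals are reported (and the Wald p alongside, as `p_wald`) since
  interval construction is much less affected.
* **Instability.** Fits with monotone likelihood (perfect separation),
  zero or full carriage, or runaway standard errors are flagged unstable
  and never selected.

No multiple-testing correction is applied across candidates — matching the
screening procedure the pipeline replicates — and this is a real
limitation: with ~30–50 candidates, a calibrated 2.5% one-sided rate still
lets through one spurious gene per screen on average. The selected set
should be read as hypothesis-generating.

A plasma sample is **ctDNA-positive** when it carries at least one
alteration matching a selected panel entry on both gene symbol and
alteration type (a KMT2C gain does not match a KMT2C SNV panel entry).
Matching is monotone: adding calls can only turn a sample positive.

## Marker cut-points

Continuous markers (TMB, MATH, ctDNA fraction) are dichotomized at the
maximally selected log-rank cut-point: over every threshold leaving at
least a `minprop` fraction of subjects on each side (default 0.1, the
convention of the standard cut-point tools), the scan computes the
standardized two-group log-rank statistic $Z = U/\sqrt{V}$ — observed
minus expected events in the high group, with the hypergeometric variance
accumulated over distinct event times — and returns the threshold
maximizing $|Z|$, ties broken toward the smallest value. The high group is
closed on the cut (`value >= cut`), matching the usual "marker-high"
labelling. Because the statistic is rank-based, the scan is invariant
under strictly monotone transforms of the marker.

The maximum of many correlated log-rank statistics is optimistic: its
naive $\chi^2_1$ p-value is anti-conservative, so the scan reports the
statistic and no p-value. Improved tail approximations exist but are out
of scope; the test suite instead checks against the Miller–Siegmund bound
that under the null the maximal statistic stays below its 5% critical
value in the expected fraction of simulations. Degenerate inputs (all
values identical, or no admissible cut at the requested `minprop`) are
errors, not silent answers.

## Survival machinery

Kaplan–Meier medians are the first time the survivor estimate drops to
0.5 or below (`NA` when never reached); group comparisons use the
two-sided log-rank test. The multivariable Cox model takes ctDNA status
plus the clinical covariates as a single joint fit, reports per-term
hazard ratios with Wald 95% intervals, drops incomplete rows listwise
(with the dropped count surfaced), and flags non-convergence rather than
failing. Response-group contrasts use the two-sided Wilcoxon rank-sum test
with the normal approximation and tie correction; the primary contrast is
progressive disease against all other response groups pooled. The
objective response rate is (CR + PR)/n.

## Longitudinal monitoring

Trajectories join the per-sample markers, the panel-based status and the
clinical channels (tumor size on imaging, serum CEA/CA125/CA153) per
(patient, timepoint). Patients positive at every observed timepoint form
the "all-positive" group; a single-timepoint patient cannot show
persistence and is excluded with a warning. The marker–tumor-size matrix
pools all (patient, timepoint) observations and computes pairwise Spearman
correlations with pairwise-complete deletion; repeated measures per
patient are pooled without a clustering correction, mirroring the analysis
the pipeline replicates — correlations and p-values are therefore mildly
anti-conservative and should be read descriptively.

## The synthetic cohort generator

`simulate_cohort()` draws cohorts with the structure the analyses assume.
Defaults are fixed to the emulated study's printed shape: 70 patients, a
457-gene panel, 38 patients with a during-treatment sample and 31 of them
with a progression sample (139 plasma samples), 13 paired baseline tissue
profiles, and best-response marginals PD/SD/PR/CR = 12/31/23/4.

* **Planted panel.** Twelve (gene, type) pairs — eleven copy-number gains
  and one SNV — with hazard ratios 1.89–4.19 and prevalences of 7–33%
  (printed cohort frequencies where available, plausible values of at
  least 6% otherwise).
* **Carriage.** A latent per-patient tumor-burden propensity
  $u_i \sim N(0,1)$ drives carriage of the planted genes through a
  Gaussian-copula threshold model that preserves each marginal prevalence
  exactly. The loading 0.8 was chosen analytically so that about 46% of
  patients carry at least one planted alteration — the baseline
  ctDNA-positive rate the emulated cohort reports. Background passenger
  alterations are independent Bernoulli draws with printed frequencies
  for the recurrent genes (TP53 69%, PIK3CA 24%, HLA-C gains 50%, ...)
  and sparse random frequencies for fillers.
* **Survival.** PFS is exponential; a carrier's rate is the baseline
  hazard times the largest planted hazard ratio carried (a
  dominant-lesion model). Fully independent multiplicative effects were
  rejected during development: with twelve independent effects the
  product hazard gives panel-positive patients median survival under a
  month and a cohort median near 2 months, far from the cohort being
  emulated, whose panel genes co-occur within the same high-burden
  patients. The baseline rate is anchored at $\log 2 / 9.05$ per month —
  the printed panel-negative median PFS — which puts the simulated cohort
  marginal median in the 4–6 month range; censoring is independent
  exponential with a 24-month half-life. With a single planted gene the
  model reduces to exact proportional hazards at that gene's ratio, which
  is what the parameter-recovery tests use.
* **Coupling.** Per-mutation VAFs are Beta(1.5, 30) (mean ≈ 0.048) scaled
  mildly by $e^{0.35 u_i}$; best response is assigned by ranking a noisy
  log-burden (worse response at higher burden) with the marginals fixed;
  tumor size follows a monotone power link to burden with log-normal
  noise (sd 0.55, targeting a Spearman correlation near 0.3 with ctDNA
  fraction); serum markers are deliberately uncoupled log-normal
  channels, since the emulated study found no tumor-size correlation for
  them. On treatment, VAFs shrink by response-dependent factors (CR
  strongest) and copy numbers regress toward diploid, with calls dropping
  out below a 0.5% VAF detection floor or inside the neutral copy band;
  at progression both rebound. Tissue profiles share the plasma gene set
  except for Poisson(37/13) plasma-only and tissue-only genes per
  patient, reproducing a ≈ 98.75% expected concordance, with tissue VAFs
  running about threefold higher.

What the generator does **not** emulate: sequencing error and depth,
subclonal phylogenies, gene–gene interaction beyond the shared propensity,
informative censoring, and real covariate–outcome associations (clinical
covariates other than ctDNA status are independent noise). Tests passing
on this generator show the pipeline's statistical machinery is correct and
calibrated under the structure above; they do not certify performance on
real cohorts.

## Problem sizes and tolerances used by the test suite

The suite checks MATH against a brute-force oracle on 1,000 random VAF
vectors at 1e-9 relative tolerance; cut-point scans against an exhaustive
`survival::survdiff` scan on random instances up to n = 200; screen
calibration on 200 null cohorts (all hazard ratios 1, n = 70) with the
per-candidate selection rate required within 2.5% ± 1.5 percentage points,
and screen sensitivity/false-selection on 100 default cohorts; Cox
interval coverage of a planted hazard ratio 2.7 on 200 simulations at
n = 300 (≥ 93%); the Kaplan–Meier median of a 10,000-subject exponential
sample against its closed form (±0.2 months); and bit-identical pipeline
output TSVs across two same-seed runs at the default 139-sample scale.
These sizes keep the full suite to a few minutes on one CPU while leaving
the Monte-Carlo error well inside each tolerance.

## Known limitations

* The screen applies no multiplicity correction (by design, to match the
  replicated procedure).
* Cut-point p-values are not corrected for selection optimism; the scan
  reports the statistic only.
* Pooled longitudinal correlations ignore within-patient clustering.
* The ctDNA-fraction formula assumes a diploid background and one mutant
  copy; it is biased where the max-VAF locus sits in a copy-number
  altered region.
* The generator's clinical covariates are uninformative noise, so the
  multivariable model's covariate terms exercise machinery, not biology.
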