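---
title: "Methods: copy-number dynamics in serially biopsied tumors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: copy-number dynamics in serially biopsied tumors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serialcna)
```

# The setting

`serialcna` analyzes allele-specific copy-number profiles of tumors biopsied
three times during a neoadjuvant treatment course: at diagnosis (week 0),
after a first chemotherapy block (week 12), and at surgery (week 25). The
inputs are the *outputs* of purity/ploidy-aware copy-number callers in the
ASCAT/Battenberg mold: per-sample segment tables with tumor-adjusted total
and minor copy number, optional subclonal state mixtures, per-sample ploidy
and aberrant cell fraction (ACF, the tumor purity), a clinical table, an
expression matrix, and a gene annotation. The package does not re-estimate
purity or ploidy from raw array data and does not segment; those are the
callers' jobs.

Three analysis layers sit on top of this input contract:

1. **Instability and aberration scoring.** A segment is a gain when its
   total copy number exceeds ploidy + 0.6 (strictly), a loss below
   ploidy − 0.6; gains and amplifications are one event. The genomic
   instability index (GII) is the probe-weighted fraction of the genome
   deviating from ploidy by the same margin. Gene-level log-ratios adjusted
   for purity and ploidy are `gamma * log2(CN / ploidy)` with the
   array-noise factor `gamma = 0.55`.
2. **Response association.** Patients are grouped by the response ratio
   (tumor size at surgery over size at diagnosis): good responders below
   0.10, non-responders above 0.90, intermediate otherwise, with the
   boundary points assigned to the intermediate group because the extreme
   groups are defined by strict inequalities. Gene-level adjusted logR is
   tested between the extreme groups with a pooled-variance t-test after an
   expression-correlation filter (Pearson r ≥ 0.5 between logR and mRNA
   expression), followed by Benjamini-Hochberg correction.
3. **Clonal dynamics.** Per patient, a reference sample (week 0 if its
   profile is good, else week 12, else the patient is excluded) anchors a
   set of tracked aberrations; their carrier fractions are re-estimated at
   every time point and a genome scan tests whether increases outnumber
   decreases (or vice versa) across patients.

# The tracking model

All tracking arithmetic rests on one mixture identity. A bulk sample is a
mixture of normal cells (2 copies, 1 minor) and tumor cells at ACF
$\rho$; if a fraction $f$ of tumor cells carries an aberration with integer
total state $s$ on an otherwise diploid background, the observed bulk total
copy number of that segment is

$$b = 2(1 - \rho) + \rho\,[\,2 + f (s - 2)\,] = 2 + \rho f (s - 2).$$

Every estimator in the package is an inversion of this identity:

* **Implied ACF** (`implied_acf`): for a segment clonal in the reference
  ($f = 1$), $\rho = (b - 2)/(s - 2)$, clamped to $[0, 1]$.
* **Sample ACF** (`estimate_sample_acf`): good-quality samples keep their
  caller-fitted ACF. For others, the implied ACFs of the reference's clonal
  gains and losses are pooled and the *main peak* of their density is taken:
  a Gaussian kernel with Silverman's rule-of-thumb bandwidth, evaluated on
  the fixed grid 0.01–1.00 in steps of 0.01, returning the argmax. When the
  implied values are numerically a point mass the bandwidth degenerates and
  the median is returned directly, which also makes the noise-free case
  exact. At least 3 informative segments are required; otherwise the sample
  is dropped from tracking.
* **Carrier fraction** (`track_cna_fraction`): given $\rho_t$,
  $f = (b - 2) / (\rho_t (s - 2))$ for gains and losses; copy-neutral LOH is
  invisible on the total-copy axis and is solved on the minor allele
  instead, $b_{minor} = 1 - \rho_t f$. Fractions are clamped to $[0, 1]$,
  and $\rho_t = 0$ (tumor absent) leaves the fraction undefined.

**Which aberrations are trackable.** Only patients whose reference sample is
diploid (ploidy < 3) enter this layer — on non-diploid backgrounds the
"one aberrant state against a normal background" reading of the mixture is
ambiguous. Within a diploid reference, segments with exactly one aberrant
state are kept: clonal aberrant segments, and subclonal mixtures of one
aberrant and one normal state. Each is classified gain / loss / LOH
(total state 2 with minor allele 0) and clonal / subclonal.

**Symmetric estimation at the reference.** The carrier fraction entering an
increase/decrease comparison is estimated *by the same mixture inversion at
every time point, the reference included*. The subclonal mixture fraction
reported by the caller fixes the aberrant state and the clonal/subclonal
label (column `carrier_ref`), but is not compared directly against a noisy
follow-up estimate: doing so would make clonal aberrations (reference
fraction exactly 1, follow-up estimates clamped to at most 1) callable only
as decreases under noise, biasing the scan's null. With both sides
estimated, noise enters the comparison symmetrically.

**Change calls and the selection scan.** A follow-up fraction more than
`change_delta = 0.05` above the reference estimate is an increase, more
than 0.05 below a decrease, otherwise unchanged (and excluded from the
counts). The dead zone keeps symmetric estimation noise out of the counts;
no tie rule is needed. Counts are summed per genome bin and aberration
class across all patients' follow-up comparisons — each patient contributes
at most one count per bin, class and follow-up week, and conflicting calls
from overlapping aberrations cancel to unchanged. Under no selection,
increases and decreases are equally likely, so with $I$ increases and $D$
decreases the one-degree-of-freedom goodness-of-fit statistic

$$\chi^2 = (I - D)^2 / (I + D)$$

is tested against the upper chi-squared tail (no continuity correction; the
null is symmetric and calibration is verified by simulation). Gains, losses
and LOH are corrected as separate Benjamini-Hochberg families, mirroring
the per-class genome plots this analysis feeds. A bin is under positive
selection when increases dominate at q < 0.05, negative when decreases
dominate. As a worked point: 13 increases and 0 decreases give
$\chi^2 = 13$, p ≈ 3.11 × 10⁻⁴.

# The input format contract

The segment TSV stores, per the caller convention, *tumor-cell-adjusted*
total and minor copy numbers for samples whose purity/ploidy fit is good
(quality `good`, ACF known) — bulk values are reconstructed as
$b = 2(1-\rho) + \rho\,\mathrm{CN}$ when needed. For samples whose fit
failed (quality `poor` or `non_aberrant`, ACF unknown) adjustment is
impossible by definition, and the stored values are the raw bulk copy
numbers; these are exactly the samples whose ACF the density-peak estimator
recovers. Subclonal segments carry a second state (`state2_total`,
`state2_minor`) and the fraction of the first state (`frac_state1`); the
first state is recovered from the stored average, which is exact for clean
calls and can mis-round under heavy noise — the same failure mode as the
upstream caller.

Samples that come back *non-aberrant* (too little aberrant DNA to fit
purity) follow the manual protocol: a flat profile with a pathologist
estimate of 0% tumor cells is assigned ACF 0; a non-aberrant profile at
week 0 or 12 while other time points are aberrant is treated as unknown.

# The synthetic cohort generator

The generator (`simulate_cohort`) emulates the statistical structure the
analysis assumes, at desk scale, with ground truth for every latent
quantity. Defaults encode the study conditions:

* **Design:** three biopsies at weeks 0/12/25; two arms assigned 50/50;
  response mix 33:68:22 (GR:IR:NR) with response ratios drawn uniformly
  inside each group's range (GR 0–0.0976, IR 0.106–0.83, NR 0.903–1.6) and
  tumor sizes back-computed from the ratio (diagnosis diameter lognormal
  around 40 mm, at least 26 mm); pathological complete response mostly
  within GR (rate 0.67), occasionally IR (0.05).
* **Cellularity trajectories:** mean ACF 0.65 at diagnosis in all groups,
  declining to 0.30/0.00 (GR), 0.45/0.25 (IR), 0.55/0.50 (NR) at weeks
  12/25, with per-sample Gaussian spread 0.05. ACF below 0.05 presents as a
  flat non-aberrant profile with pathologist 0%.
* **Aberration landscape:** a miniature genome (22 chromosomes × 10 Mb,
  1 Mb bins, 100 probes/Mb) so full cohorts simulate in about a second;
  real coordinates can be passed instead. Clonal aberrations are Poisson
  (rate 10 per genome, scaled 1.4/1.0/0.6 for GR/IR/NR so instability
  associates with response, as observed clinically); 1–3 subclones carry
  1–2 aberrations each with starting carrier fractions uniform on
  (0.3, 0.7) evolving by bounded mean-zero Gaussian steps (s.d. 0.15)
  clamped to [0, 1] — the simplest mechanism consistent with
  increase/decrease dynamics, as no generative model is prescribed by the
  upstream method. 10% of patients are genome-doubled (ploidy ≈ 4),
  exercising the diploid-only exclusion.
* **Planted selection:** a selection locus adds, in each carrier patient, a
  dedicated subclonal gain at a fixed bin whose fraction moves by a
  configured ±delta per treatment interval (positive loci start at
  0.15–0.35 and rise; negative at 0.65–0.85 and fall). The null generator
  (`simulate_null_cohort`) is identical except every subclone — planted
  loci included — drifts by the symmetric mean-zero steps. Starting
  fractions symmetric about 0.5 plus symmetric steps make
  increase/decrease counts exchangeable under the null even with clamping
  (the construction is invariant under f → 1 − f).
* **Observation model:** observed bulk copy number is the mixture identity
  plus Gaussian noise (s.d. 0.05 by default on the total, half that on the
  minor allele); good-quality samples store the adjusted values derived
  from the noisy bulk, others store the bulk itself. Follow-up samples have
  a good fit with probability 0.7, week-0 samples fail with probability
  0.05 (pushing the reference to week 12), and follow-up biopsies are
  missing with probability 0.05.
* **Expression:** half the genes are linear in their gene-level adjusted
  logR (slope 2 expression units per logR unit, noise s.d. 0.3 — a slope
  chosen so that genes with appreciable copy-number spread exceed the 0.5
  correlation threshold in expectation); the rest are uncoupled. The 11
  PAM50 proliferation genes additionally track the sample's true aberrant
  genome fraction (slope 3), and tumor-free biopsies express baseline only.

What the generator does **not** emulate: raw probe intensities or BAF
tracks, segmentation error (breakpoints are exact), caller errors in the
subclonal mixture fractions, expression-array probe effects, copy-number
variants of germline origin, and any linkage between aberrations beyond
shared subclone membership. Passing tests therefore validate the
arithmetic, the estimators and the scan's error control under this
idealized observation model — not robustness to segmentation or
state-calling errors in real data.

# Numerical and design choices

* The GII reuses the ±0.6 aberration margin around (possibly non-integer)
  ploidy; probes are the weighting unit. No separate tolerance is defined
  anywhere else.
* Cross-sample comparability uses fixed 1 Mb bins with a
  segment-covers-bin-midpoint rule; per-patient breakpoints differ, so some
  grid is required, and the midpoint rule is deterministic for segments
  straddling a bin. Genes are likewise assigned by midpoint.
* Coordinates are 1-based inclusive everywhere internally; the BED-like
  annotation is converted on read/write. Chromosome labels are accepted
  with or without a `chr` prefix.
* A zero copy number is floored at 0.05 copies before the log transform so
  logR stays finite; floored values are flagged.
* "Student's t test" is the classic pooled-variance test to match the
  name; `welch = TRUE` switches both the differential test and the group
  comparison to Welch.
* The expression-correlation filter is computed on diagnosis (week 0)
  samples with good fits, since the differential question concerns
  untreated tumors; the time point is configurable. The filter itself
  provides the removal of germline CNVs (little expression effect); no
  separate blacklist exists.
* Significant genes are merged into regions when they fall in the same or
  adjacent bins, giving the locus-level count.
* The selection scan pools counts across treatment arms by default (the
  worked 13-increase configuration is a pooled count); `arm =` restricts
  to one arm.

# Problem sizes and verification

The test suite and the acceptance script validate, among others:

* exact (≤ 10⁻⁶, observed ≈ 10⁻¹⁵) recovery of ACFs and carrier fractions
  on noise-free 20-patient cohorts;
* formula-level agreement (10⁻¹⁰) of every statistic with independent
  textbook evaluations on ≤ 30-element inputs;
* calibration of the scan on 200 null cohorts of 40 patients over 100 bins
  (mean q < 0.05 rate at or below 0.05; p < 0.05 mass not inflated);
* ≥ 90% detection, with correct direction, of loci planted at ±0.3 carrier
  fraction per interval in 85% of 40 patients, over 50 replicates;
* > 90% agreement between the filter's kept set and ground-truth coupling.

These sizes were chosen so the whole suite runs on a laptop in minutes
while keeping Monte-Carlo intervals tight enough to be meaningful.

# Known limitations

* Declining purity makes follow-up fraction estimates noisier than
  reference ones; clonal segments therefore retain a mild excess of
  decrease calls. At the tested sizes the scan stays calibrated at the
  q < 0.05 level; genome-scale cohorts with many counts per segment could
  surface the excess, and a purity-stratified dead zone would be the
  natural refinement.
* Cohort-level associations (GII–proliferation correlation, GII ANOVA)
  emerge from the generator's group-dependent aberration rates and are
  noisy at desk scale; they are reported, not asserted against fixed
  values.
* The binned reconstruction of frequency profiles approximates a
  segment-grid analysis; sub-bin aberrations shorter than half a bin can
  be missed by the midpoint rule.
* Whether "unchanged" calls existed in the original protocol is unknown;
  the dead zone is this package's choice, and its null behavior is
  simulation-verified.
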