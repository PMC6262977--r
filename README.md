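# serialcna

Copy-number dynamics in serially biopsied tumors.

`serialcna` is for analysts working with allele-specific copy-number
profiles of tumors biopsied repeatedly during neoadjuvant treatment — at
diagnosis (week 0), mid-course (week 12) and surgery (week 25). Starting
from the outputs of purity/ploidy-aware callers (ASCAT/Battenberg-style
segment tables with tumor-adjusted copy numbers, per-sample purity and
ploidy), it answers three questions:

1. **How unstable is each genome, and does instability predict response?**
   Segments are scored +1/−1 when total copy number exceeds
   `ploidy + 0.6` / falls below `ploidy − 0.6` (strict inequalities; gains
   and amplifications are one event). The genomic instability index is the
   probe-weighted aberrant fraction of the genome,
   GII = Σ probes(aberrant) / Σ probes, compared between response groups by
   t-test / one-way ANOVA and correlated with an 11-gene proliferation
   score.
2. **Which copy-number changes distinguish good responders from
   non-responders?** Gene-level adjusted log-ratios,
   logR = γ·log2(CN / ploidy) with γ = 0.55, are filtered on correlation
   with mRNA expression (Pearson r ≥ 0.5), tested between the extreme
   response groups (pooled-variance t-test) and corrected by
   Benjamini-Hochberg. Response groups come from the shrinkage ratio
   RR = size(surgery)/size(diagnosis): GR below 0.10, NR above 0.90.
3. **Which subclones expand or shrink under treatment?** For each patient a
   diploid reference sample anchors tracked aberrations (gain/loss/LOH,
   clonal/subclonal). The fraction *f* of tumor cells carrying an
   aberration with state *s* is recovered at every time point from the bulk
   mixture identity `bulk = 2 + ρ·f·(s − 2)` (minor-allele version for
   copy-neutral LOH), with the sample purity ρ taken from the caller or
   re-estimated as the main density peak of per-segment implied purities.
   Increases and decreases relative to diagnosis are summed per genome bin
   across patients and tested with the goodness-of-fit statistic
   `χ² = (I − D)²/(I + D)` (df 1) against a 50/50 null, with BH correction
   per aberration class.

A synthetic-cohort generator (`simulate_cohort`, `simulate_null_cohort`)
emulates all of the inputs — including subclones with drifting carrier
fractions, planted selection loci, response-dependent cellularity
trajectories and expression coupled to copy number — and returns ground
truth, so every stage of the pipeline is testable end to end.

## Worked example

```r
library(serialcna)

loci <- data.frame(bin = c(43, 77), direction = c("positive", "negative"),
                   delta = 0.3, carrier_prob = 0.85)
cohort <- simulate_cohort(sim_config(seed = 42, n_patients = 30,
                                     genome = default_genome(10),
                                     selection_loci = loci))
cohort
#> Synthetic cohort: 30 patients, 88 samples, 3099 segments, 200 genes

res <- run_pipeline(cohort, "demo_run", plots = FALSE)
res$tracking
#> CNA tracking: 23 patients, 407 tracked aberrations, 7 excluded

subset(res$selection, direction != "none")
#>  bin chrom start   end class n_increase n_decrease chi2        p        q direction
#>   43     5 2e+06 3e+06  gain         24          1 21.2 4.22e-06 0.000152  positive
#>   77     8 6e+06 7e+06  gain          1         26 23.1 1.50e-06 0.000108  negative
```

The two planted loci — a subclonal gain expanding by +0.3 carrier fraction
per treatment interval at bin 43 and one contracting at bin 77 — are the
only bins called, with the correct directions: at bin 43, 24 patient
comparisons showed the carrier fraction rising by more than the 0.05 dead
zone against 1 falling, giving χ² = 21.2 and q ≈ 1.5 × 10⁻⁴. Seven of the
30 patients were excluded from tracking (non-diploid reference, no usable
reference profile, or no follow-up biopsy), and the run's `manifest.json`
itemizes the reasons. The same run writes per-sample GII, per-bin gain/loss
frequencies, the expression-filtered differential table and per-aberration
carrier fractions; `report("demo_run")` prints the summaries.

As a single worked statistic: 13 carrier-fraction increases against 0
decreases give

```r
selection_chisq(13, 0)
#>   chi2           p
#> 1   13 0.000311491
```

## Command-line use

A thin wrapper over the same functions lives at `inst/scripts/serialcna`:

```sh
Rscript inst/scripts/serialcna simulate --seed 1 --patients 20 --out cohort
Rscript inst/scripts/serialcna run --cohort cohort --out run
Rscript inst/scripts/serialcna report --run run
```

See `vignettes/serialcna-methods.Rmd` for the model, estimator and
generator details, the numerical choices, and known limitations.
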