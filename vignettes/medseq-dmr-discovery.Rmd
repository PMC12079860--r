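---
title: "From tissue DMR discovery to blood-based marker evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From tissue DMR discovery to blood-based marker evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis this package implements

MeD-seq profiles genome-wide DNA methylation by digesting genomic DNA with
the LpnPI restriction enzyme, which cuts only at methylated CpG-containing
recognition sites and releases 32-bp fragments centred on the site. After
sequencing, the number of reads attributable to each LpnPI site is a direct
readout of that site's methylation level. `medseqr` implements the complete
downstream analysis:

1. **Read filtering and counting** (`filter_reads()`, `assign_reads()`): a
   read is genuine LpnPI product only if a recognition site lies 13--17 bp
   from one of its ends; qualifying reads increment the matched site's
   counter. Sample QC (`qc_sample()`) requires more than 20 million total
   reads and more than 20% CpG-containing reads at production scale (both
   thresholds configurable; toy-scale runs use proportionally smaller
   values).
2. **Region scores** (`define_regions()`, `score_regions()`): per-site
   counts are summed over transcription start sites (1 kb either side of
   the TSS), gene bodies (1 kb past the TSS to the transcription end site,
   strand-aware) and CpG islands, then normalised to reads per million
   (RPM).
3. **DMR calling** (`per_site_test()`, `call_dmrs()`): each site is tested
   with a 2x2 chi-square on pooled group counts versus library totals,
   Bonferroni-corrected over the testable sites; runs of neighbouring
   significant sites with a common direction are binned into candidate
   DMRs and filtered on site count, span and fold change.
4. **Methylation scores** (`fit_dmr_thresholds()`, `score_samples()`): each
   DMR gets a Youden-optimal RPM threshold on training labels; a sample's
   DNA methylation score is the number of DMRs it is positive for.
   `compare_scores()` contrasts score distributions between groups.
5. **qMSP panel** (`qmsp_levels()`, `qmsp_thresholds()`,
   `call_positivity()`): marker methylation relative to the ACTB reference
   is `2^-dCt`; a sample is positive when its level strictly exceeds the
   control group's 95th percentile.
6. **Diagnostics** (`asap_score()`, `fit_combined()`,
   `evaluate_classifier()`, `compare_auc()`): the ASAP clinical risk score,
   logistic models combining it with methylation markers, and evaluation by
   AUC and sensitivity at a fixed specificity, with training-fitted models
   and thresholds frozen before touching a validation cohort.

A single driver, `run_demo()`, chains the phases on synthetic cohorts:

```{r demo}
library(medseqr)
demo <- run_demo(seed = 1)
demo$dilution            # signature AUC across the tumor-fraction ladder
demo$evaluation$results  # combined-model table, train and validation
plot_dilution(demo$dilution)
```

## Modelling decisions and their rationale

**Chi-square table.** The site test needs counts, not rates. We pool raw
counts within each group and form the 2x2 table *site reads / all other
reads* by *case / control*: the library-total complement row is exactly the
coverage normalisation a contingency test admits, while RPM values are used
where a rate is the right quantity (direction and fold change). The
statistic is the standard uncorrected chi-square; `stats::chisq.test()`
serves as an independent oracle in the test suite.

**Run binning instead of an explicit window.** Significant sites are binned
whenever consecutive significant sites lie within `max_gap` (default
1000 bp) and share a direction; a direction flip or a larger gap starts a
new DMR. This is one consistent reading of sequential "sliding-window"
detection over site-resolution data; the geometry is controlled entirely by
`max_gap`. Default retention thresholds -- at least 4 sites, at least
100 bp, fold change at least 2 (applied symmetrically to hypomethylated
DMRs) -- are deliberate, documented defaults; every one is a visible
argument of `call_dmrs()`.

**Bonferroni denominator.** The number of testable sites (pooled coverage
above zero) after sex-chromosome removal, genome-wide rather than per
region class. Sites on chrX/chrY are removed before testing to avoid
sex-composition artefacts.

**Youden thresholds.** "Optimal ROC threshold" is taken as the Youden-J
maximiser (`criterion = "closest01"` is available as an alternative).
Candidate cut points are midpoints between consecutive sorted unique
scores, plus sentinels outside the observed range; positivity is strict
(`score > threshold` for hypermethylated DMRs, `<` for hypomethylated
ones), and ties in J resolve toward the larger threshold. With perfectly
separated training groups this lands in the middle of the separating gap.

**Score comparison.** Group comparison of cumulative methylation scores
uses a two-sided Mann--Whitney test per signature with Benjamini--Hochberg
correction and a q < 0.01 flag, rather than a negative-binomial
count-model fit: the inputs are small integer score vectors without the
mean--dispersion structure such a model estimates, so a rank test is the
appropriate tool. A negative-binomial Wald alternative is out of scope by
design.

**Percentile interpolation.** The 95th percentile of control levels uses
linear interpolation between order statistics (type-7 quantile, the R
default): `h = (n-1)q + 1`. The interpolation rule can shift borderline
positivity calls; it is fixed and documented here, and the test suite pins
it against an independent order-statistic computation.

**Undetermined Ct.** A target that never amplifies has no Ct; it maps to
relative methylation 0 (no methylated template) and is flagged, rather
than dropped, matching qMSP semantics.

**ASAP score.** The printed formula is evaluated exactly, with base-10
logarithms and sex coded 1 = male. Non-positive biomarker inputs are raised
to the assay detection floor before the logarithm; full detection-limit
clipping (AFP to [0.5, 2000] ng/mL, PIVKA-II to [5, 75000] mAU/mL) is a
separate, explicit cohort step (`clip_to_detection_limits()`), so that the
formula itself can also be applied to already-clipped laboratory values
without double transformation.

**Backward elimination.** The removal criterion is the largest Wald p-value
above 0.05, iterated to convergence; the likelihood-ratio variant some
statistical packages default to is a noted alternative. AIC is reported as
`2k - 2 log L` with the intercept counted in `k`; this convention is always
positive for binomial likelihoods, and values from software using a
different sign or scaling convention are not directly comparable to it.
Perfect separation is flagged on the fit object instead of erroring.

**Fixed-specificity operating points.** The threshold is the smallest score
cut whose training-control specificity is at least the target (ties resolve
toward higher specificity). On a validation cohort the training threshold
is carried over unchanged, so achieved specificity may drift -- both
behaviours are asserted in the test suite. Whether a validation cohort
should instead be re-thresholded at its own specificity is genuinely
ambiguous; both modes are available via the `threshold` argument of
`evaluate_classifier()`.

## What the synthetic generator emulates -- and what it does not

`generate_genome()` builds a toy chromosome with Poisson-placed genes, CpG
islands and LpnPI sites (island site density boosted five-fold); it stands
in for a reference genome plus UCSC-style annotation at desk scale. Counts
from `simulate_site_counts()` are negative binomial (Poisson as dispersion
goes to 0) around `mean_depth` x a gamma site weight shared by both groups,
so unplanted sites are exactly null; planted DMRs multiply (or divide) the
case-group mean by the planted fold change. The per-site depth distribution
of real MeD-seq libraries is not published, so the defaults
(`mean_depth = 50`, `dispersion = 0.1`, gamma weight CV ~ 0.45) are
placeholders with realistic overdispersion, not estimates.

`simulate_cfdna_counts()` models plasma as a convex mixture: expected site
count = `tumor_fraction` x tumor profile + `(1 - tumor_fraction)` x
background profile. The default `tumor_fraction` of 0.02 reflects the 1--3%
hepatocyte contribution to circulating cfDNA. The demo evaluates combined
classifiers at fraction 0.01: tumor-derived DNA is a subset of
hepatocyte-derived DNA, so early-stage disease sits at or below the bottom
of that range, and at 0.01 the expected separation between the
marker-only, ASAP-only and combined models is large relative to
Monte-Carlo noise at the demo's cohort sizes.

What passing tests on these cohorts show is that the *pipeline arithmetic
and its calibration* behave as specified -- not that real plasma data would
yield the same AUCs. The generator omits, among other things: fragment-size
and GC biases, bisulfite-conversion chemistry, read quality, hepatocyte- vs
leukocyte-of-origin composition shifts, batch effects, and biological
correlation between neighbouring DMRs. Clinical covariates are independent
lognormals per group, so the ASAP score's simulated performance is purely a
consequence of the chosen group medians.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at deliberately small
scale, chosen so the whole suite completes in a few minutes: a 1-Mb toy
chromosome carries roughly 10,000 LpnPI sites; tissue cohorts use 10--20
samples per group at depth 50; cfDNA cohorts use 250 samples per group so
that an AUC is estimated with a standard error near 0.02; the family-wise
error calibration uses 100 replicate null simulations (upper acceptance
bound 0.05 plus two binomial standard errors); recovery uses 90 planted
DMRs across 15 replicates. The dilution ladder {1, 0.25, 0.05, 0} is
asserted to be non-increasing within 0.05 per step -- about twice the
standard error of an AUC difference at those cohort sizes -- because the
expected AUCs at fractions 0.05 and 0 differ by less than sampling noise
(both are near 0.5 once tissue-trained thresholds stop being exceeded).

Degenerate inputs are handled explicitly rather than by accident: zero
pooled coverage gives p = 1 and no direction; constant training scores drop
the DMR with a warning; all-tied Mann--Whitney data give p = 1; infinite
fold changes are capped at 1e6 and flagged; empty read lists, empty DMR
sets and empty cohorts propagate as empty results, not errors, except where
an empty validation cohort is a usage error.

## Known limitations

* Alignment is out of scope: reads enter as mapped positions (or per-site
  count tables via `read_site_counts()`); bowtie2/hg38 and demultiplexing
  belong upstream.
* The caller pools counts within groups, so per-sample dispersion does not
  enter the site test; with strong overdispersion the per-site test is
  anticonservative, and family-wise control in practice rests on the run,
  size and fold filters (the calibration test measures exactly this
  combined behaviour).
* One train/validation split; no cross-validation machinery.
* GALAD and other composite scores beyond ASAP are not implemented.
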