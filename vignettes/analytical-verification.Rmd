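---
title: "Analytical verification of a continuous-score classifier: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analytical verification: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assayval)
```

## The problem

A molecular diagnostic that reports a continuous score and a binary call
(positive/suspicious vs negative/benign) must demonstrate, before clinical
use, that its results survive the perturbations of real laboratory work:
varying RNA input, dilution of the signal-bearing material by adjacent
normal or benign tissue, contamination by blood or residual genomic DNA,
and replication across operators, instruments, reagent lots, runs and
laboratories. `assayval` implements the statistics of such a verification
program end to end. Because production classifiers and patient specimens
are proprietary, the package pairs every analysis with a synthetic-data
generator and a transparent linear surrogate classifier, so the whole
pipeline is executable, testable, and auditable.

## Models

### Score tables

Replicate-level scores are modeled additively. For a technical-factor
study (input mass, gDNA level, laboratory), sample $i$, condition $j$,
replicate $k$:

$$S_{ijk} = \mu_i + b_j + \varepsilon_{ijk},$$

with $\mu_i$ a sample effect (random in the mixed-model view), $b_j$ a
fixed experimental effect, $\varepsilon_{ijk}$ residual noise.
`fit_effect_model()` tests $b_j$ by the balanced randomized-complete-block
F statistic $MS(\text{condition})/MS(\text{residual})$ after removing
sample means. For the balanced designs these studies use, this F-test is
identical to the REML mixed-model test of the fixed effect, so no
iterative fitting is needed; unbalanced tables are rejected with guidance
rather than silently reweighted. This equivalence is a known limitation:
for unbalanced data the package deliberately does not attempt a general
REML engine.

For reproducibility studies, run $j$ replaces the condition and gains an
interaction:

$$S_{ijk} = \mu_i + r_j + (\mu_i{:}r_j) + \varepsilon_{ijk},$$

with $r_j$ and the sample-by-run interaction random.
`estimate_variance_components()` solves the expected-mean-square equations
of the (unrestricted) mixed model on a balanced crossed design:
$\hat\sigma^2_\varepsilon = MS_E$,
$\hat\sigma^2_{int} = (MS_{int}-MS_E)/n$,
$\hat\sigma^2_{run} = (MS_{run}-MS_{int})/(a\,n)$ for $a$ samples and $n$
replicates per cell. Negative solutions are truncated to zero (the
standard method-of-moments convention). Derived summaries:

* pooled **intra-run SD** $=\sqrt{\hat\sigma^2_\varepsilon}$ — technical
  replication noise; identical to the df-weighted pooled SD over
  sample-by-run cells (`pooled_sd()`), an identity the tests check.
* pooled **inter-run SD**
  $=\sqrt{\hat\sigma^2_{run}+\hat\sigma^2_{int}+\hat\sigma^2_\varepsilon}$
  — the total experimental variability other than sample-specific effects.
  Folding the interaction into this composite is an interpretation (the
  usual verbal gloss does not pin it down); it is recorded in study output
  so reports are self-describing.

On balanced data with all components interior, these estimators coincide
with REML; the test suite verifies this against `lme4` on small instances.

Confidence intervals for any reproducibility SD come from a **block
bootstrap** (`bootstrap_sd_ci()`): whole samples are resampled with
replacement, keeping each sample's complete replicate structure, because
replicates within a sample are dependent; percentile 2.5/97.5 limits are
reported, with `B = 2000` by default. A resample on which the statistic is
undefined is redrawn and counted. Coverage for the intra-run SD at the
15×3×3 design is checked empirically in the test suite against the
0.90–0.99 band.

Inter-laboratory comparisons (`interlab_analysis()`) take a paired two-lab
design, report call concordance and Pearson $R^2$, and define the
inter-lab pooled SD as the SD of the two lab scores of each sample pooled
across samples — per pair this equals $|d|/\sqrt2$ for difference $d$, the
$\sqrt2$ relation being documented and tested. The fixed lab effect is
tested through the first model with laboratory as the condition.

The **inter-class (biological) SD** (`inter_class_sd()`) is defined as the
SD of per-sample mean scores pooled over both classes. The quantity is
often reported without a formula; this definition — replicates averaged
first, classes pooled — is the package's documented choice and is recorded
with study output.

### Counts, normalization, and the surrogate classifier

`gen_count_matrix()` draws negative-binomial counts with log-normal
per-gene baselines, a common dispersion, log-normal library-size factors
of a chosen coefficient of variation, and a subset of informative genes
with a class-dependent log2 fold change — the simplest generative model
consistent with bulk RNA-seq counts downstream of alignment and counting.
It does not emulate GC/length bias, correlated gene modules, batch
effects, or on-instrument artifacts; passing tests therefore demonstrate
the statistical machinery, not performance on real sequencing data.

`size_factors()` re-implements the median-of-ratios procedure: reference
genes are those with strictly positive counts in every sample (any zero
excludes a gene, so the geometric mean is defined); each sample's factor
is the median ratio of its counts to the per-gene geometric means. The
procedure accepts real-valued counts because in-silico mixtures are not
integers. Scaling one sample's depth by $c$ moves its factor relative to
the others by exactly $c$; absolute factors shift by the common
$c^{1/n}$ the geometric-mean reference absorbs. The classifier-facing
transform is $\log_2(\text{count}/\text{factor}+1)$ — a conventional
choice, since the real classifier's internal transform is not public.

`train_classifier()` is a ridge-shrunk class-centroid discriminant,
$w = (\bar c_{pos}-\bar c_{neg})/(1+\lambda)$, with the threshold at the
midpoint of the class mean scores. It was chosen *because* it is linear:
the score of a convex mixture of profiles is the same convex combination
of scores, so titration threshold crossings have closed forms that serve
as analytic oracles in the tests. Calls are positive strictly above the
threshold; a knife-edge score is called negative, the conservative rule
for a rule-out test. The surrogate is emphatically not a re-implementation
of any production ensemble classifier.

### Mixing and limits of detection

`mix_counts()` computes the per-gene convex combination
$p\,C_1 + (1-p)\,C_2$, real-valued throughout. Specimens are mixed by RNA
mass, while raw counts confound composition with sequencing depth, so by
default parents are first rescaled to their common mean total — that makes
$p$ a mass fraction. The endpoints are exempt: $p=1$ returns the positive
parent and $p=0$ the negative parent exactly, since a pure specimen is
itself under any depth convention; rescaling only defines the
interpolation path at interior fractions.

`in_silico_titration()` walks the grid $p = 0, 0.01, \dots, 1$ (101
points; other steps that divide 1 evenly are accepted, e.g. 0.05 for
fusion-style designs), recomputes size factors over the whole mixture
series plus the two parents — normalization is local to the series, not
inherited from a cohort, and the choice is recorded in the result — then
scores and calls each mixture. The LOD is the smallest fraction called
positive at itself *and every larger grid fraction*; the contiguity
requirement guards against non-monotone call sequences that a pure
threshold-crossing definition would mishandle. A pure-negative endpoint
that scores positive invalidates the pair (negative-control failure)
unless the check is explicitly disabled.

`in_vitro_lod()` applies the same contiguity logic to a coarse discrete
dilution ladder (e.g. 0/40/60/80/100% diluent), treating the 100% point as
a pure-negative control rather than an LOD point, and reporting the LOD as
minimum percent positive content, $100 - \max$ tolerated dilution.

### Interference

`make_contaminated()` is the mixing operation with the interferent as the
$p$-weighted component. `gen_interference_profile()` emulates the two
interferents differently: blood concentrates 90% of its reads in a small
marker-gene subset (hemoglobin-like dominance), while gDNA contributes a
near-uniform low background across genes, since genomic reads are not
shaped by transcription — its effect on scores is depth dilution of the
transcriptome signal. `fit_sigmoid()` fits a four-parameter logistic by
least squares (self-starting fit first, Levenberg–Marquardt fallback,
degenerate constant fit with a flag when the data are flat or the
optimizer fails); 4PL was chosen over an unspecified "sigmoid" because its
four parameters are identifiable from a five-point titration. The
threshold-crossing fraction is solved analytically from the fitted curve
when the threshold lies strictly between the asymptotes.
`max_tolerated_level()` uses the same contiguity rule as the LOD ladder;
for an expected-positive specimen the 100% level (pure interferent) is not
eligible, while expected-negative specimens may tolerate all levels.

### Noise-injection acceptance specification

`simulate_noise_grid()` implements the three-step simulation: for each
noise SD $\sigma$ on the grid (default 0.36 to 2.10 in steps of 0.02),
draw i.i.d. $N(0,\sigma^2)$ noise, add it to every original score,
recompute calls and metrics, repeat 1,000 times, and take per-$\sigma$
medians. Noise is added to scores only — post-classifier — never to
counts. NPV needs a prevalence: the supplied value, or by default the
sample composition. The RNG is re-seeded deterministically per $\sigma$,
so any sub-grid reproduces the full grid's values exactly.

`determine_sd_spec()` returns the largest grid $\sigma$ at which every
required metric's median meets its minimum (defaults: sensitivity ≥ 0.90
and NPV ≥ 0.90). At finite replicate counts the median curves can be
non-monotone near a requirement boundary; the default takes the largest
qualifying $\sigma$ — exactly what "maximum tolerated variability" says —
and a `monotone = TRUE` variant stops at the first failure from the low
end for users who prefer the stricter reading. The machinery is verified
against a closed form: for point-mass classes at $\pm m$ and threshold 0,
median sensitivity tracks $\Phi(m/\sigma)$, so the specification is the
largest grid $\sigma$ with $\Phi(m/\sigma)$ above the requirement.

## Generator defaults and what the checks mean

The synthetic generators are the study conditions, not tuning knobs. The
recovery checks in `scripts/acceptance.R` and the test suite use published
reproducibility summaries as ground truth: intra-run SD 0.069 and
inter-run SD 0.274 at the 15-sample × 3-run × 3-replicate design
(generated as 8 samples per class with one sample dropped to reach 15),
inter-laboratory SD 0.130 with 40 paired samples, and inter-class SD 1.452
with 191 samples on a score scale 8 units wide. Two parameters those
summaries do not identify were fixed once, on symmetry grounds:

* the inter-run variance in excess of the residual is split **equally**
  between the run effect and the sample-by-run interaction
  (`reproducibility_truth()`);
* inter-laboratory noise is placed **symmetrically** on both labs at the
  full published SD, so the per-pair pooled SD estimates that value
  directly (placing all noise on one lab would instead target the value
  divided by $\sqrt2$).

Sample spreads (class separation 4, within-class SD near 1–1.2 on the
8-unit scale) mirror a validation cohort chosen to span the score range.
Monte-Carlo sizes — 200 seeds for recovery medians, 1,000 replicates per
noise setting, 1,000 null simulations for F-test calibration, 500
simulations for bootstrap coverage, 100 random pairs for the mixing
oracle — are the package's chosen problem sizes for desk-scale
verification and complete in a few minutes in total.

What passing means: the estimators recover the truths they were derived
under, the F-test is calibrated under Gaussian exchangeable noise, the
mixing and noise machinery match their closed forms. What it does not
mean: performance claims about any real classifier or real specimens —
those require the proprietary score sets this package deliberately
replaces with declared surrogates.

## Degenerate inputs and numerical conventions

* Metrics with zero denominators are `NA`, never silently 0.
* Variance components that a design cannot estimate (single run, single
  replicate) are `NA`, never 0; negative method-of-moments solutions are
  truncated to 0.
* A residual mean square at numerical zero (relative tolerance
  $10^{-12}$) leaves the F-test p-value undefined rather than reporting
  $p = 0$.
* Scores exactly at the decision threshold are negative calls.
* The 4PL fit reports `degenerate = TRUE` instead of failing on flat or
  unfittable data; a fitted crossing is only reported inside $[0, 1]$.
* All stochastic operations take explicit integer seeds and restore the
  caller's RNG state; `run_study()` output is byte-identical under a
  repeated configuration.

## Known limitations

* The surrogate classifier is linear; nonlinear ensembles can have
  LOD/interference behavior the linear analysis does not exhibit.
* Variance components and effect tests require balanced designs;
  unbalanced real-world tables (e.g. after QC failures) must be completed
  or reduced before analysis. The generator's `drop_qc_failure` flag
  exists precisely to exercise that failure mode.
* The negative-binomial generator omits several features of real RNA-seq
  (correlated genes, batch structure, coverage bias); conclusions about
  robustness transfer to real data only through the real validation
  studies this package's machinery is meant to analyze.
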