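---
title: "Common deletion regions, duplex qPCR copy-number calling, and the statistics behind the calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Common deletion regions, duplex qPCR copy-number calling, and the statistics behind the calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdrlight)
```

## The problem

Tumor-suppressor genes are commonly inactivated by somatic copy-number
deletion (SCND), but every tumor's deletion fragment has different
breakpoints, so no single pair of primers can straddle them. What the
fragments share is a *common deletion region* (CDR): a sub-interval of
the locus contained in nearly all of them. Once a CDR is known — for
*CDKN2A* the 5.1 kb interval chr9:21,970,277–21,975,386 (hg19), from
the *P16INK4A* promoter to intron-2 — a short qPCR amplicon inside it
is deleted whenever the fragment is present, and relative
quantification against a reference gene measures the deletion dosage.

`cdrlight` implements the three stages: CDR discovery from interval
cohorts, copy-number quantification from duplex qPCR Ct data, and the
contingency-table statistics relating deletion calls to
clinicopathological covariates.

## CDR discovery

Coordinates are 1-based and inclusive throughout, matching how genomic
positions are printed; BED input (0-based half-open) is converted on
read (`start + 1`), and the two accepted file dialects must be named
explicitly — auto-detection is refused because a silent off-by-one in
deletion breakpoints is exactly the error class this layer exists to
prevent.

`coverage_profile()` is a sweep line over fragment starts and
`end + 1` positions, yielding the exact step function
$d(x) = \#\{i : s_i \le x \le e_i\}$. `find_cdr()` takes the
maximal-depth run (adjacent equal-depth segments merged) as the CDR
candidate. Two decisions here were genuinely open:

* **Support is counted by containment, not depth.** Within a
  constant-depth plateau the identity of the covering fragments can
  change, so the number of fragments containing the whole region can
  be below the plateau depth. Containment is what the assay needs — an
  amplicon is informative only for fragments that delete all of it —
  so `support_count` counts full containment and can disagree with
  `max_depth` on purpose.
* **The CDR existence rule.** Published cohorts report loci where "no
  CDR" is observable, without stating the criterion. We call a region
  a CDR when its support fraction is at least `min_fraction` (default
  0.8) *and* its length is at least `min_length` (default 1 kb). The
  defaults accept the reported CDR-bearing loci (support ≈ 0.9) while
  rejecting flat, low-support coverage; both knobs are arguments.
* **Ties** between disjoint maximal-depth runs go to the longest run,
  then the smaller start — a deterministic choice; all runs are kept
  in `alternates`.

Amplicon scoring (`amplicon_coverage()`) is containment of the whole
amplicon in a fragment, never mere overlap, and is counted
per-fragment (a sample with two fragments contributes twice), matching
how containment fractions such as 94/110 are tallied over fragments.

## The qPCR model

The duplex assay amplifies a target amplicon (inside the CDR) and a
reference-gene amplicon (GAPDH) in the same well, in triplicate. The
chain is:

1. **Replicate aggregation** — arithmetic mean and sample SD of the
   amplified wells; `NA` (no amplification) wells are excluded but
   counted. Fewer than two usable replicates is an error.
2. **Informativeness gate** — a sample is eligible only when its mean
   reference Ct is ≤ 34 cycles (inclusive at the boundary); beyond
   that the input DNA is too degraded or scarce to quantify.
3. **Relative copy number** — per-replicate
   $\Delta Ct = Ct_\text{target} - Ct_\text{reference}$ (wells paired
   by replicate index; against the mean reference Ct when the counts
   differ), then $RCN = E^{-(\Delta Ct - \Delta Ct_\text{cal})}$ with
   the paired normal tissue (or the 100% two-copy control) as
   calibrator. The efficiency is fixed at $E = 2$ — the titration
   module exists to verify that both amplicons amplify at
   indistinguishable, near-perfect efficiency, which is the regime in
   which the uncorrected comparative-Ct formula is valid; an
   `efficiency` argument overrides it.
4. **Calling** — a two-sided Student's (pooled-variance) t-test of the
   sample's replicates against the paired normal's; deletion when
   significant with a lower copy number, amplification when higher,
   at per-sample $\alpha = 0.05$ with no multiple-testing correction
   across samples (each tumor/normal pair is its own experiment and is
   reported marginally).

Three statistical choices deserve their rationale:

* **Test space.** The test defaults to the replicate $\Delta Ct$
  values rather than the exponentiated copy numbers. The noise model
  is additive Gaussian on the cycle scale, so on $\Delta Ct$ the
  t-test's assumptions hold exactly; the $2^{-x}$ transform skews the
  copy-number replicates, and at triplicate sample sizes that costs
  real size (empirical type-I error ≈ 0.03 at nominal 0.05 in
  simulation). `test_space = "rcn"` switches to copy-number space for
  users who prefer testing the reported quantity.
* **Pooled, not Welch.** Both sides are the same design (equal
  replicate counts from the same instrument), and at $n = 3$ per side
  the Welch approximation is markedly conservative (size ≈ 0.034
  versus 0.0498 for the pooled test in 50,000-replicate simulation).
* **Degenerate variance.** Noise-free simulated replicates make the t
  statistic undefined; the call then reports p = 0 when the means
  differ and p = 1 when equal, with a warning. This keeps the
  noise-free identities (below) well-defined. A tumor whose target
  fails every replicate while its reference is informative is a
  complete dropout: called deletion with p recorded as 0 and a
  `dropout` flag.

**Detection limit.** Each nonzero spike-in fraction is compared with
the 0% control; the detection limit is the smallest significant
fraction *such that every larger fraction is also significant*. The
monotone rule is our addition: the bare "lowest significant dilution"
definition is unstable under an isolated false positive at a low
fraction, and monotonicity is what a dose-response must satisfy
anyway.

## Association statistics

2×2 tables are laid out covariate-row-first (the layout association
tables are printed in): `a` = covariate-positive call-positive, `b` =
covariate-positive call-negative, `c`/`d` the covariate-negative row.
The odds ratio is the cross-product $(ad)/(bc)$ — invariant to
transposing the layout — with Wald CIs
$\exp(\ln OR \pm 1.96\sqrt{1/a + 1/b + 1/c + 1/d})$, a zero-cell flag,
and the optional Haldane–Anscombe 0.5 correction. Fisher's two-sided p
uses the point-probability rule (sum of hypergeometric probabilities
not exceeding the observed table's); the doubling rule is behind a
flag. The Cochran–Armitage trend statistic uses integer scores and the
pooled-proportion variance, two-sided from the normal approximation
without continuity correction. Report rounding is half-up: odds ratios
to 2 decimals, percentages to 1.

On the deterministic 139-sample preset (below), the distant-metastasis
odds ratios are 4.09 (single CDR assay), 2.60 (positive by either
assay) and 2.91 (positive by both), and the stage trend on the single
assay gives z ≈ 2.34 (p ≈ 0.019) — the published table reports
"p < 0.001" for that trend, which the printed stage counts do not
yield; the package reports the computed value.

## What the generators emulate — and what they do not

`gen_deletion_cohort()` plants a CDR in a locus and scatters
containing-fragment breakpoints uniformly within `breakpoint_spread`
(default 30 kb) of it; non-containing fragments are placed wholly in
the outer flank. Two deliberate simplifications: the first two
containing fragments are anchored exactly at the CDR endpoints, and
non-containing fragments never partially overlap the CDR. Together
they guarantee that the maximal-depth region *is* the planted CDR
whenever at least two fragments contain it and containing fragments
outnumber non-containing ones — which makes exact-recovery tests
meaningful. Real cohorts are messier: fragments do partially overlap
the CDR, real breakpoint distributions are not uniform, and the
maximal-depth region of real data can be narrower than the containment
consensus. Passing the recovery tests therefore validates the
sweep-line and containment logic, not robustness to adversarial
breakpoint structure.

`gen_qpcr_plate()` draws
$Ct = \text{baseline} - \log_2(\text{copies}/2) + \mathcal N(0, \sigma)$
independently per well and channel, with baseline 28 (arbitrary; only
differences matter), default $\sigma = 0.1$ cycles (a typical
good-practice triplicate spread), and spike-in mass fractions treated
as copy fractions (the two cell-line genomes taken as equal mass).
With $\sigma = 0$ the whole chain is exact: measured deletion
proportion ≡ planted null fraction, which the tests assert to machine
precision. The model has **no within-well correlation**: in a real
duplex reaction both channels share the well's template and pipetting
noise, so real $\Delta Ct$ replicates are less dispersed than
$\sqrt2\sigma$. That matters for one benchmark: with independent noise
at $\sigma = 0.1$ and triplicates, the power to flag the 20% mixture
against the 0% control is only
`power.t.test(n = 3, delta = log2(1/0.8), sd = sqrt(2) * 0.1)` ≈ 0.56,
so the assay's reported ability to detect the 20% mixture in ≥ 9 of 10
daily runs is *not* reproduced under this noise model — the
reproducibility test documents the shortfall rather than hiding it.
Reproducing it would require an effective $\Delta Ct$ SD near 0.07,
i.e. the shared-well correlation this generator deliberately omits.

`gen_clinical_table()` draws a binary covariate at a set prevalence
and the call from a logistic model with a planted odds ratio; Wald CI
coverage of planted OR ∈ {1, 2, 4} sits at ≈ 95% over 1,000
replicates of n = 400 in the acceptance suite. `table2_preset()` is
not sampled at all: it is the unique-by-construction 139-row table
whose two assay calls and eight covariates reproduce every printed
subgroup margin of the published association table (51/44/76/19
positives of 139; distant-metastasis cells 20, 12, 31, 76), with the
differentiation grade left missing for the 3 samples the published
table omits from that covariate. The joint distribution *across*
covariates is arbitrary (each covariate is assigned independently
within the four call cells), so the preset supports margin-level
statistics only.

## Problem sizes and numerical conventions

The test suite runs sweep-line-versus-per-base-count equivalence on
200 random cohorts over 1.5 kb spans, exhaustive Fisher enumeration
for all 2×2 tables with total ≤ 30, 2,000 simulated null pairs for the
type-I benchmark, 1,000 CI-coverage replicates per planted OR, and
10-seed recovery loops — sizes chosen to exercise every code path with
comfortably tight Monte-Carlo error. Rounding for reports is half-up
(`round_half_up()`), since banker's rounding would print the 5,110 bp
CDR as 5.1 but a 1,050 bp region as 1.0 kb. Seeds default to 20220917
everywhere and are explicit arguments; generators restore the caller's
RNG state.

## Known limitations

* CDR discovery assumes a single locus per run; no liftover between
  genome builds, no SV calling from reads.
* The qPCR layer starts from Ct values; fluorescence-curve processing
  and Ct determination are upstream of it. Reference-gene copy-number
  instability in tumors (which would bias every ΔCt) is not modeled.
* Association analysis is marginal per covariate: no multivariable or
  logistic modeling, no survival analysis.
* The spike-in detection-limit reproducibility gap under independent
  cycle noise, discussed above, is a property of the noise model, not
  of the detection-limit estimator.
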