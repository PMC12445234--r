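---
title: "Composite behavioral scoring and stress-signature extraction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite behavioral scoring and stress-signature extraction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbcsig)
```

## The problem and the model

A single severe stressor produces a spectrum of long-term behavioral
outcomes in rats: some animals display persistent, consistent anxiety-like
behavior across assays, others are indistinguishable from controls. Because
no single assay separates these phenotypes reliably, the field aggregates a
battery of avoidance tests into a composite score built from Cutoff
Behavioral Criteria (CBC): each measure is binarized against a percentile
cutoff of the *control* distribution, and the binary flags are summed.
Animals whose composite exceeds the observed control range are classified
*vulnerable*; stress-exposed animals within the control range are
*resilient*. Transcriptomic signatures of those phenotypes are then read
off the overlaps of pairwise differential-expression (DE) contrasts between
control (C), stress-low/resilient (SL), and stress-high/vulnerable (SH)
groups: genes in both SL-vs-SH and C-vs-SL separate the resilient group
from everything else (the *resilience* signature); genes in both SL-vs-SH
and C-vs-SH mark the vulnerable group (the *susceptibility* signature).

`cbcsig` implements this chain end to end, plus a seeded generator of
synthetic cohorts with the statistical structure the analysis assumes.

## Scoring: thresholds, ties, and sub-scores

**Percentile estimator.** The cutoff is the 20th percentile of the control
values for measures where low values indicate the affected state, and the
80th percentile where high values do. The percentile itself is estimated by
linear interpolation between order statistics (the common statistical
default, `quantile()` type 7); a nearest-rank option (type 1) is available
because the underlying scoring scheme predates any standard estimator
choice. With 10 controls at values 1..10, the two estimators give cutoffs
of 2.8 vs. 2 for a 20th-percentile measure.

**Tie rule.** "Beyond the cutoff" is a strict inequality: an animal exactly
at the cutoff is unaffected. This is the conservative, deterministic
choice; with a degenerate control distribution (all controls identical) no
animal can be flagged.

**Sub-scores.** The default registry enumerates 20 avoidance metrics —
5 per open field test under bright and dim light (latency to center,
frequency in center, time in center, total distance, center distance),
3 per elevated plus maze under bright and dim light (latency to open arms,
time in open arms, time in closed arms), and 4 for the light-dark box
(distance, latency to the light side, frequency and time on the light
side) — which is the only registry consistent with a composite bounded by
20. Direction defaults encode the anxiety reading: latencies to anxiogenic
zones and time in protected zones are high-affected; exploration of
anxiogenic zones and locomotion are low-affected. The two acoustic startle
metrics (mean startle over the 15-pulse habituation phase, and
sensitization, the percent change from the first to the last triad of
pulses) are scored as a *separate* startle sub-score at the 80th-percentile
rule, reported alongside rather than inside the 0-20 avoidance scale: the
published scale caps at 20, which accounts exactly for the avoidance
metrics, while sub-score figures show startle separately. The reported
`total` is avoidance + startle and the classification column is
configurable.

**Classification.** Vulnerable means strictly greater than the maximum
observed control total; a stress animal tied with the control maximum is
within the control range, hence resilient. Controls always keep the
`control` label.

**Selection for sequencing.** The `k_low` lowest and `k_high` highest
scoring stress animals (defaults 3/3) and `k_control` controls (default 6)
evenly spaced by score rank, with deterministic lexicographic tie-breaks on
animal id.

## Startle metrics

Startle amplitude is the maximum activity in a response window after pulse
onset minus baseline activity. Two conventions needed fixing where the
field's description is ambiguous:

- the "50 ms surrounding the pulse" is taken as `[onset, onset + 50 ms]`,
  since startle latency follows the pulse and a centered window would
  dilute the response with pre-pulse baseline; the window is configurable;
- baseline is the mean activity over the 1 s preceding onset (per-trial,
  not per-session), the standard pre-stimulus contract.

Amplitudes are not floored at zero — the difference formula legitimately
produces negative values for sub-baseline responses — and flooring is left
to the user. Amplitude is invariant to adding a constant to the whole
trace; sensitization is invariant to rescaling all amplitudes.

## The synthetic cohort generator

The generator defines the study conditions under which everything is
tested: 19 control and 20 stress-exposed animals, with stress animals a
mixture of resilient- and vulnerable-latent classes (vulnerable fraction
0.3).

Each animal carries a shared anxiety factor `a0 ~ N(0, 1)`; an avoidance
metric's standardized deviation toward its affected direction is

```
z = rho * a0 + sqrt(1 - rho^2) * eps + shift * 1[vulnerable]
```

with `eps ~ N(0, 1)` metric noise, `rho` the metric loading (default 0.3)
and `shift` the anxiety shift (default 3 control-SDs). Control values
therefore follow exactly the registry's control distribution (Gaussian by
default; a moment-matched lognormal option exists for skewed measures such
as latencies), animals are consistently anxious or calm across assays
through `a0`, and vulnerable-latent animals are displaced by `shift`
control-SDs on *every* avoidance metric. Latent anxiety is `a0 + shift` for
vulnerable animals. Two designs were considered for where the shift enters:
through the latent factor only (`z = rho * (a0 + shift) + ...`), or as a
direct per-metric displacement. The direct form was chosen: with the shift
passing only through a factor loaded at `rho`, the metric-level separation
is `rho * shift` and the maximum of 19 control latents (~1.9 on average)
overlaps a vulnerable class centered at 3, so no loading can make the
classifier recover ≥90% of latent classes at shift 3; the direct form
separates metric-level displacement from cross-assay consistency and
recovers the classes essentially perfectly at the default settings.

The registry's per-metric control means and SDs are generator defaults in
plausible natural units, not estimates from any dataset — the source study
does not publish per-metric control moments — and are fully
user-configurable.

Startle responsiveness (a per-animal lognormal gain with a mild
multiplicative habituation trend across the 15 pulses) is drawn
independently of the latent class: in the emulated design the startle
sub-score did not separate the groups, and an independent startle channel
keeps the avoidance signal the only class-informative input. Traces render
the per-pulse response heights as exponentially decaying transients on
Gaussian baseline noise; with zero noise the downstream amplitude
computation recovers the injected heights exactly (a closed-loop test).

3-h corticosterone is built as
`180 + 70 * (r * z_lat + sqrt(1 - r^2) * eps)` ng/mL with `z_lat` the
standardized latent anxiety, so its correlation with latent anxiety targets
`r` (default 0.55) across the cohort; 30-min corticosterone carries a group
effect but no latent coupling. Percent weight change is Gaussian per group
(defaults: control +0.5 ± 1.0%, stress −4.0 ± 1.5%). A caveat on small-n
correlation checks: at n = 18 the sampling SD of a correlation around 0.5
is ≈ 0.2 (Fisher z, 1/sqrt(15)), so single-cohort recovered correlations
scatter widely around the target; the targeting invariant is therefore
asserted at n ≥ 200, where the empirical correlation lands within ±0.1 of
the target.

Counts are negative-binomial at a common dispersion with library sizes
varied ±20%; planted genes are multiplied by `2^log2FC` in their affected
group (`stress_low`, `stress_high`, or both), which induces exactly the
contrast pattern the signature logic expects: a stress-high-only gene
appears in C-vs-SH and SL-vs-SH, a stress-low-only gene in C-vs-SL and
SL-vs-SH.

One master seed is split into deterministic per-stage substreams, so every
stage is individually reproducible and identical configuration plus seed
gives byte-identical outputs.

**What the generator does not emulate.** Test-order and habituation effects
across the 2-day battery; video/pixel-level structure of activity traces
(they are abstract signals); assay-specific measurement floors/ceilings
(e.g. a latency cannot exceed the session, but Gaussian tails can);
gene-gene correlation and realistic mean-variance trends in counts. Passing
tests therefore certify the analysis logic under the assumed statistical
structure, not performance on any real cohort.

## The differential-expression engine

The engine is a documented, replaceable stand-in: the signature logic
accepts DEG tables from any engine via `as_deg_table()`/`read_deg_table()`.
Its design:

- **Normalization**: median-of-ratios size factors, falling back to
  total-count ratios when fewer than 10 genes are expressed in every
  sample.
- **Dispersion**: per-gene method-of-moments on the pooled within-group
  variance of normalized counts, shrunk 50% toward the 10%-trimmed-mean
  common dispersion and *floored at the common dispersion*. The floor is a
  deliberate calibration choice: at n = 3 per group the MoM estimator is
  extremely noisy, and genes whose dispersion is underestimated by chance
  otherwise dominate the discovery list — in a pilot grid, symmetric 50%
  shrinkage alone left the empirical FDR at ~0.18 for dispersion 0.2,
  while the floor brings it to ≤ 0.08 across dispersions 0.01-0.2 with
  raw-p type-I fractions of 0.043-0.053 and power ~1.0 at log2FC 2,
  dispersion 0.05. The asymmetry (genes above the common value keep their
  own estimate; genes below are raised to it) mirrors the conservative
  max-style moderation used by early RNA-seq engines.
- **Test**: Wald z on the log2 ratio of normalized group means with a 0.5
  pseudocount on each mean (which also handles zero groups), two-sided
  normal p, Benjamini-Hochberg adjustment, significance at adjusted
  p < 0.05 (configurable).

A consequence of the gene-specific dispersion term is robustness: a single
20-fold-inflated sample inflates the gene's dispersion and the gene is
*not* called — the engine does not produce the classic single-outlier
false positive. Outlier-driven calls still occur at the detection boundary,
which is what the leave-one-out filter targets.

**Sample screening.** PCA-based flagging mirrors the exclude-if-it-
clusters-with-nothing rule: a sample is flagged when its nearest-neighbor
distance in the first two principal components exceeds 3 times the median
nearest-neighbor distance. The multiplier is configurable; `k = Inf`
disables flagging, and identical samples (all distances zero) flag
nothing.

## Signature overlap and the outlier filter

**Gene identity.** Overlaps are computed on a (symbol, normalized full
name) key: names are case-folded, whitespace-collapsed, and balanced
parenthetical aliases (including nested ones) are stripped. Symbol-only
matching would merge distinct genes printed under the same symbol — the
packaged fixture tables contain such a collision (two different
ribosomal-protein entries under one symbol), and symbol-only intersection
yields exactly one more "overlap" than the identity-keyed count, which is
pinned as a regression test.

**Direction.** The overlap is set-based by default, matching Venn-diagram
logic; a direction-consistent mode additionally requires matching
fold-change signs when both tables carry them.

**Outlier filter.** The published analyses disregarded signature genes
whose DE was "driven by outlier values" without defining the procedure
(it references supplementary material). The package's rule is stated and
logged: remove the single sample with the largest absolute within-group
z-score of the gene's log2(normalized + 1) values, rerun the DE engine,
and flag the gene if it is no longer significant at the working threshold.
The removed sample's identity and the post-removal adjusted p are attached
to the flag. If removal leaves a group below 2 samples the gene is flagged
with a degenerate-design warning. Cleanly planted 4-fold genes survive the
filter in ≥90% of seeds.

**Normality reporting.** Single-gene expression-behavior correlations
report Pearson r with a two-sided t-test p plus Shapiro-Wilk and
D'Agostino-Pearson omnibus normality tests on the transformed expression
values. The K² omnibus test (z-transformed skewness and kurtosis, referred
to chi-squared with 2 df) is implemented in the package and cross-checked
against an independent reference implementation in the test suite; it
requires n ≥ 8 and reports `NA` below that.

## Numerical choices and degenerate inputs

- Thresholds require ≥ 2 finite control values per metric; NA controls are
  an error, not silently dropped.
- Correlations drop incomplete pairs pairwise with a warning (mirroring
  cohorts with missing weight records) and refuse zero-variance input.
- TPM errors on all-zero sample columns, naming the sample; every column
  of a valid TPM matrix sums to 1e6.
- `bh_adjust` validates p ∈ [0, 1] and delegates to the standard step-up
  implementation. The adjustment is monotone in the sorted order, ≥ the raw
  p-values, capped at 1, and fixed under re-application only on tied
  outputs (re-adjusting a generic adjusted vector re-applies the m/rank
  factors, so generic idempotence does not hold for any faithful BH
  implementation).
- Sensitization is undefined (error) when the first-triad mean is zero.
- Selection tie-breaks are lexicographic on animal id everywhere, making
  every pipeline output reproducible byte for byte under a fixed seed.

## Problem sizes in the test suite

The suite exercises the statistical claims at deliberately scaled sizes
chosen to make sampling error small relative to the asserted margins:
threshold calibration at n = 10,000 controls (±0.02 of the nominal 0.20);
DE type-I, power and FDR over 100 seeds of 500-gene matrices at n = 3 per
group (30 seeds per dispersion for the FDR grid); end-to-end signature
recovery over 100 seeds of 2000-gene, 11-sample designs; classification
recovery over 100 simulated 39-animal cohorts. The full suite runs in
roughly a minute on one core.

## Known limitations

- The NB Wald test is a calibrated stand-in, not a reimplementation of any
  published empirical-Bayes DE engine; posterior-probability scales are
  mapped to adjusted p only by convention (adj_p plays the role of
  1 − PPDE downstream).
- The outlier rule is a stated convention where the original procedure is
  unpublished; borderline genes can flip between flagged/unflagged across
  reruns of a stochastic design.
- Synthetic control moments are placeholders; conclusions about real
  cohorts require replacing the registry defaults with measured control
  distributions.
- The generator's corticosterone model couples only the 3-h time point to
  latent anxiety and uses no group offset there, which is the minimal
  structure for the correlation-targeting contract, not a physiological
  model of the stress time course.
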