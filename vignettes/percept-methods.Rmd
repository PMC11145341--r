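---
title: "Scaling effects by confidence: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaling effects by confidence: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(percept)
library(dplyr)
```

## The model

Binary thresholding of p-values (keep if $p < 0.05$, discard otherwise)
is a blunt instrument for noisy, low-replicate datasets: features with
large effects but unlucky variance vanish entirely, while everything
that clears the bar is treated as equally trustworthy. This package
implements a continuous alternative. Each measured effect is scaled
toward a hypothetical mean with an intensity governed by its p-value:

$$ V = m_0 + (m_1 - m_0)\,F^{-p} $$

where $m_1$ is the replicate mean, $m_0$ the hypothetical (null or
ground-truth) mean, $p$ the p-value of a one-sample t-test of the
replicates against $m_0$, and $F > 1$ a tunable *penalty factor*. The
scaling factor $F^{-p} \in [1/F, 1]$ is 1 at $p = 0$ (full
preservation) and $1/F$ at $p = 1$ (maximal suppression), so $V$ always
lies on the segment between $m_0$ and $m_1$. The transform is an ad-hoc
reweighting, not a frequentist estimator: it trades the certainty of a
hard cutoff for a graded view in which low-confidence effects shrink
instead of disappearing. Two consequences worth keeping in mind:

* significant measurements barely move — even at $F = 500$ the factor
  at $p = 0.05$ is $500^{-0.05} \approx 0.733$, so the method cannot
  "undo" a significant effect;
* all effect sizes are flattened somewhat, so scaled magnitudes are not
  directly comparable to raw ones.

## Parameters

* **`m0`** (hypothetical mean, units of the data): 0 for log2 ratios, 1
  for raw ratios, or any externally known reference value (e.g. a
  ground-truth pixel intensity). It is both the null of the t-test and
  the attractor of the scaling.
* **`penalty` / `F`** (unitless, $> 0$): controls suppression strength.
  The package default where one is needed is `default_penalty(n) = 10 * n`,
  which offsets the mechanical decrease of p-values with sample size so
  differently-sized studies are penalised comparably. `F` is a free
  parameter everywhere; the cohort-evaluation functions default to
  `F = 20`, the value used throughout the 5-donor subsampling analyses
  here. `F <= 1` is permitted but warns, since $F^{-p} \ge 1$ then
  amplifies noise. $F^{-p}$ is evaluated as $\exp(-p \ln F)$ for
  stability at large $F$.
* **`alpha`** (default 0.05) and the effect bounds (`lower`, `upper`,
  log2 scale) define the volcano quadrants. "Significant" means
  $p < \alpha$ strictly; "affected" means effect $>$ `upper` or $<$
  `lower` strictly, mirroring the usual printed forms
  ($-\log_{10} p > 1.3$, effect $> 0.077$, ...).
* **`coverage`** (default 0.90): the fraction of the pseudo-control
  distribution the data-driven thresholds must encompass.

## Degenerate inputs and numerical conventions

* Zero sample variance would make the t statistic undefined. We take
  the continuous limit instead: identical replicates differing from
  `m0` give $p = 0$ (a perfectly consistent deviation is preserved);
  identical replicates equal to `m0` give $p = 1$. No `NaN` ever
  propagates.
* Missing values are dropped per feature before computing $n$, mean and
  sd; features left with $n < 2$ return an `NA` row with a `note` flag
  so whole-table runs never abort.
* Quantiles use linear interpolation between order statistics
  (`stats::quantile()` type 7), stated so other implementations can
  match bit-for-bit.
* The empirical CDF places the $i$-th order statistic at position
  $i/n$ (maximum at 1). `interpolate_cdf()` returns, at each of 101
  equidistant positions $0, 0.01, \dots, 1$, the value whose position
  is nearest to the target, ties broken toward the lower position —
  a fixed grid that makes CDFs from different trials averageable.
* Bland–Altman "95% limits" are the classical limits of agreement,
  $\bar d \pm 1.96\,\mathrm{sd}(d)$ with the $n-1$ denominator.
  Standard deviations use $n-1$ throughout.
* Image pixels are addressed 1-based, row-major, the native R
  convention for matrices.

## Data-driven effect thresholds

Rather than a fixed fold-change cutoff, `pseudo_control_thresholds()`
derives bounds from the controls themselves: per feature, the control
donor labels are permuted (seeded) and each donor's value is divided by
the mean of the permuted cohort for that feature; the pooled log2
ratios form a "pseudo-control" distribution of effect sizes expected
from experimental variability alone, and the central `coverage`
quantiles become the bounds. Because a permutation leaves a mean
unchanged, this is numerically identical to dividing each control value
by its feature's control mean — the permutation is kept explicit (and
seeded) so that alternative randomisation schemes, e.g. ratios between
randomly paired donors or random cohort splits, can be swapped into the
same function without changing its contract. The bounds are not forced
symmetric; real pseudo-control distributions rarely are.

A point that surprised us while validating the ratio pipeline: ratios
formed against a *finite* control cohort are not i.i.d. null even for
pure-noise data. All case ratios of a feature share that feature's
control-mean estimation error, which inflates the one-sample t-test's
type-I rate above its nominal level (noticeably below ~30 controls),
and the arithmetic control mean contributes a Jensen bias of about
$-\sigma^2 \ln 2 / 2$ on the log2 scale. This is a property of the
ratio design itself, not of the scaling; the tests therefore check the
nominal 5% level on an i.i.d. null table and treat the ratio pipeline
separately.

## What the synthetic generators emulate — and what they do not

`generate_cohort()` produces per-donor intensities
`baseline * 2^(effect + noise)` with log-normal baselines
(`exp(N(14, 2))`, a proteomics-like dynamic range), a minority of truly
affected features (default 30% at $|\log_2 \mathrm{FC}| = 0.5$, signs
randomised), and i.i.d. Gaussian log2 noise (default sd 0.6, roughly
the donor-level spread seen in CSF proteomics cohorts). The noise
defaults are deliberately harsh relative to the effect so that small-n
draws are unreliable — the regime the method is for.
`generate_ground_truth_image()` plus `simulate_stack()` reproduce the
imaging demonstration: a binary 0/1 motif corrupted by standard-normal
per-pixel noise, replicate by replicate.

The generators do **not** simulate missingness mechanisms, batch or
center effects, feature–feature correlation, heavy-tailed noise, or
peptide-level quantification. Passing tests on these cohorts therefore
show that the machinery behaves as specified under clean i.i.d. noise
with known truth; they do not certify performance on real data, where
the published analyses of deposited cohorts are the relevant evidence.

## Evaluation design

`subsample_donors()` draws `k` donors (default 5) without replacement,
`trials` times (default 100), computing per-feature raw means and
scaled values and their mean absolute distance to the full-cohort
population mean. Distances are comparable only on a common feature
set, so features with fewer than 2 finite values in a draw are dropped
from both sides. `normalize_distances()` rescales both columns by the
mean raw distance, making the raw baseline exactly 1. On the default
synthetic cohort (500 features, 40 case donors, 30% affected), scaled
5-donor summaries sit consistently closer to the population than raw
means — the direction, not any particular percentage, is the property
the test suite asserts, because the magnitude of the improvement
depends on the dataset's effect/noise mix.

Problem sizes used by the test suite were chosen to make the stochastic
properties decisive at desk scale: 64×64 images over 50 seeds for the
imaging comparison, 500 features × 40 donors × 100 trials for the
subsampling evaluation, 10,000 pooled pseudo-ratios for the threshold
coverage check.

## Open design choices made here

* **Four volcano categories.** Only three are usually named; points
  significant but inside the effect window get their own label `S/NA`
  so that categorisation is a true partition of the plane.
* **Subsample size bounds.** `2 <= k <=` cohort size; a full-cohort
  draw reproduces the population exactly (distance 0), a useful
  self-check.
* **Noise scale.** The imaging noise is standard normal by default
  (the parameter-free reading of "random noise"), with `noise_sd`
  exposed.
* **Penalty for 5-donor subsampling.** `F = 20` follows the published
  analyses even though `10 * n` would give 50; both are one argument
  away.
* **Seeding.** Every stochastic function takes an explicit `seed`;
  `run_scale_workflow()` derives stage-specific substreams from its
  master seed (the pseudo-control permutation uses `seed + 1`) so
  adding a stage never perturbs another stage's draws.

## Limitations

The transform is designed for small-n settings. With many replicates,
p-values for real effects collapse toward 0 and scaling converges on
mean smoothing; conversely it cannot rescue a design whose hypothetical
mean `m0` is wrong, since `m0` is both the test's null and the
attractor. Scaled magnitudes are compressed relative to true effect
sizes, increasingly so at large `F`, and no multiple-testing correction
is applied anywhere — the method consumes raw p-values by design.
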