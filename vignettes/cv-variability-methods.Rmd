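---
title: "Methods: global CV-shift estimation between replicate groups"
author: "cvdelta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: global CV-shift estimation between replicate groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvdelta)
```

## The question and the estimator

Given a probe-by-sample expression matrix with two groups of biological
replicates (wild-type and knockout), `cvdelta` estimates a single global
quantity: the geometric-mean fold-change in the coefficient of variation of
expression, knockout over wild-type, across all probe sets.

Per probe set $g$, each group yields a sample mean $\bar{x}_g$, sample SD
$s_g$ (denominator $n-1$), and CV $= s_g/\bar{x}_g$. The per-probe contrast
is $\Delta\log_{10}\mathrm{CV}(g) = \log_{10}\mathrm{CV}_{KO}(g) -
\log_{10}\mathrm{CV}_{WT}(g)$, and the estimator is its arithmetic mean
over analyzed probes — identically the $\log_{10}$ of the geometric mean of
the per-probe CV ratios. The log-ratio form is preferred to the arithmetic
difference $\Delta\mathrm{CV}$ because it weights all probes equally rather
than overweighting high-CV probes; the arithmetic variant is nevertheless
always computed as a robustness check, on the *same* probe set (probes with
a zero or undefined CV in either group are excluded from both variants so
the two remain comparable).

The CV rather than the SD makes variability comparable across genes whose
expression differs by orders of magnitude, and makes the whole analysis
invariant to a global intensity rescaling — a property the test suite
asserts, together with exact antisymmetry under swapping the group labels.

### Significance in log space

The null hypothesis — no KO/WT difference in CV, i.e.
$\mathbb{E}[\Delta\log\mathrm{CV}] = 0$ — is tested with a one-sample,
two-tailed $t$-test, $t = \bar{d}/(s_d/\sqrt{n})$, $df = n-1$. With
$n \approx 45{,}000$ probes even a modest global shift produces $|t|$ in the
tens, and $2\,S_t(|t|)$ underflows the smallest positive double
($\sim 10^{-308}$). The p-value is therefore computed as
$\log p = \log 2 + \log S_t(|t|)$ via `pt(..., log.p = TRUE)` and reported
as $pp = -\log_{10} p$, which is exact arbitrarily deep into the tail
(the suite checks agreement with the direct computation to $10^{-6}$
relative wherever the direct p does not underflow, and finiteness well past
$pp = 300$). The linear-scale p is also returned, as 0 when it underflows.
Normality of the per-probe deltas is not required at this sample size; the
distributions are in practice close to Gaussian anyway, which the histogram
overlay lets one inspect.

### The median-expression filter

A tissue expresses roughly half or fewer of the genes an expression array
probes; sub-threshold probe sets measure mostly noise, whose CV behavior is
dominated by the measurement floor. The default analysis therefore filters
out probe sets whose mean expression in *either* group falls below the
dataset-wide median. The threshold is the median over probes of the
per-probe grand mean (mean across all samples of both groups), one
threshold per dataset. Two genuinely open conventions were settled as
follows:

* *Threshold basis.* "Median expression of the dataset" could mean the
  median of per-probe means or of all raw values/pooled per-group means.
  The per-probe grand mean is the default because it yields exactly one
  well-defined expression level per probe regardless of replicate
  imbalance; `threshold_method = "pooled_means"` exposes the alternative.
* *Boundary.* Probes exactly at the threshold pass — only strictly
  sub-median expression is filtered. With ~45,000 distinct values the
  choice is immaterial in practice; degenerate all-tied inputs (every probe
  at the threshold) retain all probes.

The unfiltered analysis is always computed alongside; `summary()` prints
all four statistic-by-filter combinations.

### Outliers versus a global shift

A mean shift in $\Delta\log\mathrm{CV}$ could reflect either a few probes
with wildly different CV or a broad change across the transcriptome. The
two are distinguished by the relation between mean and median: outliers tug
the mean while leaving the median near zero; a global shift moves both
together. The package quantifies this with a 95% percentile bootstrap
interval for mean − median (resampling probes with replacement, default
1000 resamples, seeded and bit-reproducible). A closed-form distribution
for mean − median is awkward; the percentile bootstrap is the standard
nonparametric choice. The histogram overlay is a normal fitted by moments,
so its centre marks the mean; Freedman–Diaconis binning (capped at 200
bins) is used since no binning convention is canonical.

## The synthetic generator

`simulate_dataset()` provides ground truth. Its model:

* True levels $\mu_g$ log-normal: $\log_{10}\mu_g \sim N(2,\ 0.8)$ —
  intensities centred at 100 arbitrary units spanning ~4 decades, a typical
  processed-array range.
* WT replicate value $= \mu_g(1+\varepsilon_m) + \varepsilon_a$ with
  $\varepsilon_m \sim N(0,\ \texttt{cv\_mult}=0.1)$ and
  $\varepsilon_a \sim N(0,\ \texttt{sigma\_add}=2)$. Multiplicative noise
  gives SD $\propto$ mean at high expression; the additive floor, which does
  not vary with expression, makes CV
  $\approx \sqrt{\texttt{cv\_mult}^2 + \texttt{sigma\_add}^2/\mu^2}$ fall
  monotonically with $\mu$ — the two mean–variance signatures of real
  arrays. The defaults were fixed once, by a coarse grid over
  (`sigma_add`, `mean_log_sigma`), to the qualitative targets
  $r(\log SD, \log \bar{x}) > 0.9$ and $r(\log CV, \log \bar{x}) < -0.3$
  with a sub-1% clip rate; they are not fitted to any particular dataset
  (no public dataset publishes its noise parameters).
* KO replicate value $= \mu_g 10^{\delta}(1+\varepsilon_m') +
  \varepsilon_a'$ with *both* noise components scaled by $f_g$:
  $\varepsilon_m' \sim N(0, f_g\,\texttt{cv\_mult})$,
  $\varepsilon_a' \sim N(0, f_g\,\texttt{sigma\_add})$. Scaling both
  components makes the KO sample-CV distribution $f_g$ times the WT one (up
  to the small noise in the denominator mean), so
  $\mathbb{E}[\Delta\log_{10}\mathrm{CV}] = \log_{10} f_g$ and parameter
  recovery is a clean end-to-end check. $f_g$ equals the global `f_cv` for
  most probes, times `outlier_factor` for a random `outlier_fraction` of
  probes — emulating an outlier-driven scenario at `f_cv = 1`.
* Values below a small positive floor (`intensity_floor = 1e-3`) are
  clipped, keeping matrices nonnegative so they pass the same validity
  screens as deposited data; a clip rate above 1% warns and above 20%
  errors. Clipping rather than rejection preserves the independence
  structure; the rate is reported.

What the generator does **not** emulate: probe-level (multi-feature)
summarization, batch and litter/cage structure, correlated noise across
probes, heavy-tailed or skewed noise, and platform-specific normalization
artifacts. Passing tests on synthetic data therefore demonstrate that the
statistics recover what the model encodes — not that any particular
biological dataset satisfies the model. On real data, litter effects or
processing differences can produce genuine global CV shifts whose *cause*
this package deliberately does not adjudicate.

## Defaults and sizes used in the checks

Replicate counts default to 4 per group (the realistic floor for public
knockout series; fewer than 4 fails validation by default, and the
additional precision of 5 is used where a specific strong-shift scenario is
exercised). The automated checks run at sizes chosen to keep the full suite
fast while leaving the statistical properties intact: parameter recovery at
20,000 probes × 50 simulations per $f_{cv} \in \{0.67, 1, 1.5\}$ (the
recovered mean must fall within $3\cdot$SEM of $\log_{10} f_{cv}$ in ≥95%
of runs); null calibration over 200 null simulations of 5,000 probes
(p-uniformity is size-free, so the smaller matrix only speeds things up);
the outlier diagnostic at 20,000 probes with 2% outlier probes at 10× CV,
replicated 5 times with a majority rule since the median displacement sits
near its $3\cdot$SEM decision bound by construction; and structure checks
at the full default 45,000 probes.

## Numerical and degenerate-input conventions

* Sample SD uses the $n-1$ denominator throughout (4–5 replicates make the
  bias correction material).
* All logarithms are base 10, matching the field's axes and the $pp$
  convention.
* Probes with any missing replicate value in either group are excluded
  (with a logged count) rather than analyzed at unequal $n$, which would
  bias SD comparisons.
* A probe with nonpositive mean has an undefined CV; a probe with zero CV
  in either group has an undefined log-ratio: both are excluded with
  recorded reasons from both statistic variants.
* A constant delta vector yields $t = 0$, $pp = 0$ when its mean is zero,
  and an infinite-$t$ sentinel with a warning when it is not.
* Bootstrap and generator draw from private, seeded RNG streams and restore
  the caller's `.Random.seed`; identical seeds reproduce results
  bit-for-bit. Collections derive per-dataset seeds from a master seed plus
  the dataset index.
* Expression values are analyzed exactly as deposited (no renormalization,
  no log-transform of intensities): the statistics are computed on
  linear-scale values and only *summaries* are logged.

## Limitations

The method estimates one global shift per dataset; it neither identifies
which genes change variability (no per-gene test, no multiplicity
correction) nor explains why — biological feedback, background genetics and
husbandry inconsistencies are all observationally equivalent at this level.
The accompanying cross-dataset correlation of mean expression shift versus
mean variability shift (`cross_dataset_correlation()`) can rule out one
specific artifact — a global transcriptional induction/repression masquerading
as a variability change through the CV–expression relationship — but no
more than that.
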