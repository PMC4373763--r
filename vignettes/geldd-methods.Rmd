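---
title: "geldd: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{geldd: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geldd)
```

This vignette documents the statistical model behind `geldd`, the
assumptions baked into each stage, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the numerical conventions a careful user should know about. It states no
empirical result that the test suite does not itself compute.

## The problem

Two-dimensional gel electrophoresis separates a proteome into spots by
isoelectric point (x) and molecular weight (y); the integrated stain
volume of a spot is a proxy for protein abundance. Differential display
compares spot volumes between two cell lines. The statistical difficulty
is that each spot has its *own* noise level: small spots near the gel
edges can fluctuate two-fold between biological replicates of the same
line, while large central spots are reproducible to a few percent. A
single global fold-change cutoff is therefore either too lax for noisy
spots or too strict for quiet ones. `geldd` gives every spot a personal
threshold estimated from control replicates, and requires a differential
call to clear both that threshold and an FDR-adjusted Welch test.

## Intrinsic variability: the bootstrap null

For one spot with control volumes $v_1,\dots,v_n$ ($n \ge 2$, all
positive), two pseudo-groups of configurable sizes (default 7 and 7) are
drawn with replacement, and the orientation-free fold difference of their
means, $\max(\bar m_1,\bar m_2)/\min(\bar m_1,\bar m_2) \ge 1$, is
recorded; the default 1000 repetitions yield an empirical distribution
whose 95% quantile (type-7 linear interpolation) is the spot's intrinsic
fold variability $q_{95}$.

Choices made where the procedure was genuinely open:

* **Orientation-free fold.** The null fold is used as a symmetric
  threshold for both up- and down-regulation, so the max/min form (always
  $\ge 1$) is the natural statistic. Swapping the pseudo-groups leaves it
  unchanged, and it is invariant to rescaling all volumes — the quantile
  is scale-free.
* **Pseudo-group sizes.** Two groups of sizes equal to the real design
  (7, 7) are drawn from the *pooled* control replicates. An unbalanced
  (6, 7) variant is available via `bootstrap_settings(subgroup_sizes=)`
  for designs where one gel was lost.
* **Quantile estimator.** Type-7 (the R default) is fixed explicitly so
  results are bit-reproducible across environments.
* **Seeding.** One master seed; every spot consumes a deterministic
  substream derived from it by a counter, so any subset of spots
  reproduces identically regardless of processing order or parallelism.

## The threshold GLM

Per-spot quantiles from 7 replicates are noisy; they are smoothed with a
Gaussian GLM on the log scale:

$$\log q_{95,i} = \beta_0 + \beta_1 \log \bar V_i + \beta_2 x_i +
  \beta_3 y_i + \varepsilon_i,$$

with $\bar V_i$ the mean control volume and $(x_i, y_i)$ the spot
coordinates normalized to the unit square per gradient (so the position
covariates are scale-free across gel formats). The predicted threshold is
$T_i = \max(1, e^{\hat\eta_i})$.

* **Family and link.** Fold quantiles are $\ge 1$ and multiplicative, so
  a Gaussian model on $\log q_{95}$ (equivalently, a log-link mean model)
  is used. This is an assumption, not a known property of any particular
  software's internals.
* **Position encoding.** Two additive linear terms, no interaction. The
  synthetic generator produces exactly this structure, which is what makes
  coefficient-recovery tests meaningful; on real gels the surface may be
  curved, and the linear terms are then a first-order approximation.
* **Degenerate designs** (e.g. a constant covariate) are refused with a
  pointer to `intercept_only = TRUE` rather than silently dropped.
* At least 10 spots are required to fit; the flooring at 1 only binds
  when the fitted surface dips below no-change.

## Differential calls

Fold change is knockdown mean over control mean (values < 1 are down in
the knockdown). Welch's t-test is run on **log volumes by default**
(`scale = "log"`), consistent with the multiplicative threshold; the raw
scale is available because volume-scale testing is also defensible and
some labs prefer it. Discovery p-values are two-tailed and adjusted by
Benjamini–Hochberg step-up (ties need no special handling in the standard
min-cummin formulation). Selection requires

* `p_fdr <= alpha` (default 0.05), **and**
* `max(fold, 1/fold) >= threshold`.

The conjunction is never less conservative than FDR alone — a property
the test suite checks on every input it generates. Spots with any
non-positive volume in a tested group are excluded with a warning: fold
changes on zero means are undefined, and a zero inside a log-scale test
is meaningless.

Validation against a reference line (non-transfected wild-type gels)
requires direction concordance of the knockdown-vs-reference fold with
the knockdown-vs-control fold *and* a one-tailed Welch p $\le \alpha$.
The one-tailed choice reflects that validation asks a directional
question ("is it still up?"), not a two-sided one. This exact criterion
is a design decision; the literature rarely states one.

## Power analysis

`spot_power(log_sd, n, fold, alpha)` is the probability that the
two-sided test detects a true fold change `fold` for a spot whose
log-volume SD is `log_sd`, with the standardized effect
$\log(\mathrm{fold})/\sigma_{\log}$ and noncentrality
$\delta = \log(\mathrm{fold})/\sigma_{\log}\sqrt{n/2}$.

Two methods are provided:

* `"pooled"` — the textbook noncentral-t formula with $2n-2$ df. This is
  what classical sample-size packages compute. It is *optimistic* for the
  Welch test at small $n$: the Welch–Satterthwaite df is estimated per
  dataset and its randomness costs real power (at $n = 4$ the gap
  approaches 0.05).
* `"welch"` (default) — the exact power of the Welch test under equal
  group SDs, obtained by Gauss–Legendre quadrature over the joint
  distribution of the two sample variances (the scaled total is
  $\chi^2_{2(n-1)}$ and the split is Beta$((n{-}1)/2,(n{-}1)/2)$,
  which determines the Satterthwaite df). Accuracy is ~10⁻⁴ with the
  default 48 nodes; the acceptance suite checks it against Monte Carlo
  within 0.005. Since the pipeline's tests *are* Welch tests, this is the
  self-consistent default.

`sample_size_profile()` converts a pilot experiment's per-spot SD
distribution into the fraction of spots reaching a target power (default
0.8) for each candidate per-group $n$ (default 2–12) and fold (default 2
and 1.5), plus the smallest $n$ meeting a coverage goal.
`calibrate_sd_scale()` rescales a base SD distribution by bisection so
that an exact target fraction of spots meets the design point — the tool
used to build synthetic pilots whose power profile matches a stated
design outcome; the returned scale is taken from the feasible side of the
bisection bracket so the boundary spot still counts.

## Spot deconvolution

Hit confidence follows the MASCOT-style rule: at least three MS/MS
spectra with ion scores strictly above 20, or two strictly above 40.
The rule is monotone (extra spectra never hurt). NSAF is
$(S_k/L_k)/\sum_j (S_j/L_j)$ over the proteins of one list; entries with
zero spectra get NSAF 0, and an all-zero list is an error rather than a
silent NaN.

Triage of a mixed spot compares the knockdown/control NSAF ratio of each
protein confident in both conditions against `min_ratio` (default 1.5)
and the spot's own regulation direction; a protein moving with the spot
is `concordant_regulated`, against it `discordant_flag_wb`, otherwise
`unchanged`. Proteins confident in only one condition cannot be ratioed;
the highest-NSAF such protein per condition is flagged
`single_sample_flag_wb`. Zero counts are replaced by a pseudocount
(default 0.5) before ratio formation — it preserves direction while
avoiding division by zero; results for spots with reasonable counts are
insensitive to its exact value. "Major hit = highest NSAF" is our
operationalization of "major protein component"; no standard metric
exists. The raw spectral counts are carried through to the output so a
reviewer can apply a different rule.

## The synthetic-data generator: a stated world

`generate_spot_table()` draws, for spot $i$ and gel $g$,

$$\log V_{ig} \sim \mathcal N\!\big(\mu_i + [g \in \mathrm{kd}]\,
 \log f_i,\; \sigma_i\big), \qquad
 \sigma_i = c_0 \exp\!\big(c_V (\mu_i - \mu_c) + c_x (x_i - 0.5) +
 c_y (y_i - 0.5)\big).$$

Defaults, chosen once and documented here:

| parameter | default | why |
|---|---|---|
| `n_spots` | 2000 | typical per-gradient spot counts (≈1600–2300) |
| `n_replicates_per_group` | 7 | the replicated 2DE design the pipeline targets |
| `log_volume_mean_range` | log(1e4)–log(1e7) | volumes spanning three orders of magnitude |
| `cv_intercept` $c_0$ | 0.30 | ~30% relative SD at mid-volume, gel centre — a realistic 2DE replicate CV |
| `cv_slope_logvolume` $c_V$ | −0.05 | larger spots are more reproducible |
| `cv_coeff_x`, `cv_coeff_y` | 0.30, 0.20 | mild positional trend (edge spots noisier) |
| spiked folds | user-set, typically 0.3–2.6 | the magnitude range differential display targets |

The log-normal law is an assumption: gel volumes are positive and
right-skewed, and no distributional statement is available to copy. The
variance model mirrors the threshold GLM's covariates deliberately — it
makes GLM recovery testable — which also means a green recovery test
shows correctness of the fitting machinery, *not* that real gels are
log-linear in these covariates.

What the generator does **not** emulate: missing/unmatched spots
(`dropout_rate` exists but defaults to 0, since the workflow assumes
edited, complete spot sets), stain saturation, spot overlap and bleeding,
correlated per-gel effects (each volume is independent given its gel's
group), or any pI/MW physics behind the coordinates. Green pipeline tests
on synthetic data therefore establish statistical correctness of the
machinery under the stated model, not robustness to gel artefacts.

`generate_hit_tables()` allocates a spot's total spectra to its proteins
multinomially with weights share × length × effect (longer proteins yield
more detectable tryptic peptides), and draws ion scores from a mixture
(85% exponential excess above 20, 15% uniform 5–20) so the confidence
filter has realistic material on both sides of its cutoffs.

## Numerical conventions and edge cases

* Zero-variance Welch comparisons: equal means give $p = 1$, unequal
  means $p = 0$ (the limit of the statistic).
* One-tailed p-values orient the alternative by the observed sign:
  $p_1 = p_2/2$ (0.5 at $t = 0$).
* Normalization scales every gel to the mean pre-normalization total; it
  is idempotent and preserves within-gel ratios exactly. A gel with zero
  total volume is an error.
* **Compositional attenuation.** Total-volume normalization makes volumes
  compositional: if a noticeable fraction of spots is truly up in one
  group, that group's totals rise and normalization shrinks *every* fold
  toward 1 (with 5% of spots at fold 2, the attenuation is ≈ 5% of the
  log-fold). The spike-recovery acceptance test accounts for this
  explicitly; users comparing heavily asymmetric conditions should be
  aware of it.
* All stochastic stages derive per-unit substreams from one master seed;
  pipeline outputs embed the seed and a configuration fingerprint and no
  timestamps, so a rerun is byte-identical.
* BH-adjusted p-values are capped at 1 and equal the brute-force step-up
  definition exactly (tested on 1000 random vectors).

## Known limitations

* The threshold surface is linear in $\log \bar V$, $x$, $y$; no spline
  or interaction terms. For gels with strongly curved variance surfaces
  the thresholds will be locally mis-calibrated.
* Variability is estimated from **control replicates only** (the design
  the method was built for); a knockdown-based or pooled estimate is out
  of scope.
* `spot_power` assumes equal group SDs and equal $n$; unequal designs
  would need the two-SD generalization of the quadrature.
* The FDR procedure is plain Benjamini–Hochberg; no permutation FDR and
  no moderated/shrinkage t-statistics — with 7 replicates per group,
  shrinkage across spots would likely add power, but it changes the
  method.
* Triage compares NSAF within one spot across conditions, as the
  within-spot hit lists imply; cross-spot protein inference is out of
  scope.
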