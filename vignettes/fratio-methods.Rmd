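---
title: "Separating fixed from random effects with resampling F-ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating fixed from random effects with resampling F-ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(fratiotest)
```

## The problem

In comparative biomedical signal studies — the motivating case is EEG
features such as spectral band powers and fractal-dimension estimates
measured on patients and controls under several mental conditions — the
subjects are a random draw from a larger population.  A group difference
found by a plain (M)ANOVA may therefore be *sample-specific*: the
between-group sum of squares $h^2$ mixes a fixed group effect
$(\Delta a)^2$, a random person effect $(\Delta pa)^2$, and error
$(\Delta e)^2$,

$$h^2 = (\Delta a)^2 + (\Delta pa)^2 + (\Delta e)^2.$$

The classical remedy enhances the error term from $e^2$ to
$e^2 + (\Delta pa)^2$ (the mixed-model group test implemented in
`classical_mixed_f()`), which costs power.  The alternative implemented
here exploits a different signature: a *fixed* effect is stable from
subsample to subsample, a *random* one is not, so the **variance of the
F statistic across random subject subsets** carries the information.

## The resampling F-ratio

`resample_f()` draws, $m$ times, a random subset containing a fraction
$p$ of every group's subjects (without replacement; per-group size
`round(p * n_g)` with round-half-to-even), keeps all their conditions,
and recomputes the F statistic of the chosen multivariate construction
(Hotelling–Lawley, Pillai, or Roy, from the eigenvalues $c_i$ of
$HE^{-1}$; `manova_decompose()` / `manova_f()`).  From the $m$ subset
values $F_j$ it forms

$$\sigma^2(F) = \frac{1}{m-1}\sum_j\left(F_j - \langle F\rangle\right)^2,
\qquad
R = \frac{\sigma^2(F)}{4\,\langle F\rangle^2}.$$

Error propagation under a pure random effect ($\nu = 1$, where $\nu$ is
the random share of the effect term) gives the null expectation
$E[R] = 1/(2\,df_k) + 1/(2\,df_{ek})$; a fixed effect ($\nu < 1$)
suppresses $R$.  `estimate_nu()` inverts the relation.

Two caveats shape the whole design:

* The subset spread estimates the sample-to-sample variance of F only
  *up to a factor* that depends on $(m, p,$ group sizes$)$: subsets of a
  single sample overlap and resample persons without replacement, which
  restricts the variance.  No analytic correction is applied.  Instead
  **all inference is by Monte Carlo**: the observed statistic is
  compared with a null distribution generated by the *identical*
  resampling procedure with identical $(m, p, k,$ group sizes$)$, so
  the unknown factor cancels.  This is the package's central
  calibration argument.
* A corollary is that the *point estimate* $\hat\nu$ inherits the
  uncorrected factor.  At the canonical design (15 + 15 subjects,
  $k = 4$, $m = 30$, $p = 2/3$) the measured null mean of $R$ is about
  0.36 against the idealized 0.50, so $\hat\nu$ centers near 0.81
  rather than 1.  $\hat\nu$ should be read as a relative indicator
  (smaller means more fixed), not as a calibrated estimate; the
  hypothesis tests are unaffected because of the cancellation above.

## The test-statistic family

With per-measure univariate statistics $F_i$ summarized on the *same*
subsets, the family is

* `teststat0` $= \sum_i \sigma^2(F_i) \,/\, 4(\sum_i \bar F_i)^2$ —
  pools the univariate ratios; small values flag a fixed effect in at
  least one measure.
* `teststat1` — replaces the $F_i$ by their contributions
  $k_i^j F_j$ to the df-adjusted eigenvalues $c_i\,df_e/df_h$ of
  $HE^{-1}$, weighted $1/g_i$ per the statistic type.
* `teststat1R` $=$ `teststat1` divided by the multivariate ratio
  $\sigma^2(F_{multi})/4\bar F_{multi}^2$ from the same splittings; its
  null expectation is 1, and significant deviations flag a fixed
  single-measure effect or a between-measure effect.
* `teststat1M` — the incremental form: a carried-over $F_c$ from $n_c$
  accepted measures plus one candidate,
  $[n_c^2\,\sigma^2(F_c) + \sigma^2(F_{add})] \,/\,
   4(n_c F_c + \bar F_{add})^2$, normalized as in `teststat1R`.  It
  asks whether adding the candidate changes the picture.

### The contribution matrix

The decomposition of an eigenvalue into per-measure contributions is
not unique; the package pins it down by the *trace picture*: the
diagonal entries $d_j$ of $HE^{-1}$ represent, on average, the
individual F values, and their sum is the trace.  Each $d_j$ is
distributed over the retained eigendirections proportionally to the
squared eigenvector loadings (normalized across directions) and the
rows are rescaled so that $\sum_j k_i^j F_j = c_i\,df_e/df_h$ holds
exactly.  Two consequences drove this choice:

* For a rank-one effect (two groups, $s = 1$) it reduces to
  $k^j \equiv 1$, and for uncorrelated measures to a 0/1 selection
  matrix.
* It keeps `teststat1R` centered at 1 under the null (measured
  $1.004 \pm 0.014$ over 200 replicates at the canonical design).  The
  tempting alternative — weighting measures by the full-sample loadings
  themselves — inflates the null mean to $\approx 1.4$, because the
  loadings are selected by exactly the noise the resampling measures.

Contributions are computed once on the full sample and held fixed
across splittings; per-splitting eigenvector tracking is unstable for
small subsets.  Negative diagonal entries of $HE^{-1}$ (possible with
correlated noise) are clipped to zero before attribution so the matrix
stays non-negative; the rescaling keeps the identity exact.

Under a single-measure fixed effect the implemented `teststat1R`
deviates *downward* from 1 (the fixed effect stabilizes the pooled
univariate terms more than the recomputed trace statistic); deviations
upward arise from between-measure effects.  Tests therefore treat the
deviation two-sided.

### Effective degrees of freedom

Pooled variance terms are summarized by the Welch–Satterthwaite form
$df_{eff} = (\sum\sigma_i^2)^2 / \sum(\sigma_i^4/df_i)$, which spans
$[1, \sum df_i]$ — 1 when one term dominates, the maximum for equal
contributions.  (The simpler ratio $\sum\sigma_i^2 / \sum\sigma_i^2/df_i$
is identically 1 for unit dfs and cannot express the observed spread,
so it is not used.)  For the pooled statistics the dfs are taken over
the per-measure resampling variances.

## Monte Carlo null distributions

`simulate_dataset()` generates the design the method is calibrated for:

$$\mathrm{value}(s \in g, t, j) = \beta_t + \Delta a_{g,j} + P_{s,j} +
\varepsilon_{s,t,j},$$

with one person deviate $P_{s,j} \sim N(0, \sigma_p^2)$ per subject and
measure shared across the $k$ conditions, i.i.d. cell errors
$N(0, \sigma_e^2)$ (optionally equicorrelated across measures), fixed
condition offsets $\beta_t$, and contiguous group blocks.  Defaults are
the canonical study conditions: 2 groups × 15 subjects, $k = 4$,
$\sigma_p = \sigma_e = 1$, offsets $\{0, 1, 2, 3\}\sigma_e$, no group
effect.  The offsets only mimic realistic state effects; both $H$ and
$E$ are computed about cell means, so the null distribution is
invariant to them (property-tested by Kolmogorov–Smirnov).  The
sampler is pluggable (`rdist`), since the Monte Carlo calibration never
relies on normality.

`build_null_distribution()` repeats simulate → resample → evaluate $L$
times (default $L = 100$; the add-one p-value $(r+1)/(L+1)$ of
`p_value()` has resolution floor $1/(L+1)$, so $L$ must be chosen to
match the probabilities of interest).  Quantiles use the rank rule
(`empirical_quantile()`, the $\lceil PL\rceil$-th smallest; rejection on
the low tail).  For statistics whose null level drifts with $df_{eff}$,
`quantile_vs_dfeff()` bins replicates by $df_{eff}$, fits
$q_P = a_P + b_P\,df_{eff}$, and `p_value()` level-adjusts the deviates
to the observed $df_{eff}$ along the fitted slope — deterministic and
cheap, instead of waiting for replicates with matching $df_{eff}$ to
arise by chance.

Every operation is a pure function of its inputs and seed; replicate
sub-seeds are drawn once from the master seed, and a failed replicate
is retried at most three times on a shifted sub-seed before aborting.

### What the generator does not emulate

Real feature tables bring heavy-tailed and skewed measures, artifact
segments, unbalanced designs and missing cells, serial dependence
between conditions, and measure correlations beyond equicorrelated
errors.  Passing the calibration suite therefore shows that the
machinery is correct *under the stated model*, not that the EEG
findings of any particular study are reproduced — the original
recordings are not available, and no claim about them is tested here.

### Comparison with the classical test

`compare_with_classical()` runs the scenario study: per simulated
dataset the classical mixed-model tail probability and the Monte Carlo
p-value of the ratio, summarized by the sign counts of
$\Delta P = P_{classical} - P_{F\text{-}ratio}$ and a 1-df
goodness-of-fit statistic against 50/50.  Under the null the signs are
balanced (calibration-tested).  Under a Gaussian fixed effect with
$\sigma_p = \sigma_e$, the classical mixed test — which is the exact F
test for this design — keeps the sign majority at every effect size we
measured; the resampling test's advantages should be sought where the
classical assumptions fail (non-normal deviations, its pluggable
`rdist`), not inside them.

## Hypothesis weighting and the discriminant

Significance outcomes of nested measure sets are turned into fractional
feature weights by posterior odds.  With prior $P[H_0] = c$ (default
0.5, no preference) and a common $P[B\,|\,H_1] = c_2$ across
alternatives, the likelihood ratio against the null is
$c_2(1-c)/(c\pi)$, and the ratio of two alternatives' likelihood ratios
leaves the weight $\pi_{anchor}/\pi_{other} \le 1$ for the less
significant one — the more significant (anchor) set enters at weight 1.
Because $c_2$ is only exactly common for small $\pi$, the default
applies the posterior-odds-consistent finite-$\pi$ correction
$(1-\pi_{other})/(1-\pi_{anchor})$: for the canonical pair
$(0.05, 0.10)$ the corrected weight is $0.4737$.  Weights below
`drop_threshold` (default 0.05, "falls close to zero") are set exactly
to 0, dropping the measure and reducing the feature-vector dimension.

`weighted_discriminant()` standardizes each retained measure across
subjects, multiplies by its weight (so a weight acts on comparable
scales — the ordering standardize-then-weight is a deliberate choice),
computes the two-class Fisher axis
$w = S_{pooled}^{-1}(m_2 - m_1)$, and classifies by the nearest group
mean on the axis.  Accuracy is resubstitution by default (optimistic by
roughly the feature-to-subject ratio); leave-one-out is available via
`method = "loo"`.  Zero-weight measures are removed before the axis is
computed, so they can never perturb the scores.

## Numerical choices

* Rank of $HE^{-1}$: eigenvalues below $10^{-10} c_1$ (or $10^{-12}$
  absolute if $c_1 = 0$) are discarded; eigenvalues are computed from
  the symmetric form $R^{-T} H R^{-1}$ with $E = R^T R$.
* Negative method-of-moments variance components are clamped to 0.
* Subset sizes use round-half-to-even; $p = 1$ is allowed but flagged
  as degenerate ($\sigma^2(F) = 0$).
* Monte Carlo p-values use the add-one rule, so they are never 0.
* The fixed factor 4 in every denominator of the family makes
  $E[R\,|\,\nu = 1] = 1/(2df_k) + 1/(2df_{ek})$; since all calibration
  is Monte Carlo, the constant affects reporting only.

## Problem sizes used in the checks

The shipped suite calibrates at the canonical design with 200
replicates for the `teststat1R` null mean, 500 univariate replicates
for $\hat\nu$, $L = 500$ plus 200 test replicates for the 5% type-I
check, 100 replicates per point of a four-point effect-size grid for
power monotonicity, and 100 scenario datasets against an $L = 2000$
null for the classical comparison — sizes chosen so Monte Carlo error
stays well inside the asserted bands while a full run remains a
desk-scale computation.
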