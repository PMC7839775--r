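---
title: "Methods: phylogenetic multilevel meta-analysis of signal adjustment to noise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic multilevel meta-analysis of signal adjustment to noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noisemeta)
```

## The problem and the model

Noise-exposure experiments report, per signal component and species, the
mean, SD and sample size of a control and a noise-exposed group. Species
are not independent (shared ancestry), effect sizes are not independent
(several per study, several per species), and group variances are rarely
equal. The package therefore models each standardized mean difference
$y_i$ with known sampling variance $v_i$ as

$$y_i = \mu + a_{species(i)} + b_{study(i)} + e_i + \varepsilon_i,$$

with $a \sim MVN(0, \sigma^2_{phylo} A)$ over species,
$b \sim N(0, \sigma^2_{study})$ over studies,
$e \sim N(0, \sigma^2_{es})$ per effect size, and
$\varepsilon_i \sim N(0, v_i)$ the known sampling error. $A$ is the
Brownian-motion correlation matrix of an ultrametric species tree. Exactly
three random strata are used; no additional tree-free species effect is
included, so inconsistency among species is attributed to the phylogenetic
stratum.

Assumptions worth keeping in mind: the two-group summaries are trustworthy
(no digitization error model), $v_i$ is treated as known although it is
estimated, trait changes are adequately summarized on the SMD scale, and
the Brownian-motion correlation is an adequate stand-in for how species
effects covary.

## Effect sizes

`smdh()` standardizes by the square root of the *average* of the two group
variances, which stays consistent when the groups have unequal population
variances, and applies the exact small-sample correction
$J(m) = \Gamma(m/2)/(\sqrt{m/2}\,\Gamma((m-1)/2))$, $m = n_c + n_n - 2$
(computed via `lgamma`, so it never overflows; the familiar
$1 - 3/(4m-1)$ approximation agrees to four decimals for $m \ge 20$). The
sampling variance is Bonett's large-sample form

$$v_i = \frac{y_i^2\left(\frac{sd_c^4}{n_c-1}+\frac{sd_n^4}{n_n-1}\right)}{8 s_p^4}
      + \frac{\frac{sd_c^2}{n_c-1}+\frac{sd_n^2}{n_n-1}}{s_p^2},$$

which the test suite calibrates against Monte-Carlo simulation (empirical
variance of $10^5$ simulated replicates within 10% of $v_i$ for
$n \ge 10$ per group) and against an independent reference implementation.
The sign convention is noise minus control: positive values mean the
component increased under noise. Dominant and peak frequency are pooled
into one `dominant_frequency` level, as both locate the frequency carrying
the most energy.

The parser accepts rows with a reported SE instead of an SD
(`sd = se * sqrt(n)`, flagged) and rows carrying precomputed `yi`/`vi`
(passed through verbatim, flagged); rows violating invariants are rejected
with row numbers, never silently dropped.

## Phylogeny

Trees arrive as newick topologies, usually without branch lengths. Grafen
heights — each internal node at (number of descendant tips − 1), rescaled
so the root sits at height 1 — turn any rooted topology into an
ultrametric tree (`grafen_tree()`, exponent `rho = 1` by default, the
conventional choice). `phylo_cor()` then sets entry $(i, j)$ to the depth
of the most recent common ancestor divided by the total depth; the
diagonal is exactly 1 and the matrix is positive semi-definite by
construction. Tip labels are matched to dataset species after normalizing
spaces/underscores and case; an ambiguous or missing match is an error
rather than a guess.

The packaged 31-species tree is a synthetic topology over synthetic
species labels. Any real analysis should supply its own resolved topology;
results for components with substantial phylogenetic variance are
sensitive to that choice, whereas components whose phylogenetic variance
is estimated at zero are insensitive to it.

## REML estimation: numerical choices

The restricted log-likelihood is optimized over log-variances, which keeps
the components non-negative and makes the surface better conditioned.
Choices that matter:

* **Starting points** (deterministic): the DerSimonian–Laird total excess
  variance is split equally across strata, concentrated 90% on each
  stratum in turn, and set near zero — ridge-prone surfaces with several
  local optima along boundaries are the motivation.
* **Optimizer**: bounded quasi-Newton (`L-BFGS-B`, log-variance bounds
  $[-30, \log(\max(100\,\hat\tau^2_{DL}, 100))]$, tight tolerances),
  followed by a derivative-free polish (golden-section for one stratum,
  Nelder–Mead otherwise) because quasi-Newton line searches can stall on
  boundary ridges. The reported optimum is the best across all starts, and
  the criterion stores every restart's value so monotonicity is testable.
* **Boundary projection**: a component whose optimum log-variance falls
  below $\log(10^{-8})$ is reported as exactly zero.
* **Degenerate designs**: a stratum observed at a single cluster level
  (e.g. a component contributed by one study) is confounded with the
  intercept under REML; its variance is fixed at zero and the fit carries
  a note. Collinear moderators are an error.
* **Inference**: fixed effects by GLS at the optimum; z (standard normal)
  quantiles for tests and CIs, matching how such analyses are
  conventionally reported. The criterion includes the
  $\tfrac12\log|X'X|$ constant, so values are comparable with the common
  REML likelihood convention.

The test suite pins the optimum against a brute-force grid search of the
restricted likelihood (log-spaced lattice with 20 refinement rounds,
agreement to $10^{-4}$ on $k \le 5$ datasets) and against an independent
multilevel REML implementation on larger simulated datasets.

## Magnitude, direction, folded normal

Direction analyses fit the signed effect sizes. Magnitude analyses fit
absolute values by default (`mode = "abs"`): the question "how much do
signals change" is answered on the folded scale of the data, and the
reported Wald summary stays internally consistent (z = estimate/SE).
Because the mean of folded values is not the folded mean, two further
modes are provided for sensitivity analysis: `"abs+fold"` additionally
reports the folded-normal transform of the estimate and CI bounds, and
`"fold-only"` fits the signed data and folds afterwards. For
$X \sim N(\mu, \sigma^2)$,

$$E|X| = \sigma\sqrt{2/\pi}\,e^{-\mu^2/2\sigma^2} + \mu\,(1 - 2\Phi(-\mu/\sigma)) \ge |\mu|,$$

verified against quadrature to $10^{-6}$. The folded correction vanishes
when $|\mu|/\sigma$ is large, so strongly significant magnitude fits are
unaffected by the choice of mode.

## Heterogeneity

Cochran's Q (weights $1/v_i$, deviations from the fixed-effect mean,
$\chi^2_{k-1}$ reference) tests whether effects vary more than sampling
error allows; it depends only on $(y_i, v_i)$. The multilevel I² uses the
typical sampling variance
$\bar{s}^2 = (k-1)\sum w_i / ((\sum w_i)^2 - \sum w_i^2)$ and attributes
$100\,\sigma^2_l/(\sum_l \sigma^2_l + \bar{s}^2)$ percent to each stratum;
the strata sum to the total by construction, the partition is invariant to
rescaling all variances, and the phylogenetic stratum enters as
$\sigma^2_{phylo}$ itself, without tree-dependent rescaling — consistent
with the additive multilevel formulation.

## Publication- and time-lag-bias diagnostics

`eggers_test()` follows the moderator formulation: the full random-effects
structure is kept and precision $1/\sqrt{v_i}$ enters as a moderator, the
intercept being tested at $\alpha = 0.1$. Note what that intercept is: the
fitted effect at *zero* precision. Under no small-study effect it equals
the pooled effect, so the test's null hypothesis is a zero-centered
funnel; applied to a dataset with a genuinely non-zero pooled effect the
intercept test responds to that effect as well. The calibration
simulations in the test suite therefore use zero-mean funnels (empirical
size within a binomial band of 0.1 at 500 replicates), and the classical
variant — SE as moderator, slope tested — which is invariant to the pooled
mean, is available via `moderator = "sei"`. Both are computed per signal
component, on magnitude and direction scales, and labelled.

`time_lag_test()` regresses magnitude (absolute) effect sizes on
mean-centered publication year (centering makes the intercept the effect
at the mean year and the fit invariant to shifting all years) and tests
the slope at $\alpha = 0.05$. `funnel_data()` exports residual-vs-precision
coordinates so funnels can be drawn without any plotting dependency.

## The synthetic-data generator

`sim_dataset()` mirrors the generative reading of the model: a random
rooted binary topology by sequential random joins with Grafen lengths,
species effects drawn $MVN(0, \sigma^2_{phylo} A)$, study effects nested
in species, effect-level deviations, and finally two-group samples of
$n$ subjects each, drawn so the population SMDH equals the latent
$\delta_i$ (both groups share the population SD). Group summaries are the
default output, so the SMDH stage is inside every tested loop; a fast mode
emits $(y_i, v_i)$ directly with the theoretical variance
$2/(n-1) + \delta_i^2/(4(n-1))$. A single RNG stream with a documented
draw order (species vector; per species: study count; per study: study
effect, effect count; per effect: component, year, deviation) makes the
generator a pure function of `(params, seed)`.

Defaults describe the reference study conditions used throughout the
tests: 30 species, 2 studies per species, 2 effect sizes per study, 20
subjects per group, $\mu = 0.5$,
$(\sigma^2_{phylo}, \sigma^2_{study}, \sigma^2_{es}) = (0.2, 0.1, 0.05)$,
control traits at mean 4, SD 1 in arbitrary signal units (the SMD scale
makes the baseline irrelevant), publication years 1998–2018.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: digitization and reporting error in the
group summaries, unequal group variances (real SMDH data motivate them),
non-normal trait distributions, correlated selection of which components a
study reports, real taxonomic structure, and publication censoring beyond
the simple suppress-the-weakest rule used in the bias power checks.

The packaged example dataset is such a synthetic draw arranged to match
the *structure* of a published noise meta-analysis (121 effect sizes, 23
studies, 31 species, with realistic per-component counts); its numbers are
simulated, so analyses of it illustrate the machinery, not the biology.

## Problem sizes used by the checks

Chosen to make the suite informative yet quick: $10^5$ Monte-Carlo
replicates for the $v_i$ calibration; grid-search oracle on $k = 5$
datasets; 200 replicate pipelines for parameter recovery at the reference
conditions; 500 simulated funnels for the Egger size check; 100–120
replicates for the smaller null simulations.

## Known limitations

* **CI coverage with few species.** At the reference conditions the 95%
  Wald-z interval for $\mu$ covers at roughly 0.83–0.90, not 0.95. With 30
  species the REML estimate of $\sigma^2_{phylo}$ frequently lands on or
  near the zero boundary; z-quantile intervals ignore that
  variance-component uncertainty, and the intervals are too short exactly
  in the replicates that underestimate it. Point estimation is fine (bias
  below 0.02 SMD); the interval undercoverage is a property of z-based
  inference in phylogenetic meta-analysis at this scale, and it is
  reported, not hidden, by the recovery suite.
* **Surrogate topologies.** Pooled estimates for components with large
  phylogenetic variance depend on the tree; without the original resolved
  topology they are only approximately reproducible.
* The folded-normal summary treats the estimate's SE as the relevant
  $\sigma$; it is a magnitude summary, not a posterior.
* No moderator meta-regression beyond the single columns the bias tests
  need, no robust (cluster) standard errors, no Bayesian fitting,
  no trim-and-fill or selection models.
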