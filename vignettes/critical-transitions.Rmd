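---
title: "Detecting critical transitions in sediment-core microbial communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting critical transitions in sediment-core microbial communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Lake sediments archive the DNA of past microbial communities in dated
layers. A taxon-by-sample count table from such a core, together with a
calibrated chronology, is a community *time series* spanning centuries.
`coreshift` asks three questions of such a series: did the community pass
through a critical transition (an abrupt shift between alternative stable
states); were there early-warning signs of the approaching tipping point;
and how did species interactions and local stability change through the
shift?

The package chains four analysis layers, each usable on its own:

1. **Tables** — reading/writing count tables and chronologies, rarefaction,
   taxonomic collapsing, selection of the modeled taxon set.
2. **Diversity and ordination** — alpha indices with Kruskal–Wallis state
   comparisons; Bray–Curtis distances, NMDS, ANOSIM, PERMANOVA,
   stratigraphically constrained zonation, and kernel-density bimodality of
   the community state axis.
3. **Transition detection** — exact dynamic-programming breakpoints on
   diversity series, sliding-window early-warning signals (variance and
   lag-1 autocorrelation), and an ARIMA forecast-deviation test.
4. **Dynamics** — the core model: stage-wise generalized Lotka–Volterra
   (gLV) inference with Tikhonov (ridge) regularization, Jacobian
   eigenvalue stability analysis, and classification of pairwise
   interactions.

## The gLV model and its linearization

Community dynamics are modeled as

$$\frac{dN_i}{dt} = N_i\Big(r_i - \sum_{j=1}^S a_{ij} N_j\Big),$$

where $N_i$ is the relative abundance of taxon (class-level group) $i$,
$r_i$ its intrinsic growth rate (per year), and $a_{ij}$ the strength with
which taxon $j$ inhibits taxon $i$ (positive $a_{ij}$ = inhibition,
negative = facilitation). Forward-differencing the log dynamics gives, for
each consecutive sample pair $k$,

$$\frac{\Delta \ln N_i(t_k)}{\Delta t_k} = r_i - \sum_j a_{ij}\,N_j(t_k),$$

a linear regression per taxon with coefficients $(r_i, a_{i1},\dots,a_{iS})$.
Key assumptions: the community sits near its (slowly moving) attractor so
that the linearization over one sampling interval is meaningful; sampling
intervals $\Delta t_k$ are taken from the calibrated chronology and need not
be equal; and measurement zeros are sampling artefacts, replaced before the
log by a pseudocount (default: half the smallest non-zero relative abundance
in the window — the data decide the scale, not a fixed constant).

### Ridge fit and cross-validation

Each taxon's regression is solved by ridge (Tikhonov) regression with the
intercept $r_i$ unpenalized,
$\hat\beta = (X^\top X + \lambda D)^{-1} X^\top y$, with $\lambda$ chosen
per taxon over a grid of 25 log-spaced values in $[10^{-4}, 10^2]$ to
minimize the mean out-of-fold squared error of a k-fold cross-validation
(default $k = 5$). Folds are *contiguous blocks* of equations, respecting
the serial dependence of a time series; fold assignment is therefore
deterministic. A `global_lambda` mode tunes one penalty for all taxa
instead. The per-taxon default exists because abundant, well-observed taxa
support weaker shrinkage than rare ones.

With a 10-sample stage window there are 9 equations and $S+1$ unknowns per
taxon: for the default 12-taxon community the system is underdetermined,
which is exactly why the regularization is not optional.

### Stages, equilibria and stability

`stage_analysis()` slides a window of `w = 10` samples with step `s = 5`
(35 samples → 7 stages, the trailing stage truncated to 5 samples but never
shorter than `s`). Per stage it fits the gLV model, computes an equilibrium,
the Jacobian
$J_{ik} = \delta_{ik}(r_i - \sum_j a_{ij}N_j) - N_i a_{ik}$
(at an interior equilibrium $J = -\mathrm{diag}(N^*)A$), its full eigenvalue
spectrum, the mean of the real parts (the "centroid", the mean stability
level), and the stability verdict (all real parts negative).

The equilibrium $A N^* = r$ deserves care. `steady_state()` defaults to a
strict solve that refuses matrices with condition number above `1e8`,
reporting the number. But a stage window of $w$ samples yields only $w-1$
equations per taxon, so the fitted $A$ of a community richer than $w-1$
taxa is *structurally* rank-deficient — no inverse exists, and a
machine-precision pseudoinverse amplifies noise directions into absurd
equilibria. `stage_analysis()` therefore uses a truncated singular-value
pseudoinverse (`method = "pinv"`): directions of $A$ whose singular value is
below 1% of the dominant one are treated as unresolved by the regression
and excluded rather than inverted. The 1% threshold mirrors the resolution
actually achievable from a handful of noisy equations; it is exposed as the
`tol` argument. An `equilibrium = "observed"` mode instead linearizes at
the window's mean composition (the empirical quasi-steady state); it is the
most robust choice but, because the eigenvalue centroid then equals
$\mathrm{tr}(J)/S$ at the observed state, compositional closure makes it
nearly blind to transition signals. Feasibility (all $N^*_i > 0$) is always
reported but never gates the analysis: fitted stage equilibria of noisy
compositional data are routinely mixed-sign.

### Interaction typing

Pairs are classified on growth *effects* $e_{ij} = -a_{ij}$ (the effect of
$j$ on $i$; positive = activation): mutualism (+/+), antagonism (−/−),
exploitation (+/−). Classifying on raw coefficients would invert the
ecological reading, since $a_{ij}$ measures inhibition; a
`on = "coefficients"` switch retains the literal convention. Exact-zero
effects are flagged null and excluded from the type proportions. Per-type
strength is the mean absolute effect — a signed mean would let large
opposing pairs cancel.

## Ordination and zonation choices

* **NMDS**: Kruskal stress-1 via `vegan::monoMDS`, $k = 2$, 20 seeded random
  restarts. Axis signs are arbitrary, so NMDS1 (the community state
  variable) is flipped to correlate non-negatively with sample age.
* **ANOSIM/PERMANOVA**: permutation p-values use the $(b+1)/(m+1)$
  estimator, so $p = 0.001$ is the floor at 999 permutations. Note that the
  floor is attainable only when the groups are large enough that no random
  permutation recreates the separating partition (with two groups of five,
  $2/\binom{10}{5} \approx 0.8\%$ of permutations do).
* **Zonation**: agglomerative clustering restricted to stratigraphically
  adjacent clusters, with dispersion computed from squared Bray–Curtis
  dissimilarities ($\sum_{i<j} d^2_{ij}/|C|$, the incremental-sum-of-squares
  analogue; with Euclidean input it reduces to the classical criterion).
  The *two-state* cut is computed exactly, by minimizing total dispersion
  over all $n-1$ contiguous splits, rather than read off the greedy tree.
* **KDE bimodality**: Gaussian kernel, Silverman's bandwidth, 512-point grid
  spanning the range ± 3 bandwidths; modes are strict local maxima of the
  gridded density.

## Transition detection choices

* **Breakpoints**: piecewise-constant-mean segmentation by exact dynamic
  programming (equal to exhaustive enumeration), with the number of breaks
  chosen by BIC ($n\log(\mathrm{RSS}/n) + (2m+2)\log n$; the RSS is floored
  at $10^{-12}(\sum x^2 + 1)$ so noiseless data do not produce
  $\log 0$). Minimum segment length defaults to
  $\max(3, \lceil 0.15\,n\rceil)$, the conventional 15% trimming.
* **EWS**: right-aligned windows of 5 samples; variance with denominator
  $n-1$; lag-1 autocorrelation as the Pearson correlation of the window
  with its one-step shift, recorded as 0 with a degeneracy flag for
  zero-variance windows. Signals are computed on raw NMDS1 without
  detrending. Trend significance over the declared pre-transition range
  uses Kendall's tau with the normal approximation — rank-based, hence
  insensitive to the unknown scale of the indicators.
* **ARIMA**: order fixed at (1,1,0) by default, with an optional AIC search
  over $p,q \le 2$, $d \le 1$. For $d \ge 1$ a drift regressor is included,
  so a trending state-1 segment is projected along its trend; a series
  whose $d$-th difference is exactly constant is deterministic and is
  continued polynomially with zero innovation variance instead of being
  forced through a singular likelihood. Prediction intervals are
  normal-theory, widening with horizon; the deviation verdict is an
  outside-band fraction above $1-\mathrm{level}$.

## The synthetic scenario: what it emulates, and what it does not

`transition_scenario()` generates the study-shaped data every test runs on:
35 stratigraphically ordered samples spanning 1200–2010 CE, 12 class-level
taxa over a ~20% "unclassified" background, sequenced by multinomial draws
at 20,000 reads per sample.

The dynamics are two guilds of six taxa with self-limitation 0.75,
within-guild competition 0.03, and between-guild competition 0.22 (all
jittered ±15% per seed), which makes the guild-level system bistable. The
environmental driver ramps the resident guild's growth rates from 0.30 down
to 0.02 yr⁻¹ while the challenger's rise from 0.10 to 0.55 yr⁻¹ — growth
rates on the order of 0.1–0.5 yr⁻¹ are effective rates appropriate to
decadally resolved sediment communities. As the resident equilibrium
deteriorates, its dominant eigenvalue rises towards zero; when the
challenger's invasion rate crosses zero the community flips abruptly to the
challenger-dominated regime. The realized transition (first time the
challenger guild out-masses the resident) lands around 1700–1760 CE at the
default noise level (multiplicative log-normal environmental noise,
$\sigma = 0.03\,\mathrm{yr}^{-1/2}$, applied per integration step of 0.5
yr). The ground truth — transition time, stability-threshold time, regime
labels, true parameters — is stored beside the emitted counts, and a
`transition = FALSE` switch produces a matched stationary single-regime
record.

What the generator deliberately does *not* emulate: DNA degradation and
taphonomy; uneven deposition rates (ages are equally spaced); taxonomic
richness beyond the modeled guilds (real cores have hundreds of classes);
and recovery of alpha diversity after the shift (the two guilds are
symmetric, so richness is nearly conserved across the flip). Passing tests
on this scenario therefore demonstrate that the *methods* behave as
designed on data of the study's shape — not that any particular real core
contains a transition.

Two limitations found while validating deserve emphasis:

* **Sequencing depth hides precursors.** Before the flip the challenger
  guild sits far below one read in 20,000, so count-based state variables
  (NMDS1 of the table) cannot show the critical slowing down carried by the
  rare invader; the early-warning tests therefore run on the latent
  resident-guild state series (`scenario_state_series()`), where rising
  variance and autocorrelation are genuine consequences of the slowing
  resident dynamics. On real data this corresponds to the usual caveat that
  EWS need an observable coupled to the slow mode.
* **Quiet windows are nearly uninformative.** Within a quasi-stationary
  10-sample stage the composition barely moves, so the fitted interaction
  matrix is noise-dominated and the stage's eigenvalue centroid hovers near
  zero with an essentially random sign. The discriminating signal is
  *relative*: stages containing the transition show clearly positive
  centroids, quiet stages do not. Tests assert that comparative pattern,
  not per-stage sign correctness.

## Numerical and reproducibility choices

* All randomness is seeded through function arguments; `withr::with_seed`
  restores the caller's RNG state. The pipeline takes one master seed and
  derives per-module seeds deterministically, and reruns with identical
  configuration are byte-identical (provenance headers carry the package
  version and seed, never a timestamp).
* The gLV integrator is classical fixed-step RK4, one step per grid
  interval, with abundances floored at $10^{-12}$ and a blow-up guard at
  $10^6$. Environmental noise is multiplicative log-normal with
  $\sqrt{\Delta t}$ (diffusion) scaling, so halving the step does not
  change the accumulated noise variance.
* Rarefaction is sampling without replacement (multivariate
  hypergeometric), the variance-correct reading of "rarefied to the
  minimum read count".
* "Simpson" is the Gini–Simpson index $1-\sum p^2$ (bounded in [0,1];
  an inverse-Simpson switch is provided). Richness is observed taxa on
  rarefied counts.
* Taxonomy strings are rank-prefixed and semicolon-delimited
  (`k__;p__;c__;…`); other dialects are handled by a declared rank index.
  The modeled set defaults to mean relative abundance ≥ 1%, capped at the
  12 most abundant, with the pooled "unclassified" remainder excluded from
  dynamics.

## Worked example

```{r example}
library(coreshift)

dir <- tempfile()
paths <- simulate_scenario_files(dir, seed = 1)
cfg <- pipeline_config(input = paths[["table"]],
                       chronology = paths[["chronology"]],
                       out_dir = file.path(dir, "out"), seed = 1)
res <- run_pipeline(cfg)
res                         # states, ANOSIM, KDE modes, stage centroids
summary(res$stages)         # per-stage gLV fit, stability, interactions
plot(res$stages)            # eigenvalue-centroid trajectory
```

The per-stage gLV machinery is equally usable on its own: `glv()` is a
standard fitting function returning an object with `coef()`, `predict()`,
`residuals()`, `simulate()` and `summary()` methods, and
`steady_state()` / `stability()` / `classify_interactions()` consume its
fits.
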