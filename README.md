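# coreshift

Critical-transition analysis of dated microbial community time series from
sediment cores.

Sedimentary DNA turns a lake core into a community time series: a
taxon-by-sample count table whose samples are dated layers spanning
centuries. `coreshift` is for paleoecologists and microbial ecologists who
want to ask of such a series whether the community passed through a
**critical transition** — an abrupt, nonlinear shift between alternative
stable states — and what the dynamics around the tipping point looked like.

The package covers the full chain:

* **Community tables** — TSV/BIOM readers and writers with calibrated
  chronologies, rarefaction (without replacement), taxonomic collapsing,
  and selection of the modeled taxon set.
* **Diversity & ordination** — richness / Shannon / Gini–Simpson with
  Kruskal–Wallis state comparisons; Bray–Curtis dissimilarity, NMDS,
  ANOSIM, PERMANOVA (999 permutations), stratigraphically constrained
  (CONISS-style) zonation, and Gaussian-KDE bimodality of the community
  state axis.
* **Transition detection** — exact dynamic-programming breakpoint
  segmentation of diversity series (BIC-selected), sliding-window
  early-warning signals (variance and lag-1 autocorrelation, window 5,
  Kendall trend tests), and ARIMA(1,1,0) forecast-deviation tests between
  states.
* **Dynamics (the core model)** — stage-wise generalized Lotka–Volterra
  inference, local stability analysis, and interaction typing.
* **Synthetic data** — a ground-truth two-regime scenario generator so the
  whole pipeline is testable end to end without external data.

## The model

Community dynamics are modeled by the generalized Lotka–Volterra (gLV)
system

$$\frac{dN_i}{dt} = N_i\Big(r_i - \sum_{j=1}^{S} a_{ij} N_j\Big),$$

with $N_i$ the relative abundance of taxon $i$, $r_i$ its intrinsic growth
rate and $a_{ij}$ the inhibition of taxon $i$ by taxon $j$. Forward
differences of log abundances linearize this to a regression per taxon,

$$\frac{\Delta \ln N_i(t_k)}{\Delta t_k} = r_i - \sum_j a_{ij} N_j(t_k),$$

solved by Tikhonov (ridge) regression with k-fold cross-validated penalty —
necessary because a 10-sample stage window gives only 9 equations for
$S + 1$ unknowns per taxon. From the fitted $(r, A)$ the package derives
the steady state $A N^* = r$, the Jacobian (at an interior equilibrium,
$J = -\mathrm{diag}(N^*)A$), its eigenvalue spectrum, the mean real part
("centroid") as the stage's stability level, and the classification of
every taxon pair into mutualism (+/+), antagonism (−/−) or exploitation
(+/−) on growth effects $e_{ij} = -a_{ij}$.

Sliding a 10-sample window with step 5 over a 35-sample core yields 7
stages, giving trajectories of stability and interaction strength across
the transition.

## Worked example

Everything below is reproducible — the data are generated by the package's
own scenario generator with a fixed seed.

```r
library(coreshift)

dir <- tempfile()
paths <- simulate_scenario_files(dir, seed = 1)   # 35 samples, 12 classes + background
cfg <- pipeline_config(input = paths[["table"]],
                       chronology = paths[["chronology"]],
                       out_dir = file.path(dir, "out"), seed = 1)
res <- run_pipeline(cfg)
res
#> pipeline result: 35 samples, 2 states, 7 stages
#>   ANOSIM R = 1.000 (p = 0.001); KDE modes = 2
#>   stage centroids: -0.00281 -0.000788 -0.000435 0.0233 0.0164 0.000224 -0.000235
```

Reading the output: the constrained zonation splits the record into **2
states** whose compositions are completely separated (ANOSIM statistic
R = 1, the permutation floor p = 0.001 at 999 permutations), and the NMDS1
state axis is **bimodal** (2 KDE modes) — the signature of two alternative
states. The stage-wise eigenvalue centroids (units yr⁻¹) are near zero in
the quiet stages and clearly positive in stages 4–5, the windows that
contain the simulated regime flip (~1750 CE in this realization): the
community is at its least stable exactly where the transition happens.

```r
summary(res$stages)   # per-stage fit, stability, interaction proportions
#>  stage start end age_from age_to S_used centroid_re stable feasible
#>      1     1  10     1200   1414     12  -0.0028065  FALSE    FALSE
#>      2     6  15     1319   1534      6  -0.0007876  FALSE    FALSE
#>      3    11  20     1438   1653      6  -0.0004345  FALSE    FALSE
#>      4    16  25     1557   1772     12   0.0233266  FALSE    FALSE
#>      5    21  30     1676   1891     12   0.0164432  FALSE    FALSE
#>      6    26  35     1796   2010      6   0.0002241  FALSE    FALSE
#>      7    31  35     1915   2010      6  -0.0002348  FALSE    FALSE
```

(S_used drops to 6 in windows where one guild is absent from the counts;
`stable`/`feasible` are the strict all-eigenvalues / all-positive flags,
which noisy compositional fits rarely attain — the centroid trajectory is
the interpretable quantity.)

The fitting function is also usable directly, in the classic R modelling
idiom:

```r
ex <- recovery_experiment(seed = 1)            # known ground-truth (r, A)
fit <- glv(ex$observed, ages = ex$ages, episodes = ex$episodes)
coef(fit)                                      # r and A per taxon
stability(fit, method = "pinv")                # equilibrium + spectrum
classify_interactions(fit)                     # +/+, -/-, +/- typing
```

See `vignettes/critical-transitions.Rmd` for the model assumptions, every
tunable parameter, and the design decisions behind the defaults.

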