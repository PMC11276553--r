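---
title: "Causalized convergent cross mapping: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causalized convergent cross mapping: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cccm)
```

## The method

Convergent cross mapping (CCM) detects causal coupling between two time
series $X_n = [X_1, \dots, X_n]$ and $Y_n$ through state-space
reconstruction. Each observable is delay-embedded into its *shadow
manifold*

$$M_X = \{\,x_t = [X_t, X_{t-\tau}, \dots, X_{t-(E-1)\tau}]\,\},$$

with embedding dimension $E$ and lag $\tau$. If $X$ and $Y$ are coupled
through a shared attractor, states that are close on $M_X$ correspond to
times at which $Y$ also takes similar values. CCM therefore reconstructs
$Y_t$ from the $E+1$ nearest neighbors of $x_t$,

$$\hat Y_t \mid M_X = \sum_{i=1}^{E+1} w_i\, Y_{t_i}, \qquad
  w_i = \frac{u_i}{\sum_j u_j}, \qquad
  u_i = \exp\!\left\{-\frac{d(x_t, x_{t_i})}{d(x_t, x_{t_1})}\right\},$$

and reads the Pearson correlation $\rho(Y, \hat Y)$ over the predicted
range as the cross-map skill of the direction $X \to Y$. Skill that grows
with the library length (`convergence_curve()`) is the operational
signature of coupling.

Classic CCM searches the whole library, so the present is reconstructed
partly from the *future* — at odds with the usual premise of causality that
the future cannot influence the past. The **causalized** variant (cCCM)
restricts the neighbor search to indices $t_i < t$; `cross_map()` does this
in its default `mode = "cccm"`, and the earliest predictable time becomes
$(E-1)\tau + E + 1$ (0-based), the first time with $E+1$ strictly-past
manifold states.

For jointly Gaussian stationary ergodic processes, cCCM skill maps onto the
average directed information per sample,

$$\bar I(X \to Y) \approx -\tfrac12 \log_2\!\left(1 - \rho^2_{\mathrm{cCCM}}(X \to Y)\right)
  \quad \text{bits/sample},$$

exposed as `di_from_rho()`. Base-2 logarithms are used so that the unit is
bits; a natural log would change the unit, not the substance.

When the reconstruction can be modeled as the truth plus independent
zero-mean error of variance $\sigma_e^2$, the attainable skill is

$$\rho(Y, \hat Y) = \frac{\sigma_Y}{\sqrt{\sigma_Y^2 + \sigma_e^2}},$$

available as `rho_under_error()`. This closed form explains the monotone
decay of skill with decreasing SNR seen in the noise sweeps.

### Multivariate conditional cCCM

For a set $\Omega = \{X_1, \dots, X_L\}$, the influence of $X_j$ on $X_i$
conditioned on the remaining variables is quantified by the **causality
ratio**

$$\mathrm{cCCM}(X_j \to X_i \mid \Omega \setminus \{X_i, X_j\}) =
  \frac{\mathrm{Var}(e_i \mid \Omega \setminus \{X_j\}) -
        \mathrm{Var}(e_i \mid \Omega)}
       {\mathrm{Var}(e_i \mid \Omega \setminus \{X_j\})},$$

where $e_i \mid S$ is the error of reconstructing $X_i$ by past-only cross
mapping from the *joint* shadow manifold of the predictor set $S$
(`joint_embed()`, `conditional_error_variance()`, `conditional_cccm()`).
A pair with high bivariate skill but a near-zero conditional ratio given a
third variable is the signature of a common driver rather than a direct
link.

### Granger causality

For comparison, `granger_bivariate()` implements the classic two-model
log-ratio $\mathrm{GC}(X \to Y) = \ln(\mathrm{Var}(e)/\mathrm{Var}(\tilde e))$
from ordinary least squares with strictly-past lags and no intercept
(both overridable). Because no regressor carries the lag-0 term, GC is
blind to instantaneous coupling by construction, while cCCM — whose delay
vector starts at $X_t$ itself — is not. The benchmark system with a
dominant instantaneous tap reproduces exactly this divergence: cross-map
skill above 0.9 with a GC log-ratio orders of magnitude smaller.

## Parameters and how to choose them

* **`E` (embedding dimension, default 5 in the pipeline helpers).** By the
  Takens/Whitney argument $E = 2d + 1$ suffices for an attractor of
  dimension $d$, and often less. For systems with memory the practical
  rule is different and sharper: the span must exceed the largest dominant
  delay ($E\,\tau > d_{d,\max}$) *and* the delay vector
  $[X_t, X_{t-\tau}, \dots]$ must hit every dominant tap. The three-tap
  benchmark (taps at lags 1, 4, 5) shows both sides: $E=5, \tau=1$ misses
  the lag-5 tap and plateaus near 0.81, $E=6, \tau=1$ spans all taps and
  reaches ~0.95. Oversized $E$ is also harmful — neighbor density decays
  with dimension, and skill degrades again (the `pairwise_matrix()` logger
  warns when $E\,\tau > n/10$).
* **`tau` (lag, default 1).** For over-sampled signals a larger `tau`
  lengthens the span without raising the dimension and markedly improves
  noise immunity: on the sinusoid benchmark at 15 dB SNR, $E=5, \tau=5$
  is within 0.06 of its noise-free skill while $E=5, \tau=1$ is not.
  No automatic $E/\tau$ selector is provided: the quantities that would
  drive one (attractor dimension, dominant delays) are exactly what is
  unknown in practice, so they are exposed as user parameters instead.
* **`k` (neighbors).** Always $E + 1$ in the bivariate search (one more
  than the simplex dimension). For the joint multivariate search the
  neighbor count is again $E + 1$ by default, *not* scaled with the number
  of predictor blocks: scaling $k$ with the joint dimension makes the
  with-source and without-source reconstructions structurally different
  estimators, and in the confounded-trio benchmark it biases the ratio
  strongly negative. Holding $k$ fixed keeps the two error variances
  comparable; `conditional_error_variance()` accepts any `k` for
  sensitivity analysis.
* **`theiler` (temporal exclusion radius, default 0).** Neighbors
  temporally adjacent to the query are admitted by default; a positive
  radius excludes them. The benchmarks neither need nor use it.
* **`snr_db`.** SNR is defined on the mean-square power of the noise-free
  signal, so deterministic offsets count as signal; the generators draw
  noise with variance $P / 10^{\mathrm{SNR}/10}$. Across the noise sweeps,
  skill rises monotonically with SNR and is within 0.1 of the noise-free
  value from 15 dB up — the practical reliability threshold.
* **Granger orders `K`, `L` (default 5).** Chosen to match the recurring
  $E = 5$ embedding span. The GC log-ratio's *scale* depends on the
  orders: with short orders the restricted autoregression cannot proxy the
  source's past and the ratio stays visibly above the overfitting floor
  $\sim K/n$ even for instantaneous-only coupling. Conclusions should rest
  on the cCCM-vs-GC contrast and on the direction asymmetry, not on GC
  magnitudes.

## Numerical choices

* **Index convention.** 0-based sample indices everywhere; the first
  admissible leading time of a manifold is $(E-1)\tau$.
* **Ties.** Equidistant neighbors are ordered by smaller time index, so
  results are bit-reproducible across platforms.
* **Zero nearest distance.** The weight formula degenerates ($u_i = 0/0$)
  when $d(x_t, x_{t_1}) = 0$; the implemented limit splits the weight
  uniformly over all zero-distance neighbors and gives the rest zero. This
  rule is what makes the data-repetition artifact exact: concatenated
  copies plant zero-distance recurrences whose targets match perfectly.
* **Skill and error are computed over the valid range only** (times that
  actually have predictions); padding undefined predictions into the
  correlation would be meaningless. Negative correlations are reported
  as-is, never clamped.
* **Standardization** (`standardize_series()`) uses the population
  variance (divisor $n$) and is applied per series before *joint*
  embedding only, where raw variances can differ by orders of magnitude
  and would otherwise dominate the Euclidean metric. The causality ratio
  is variance-normalized, so the result is insensitive to this convention,
  and both variances entering a ratio are computed over the intersection
  of the valid prediction ranges.
* **Self-matches.** In classic-CCM mode the query point itself (a
  distance-0 self-match) is excluded from its neighborhood; admitting it
  would make every reconstruction trivially perfect. The past-only mode
  excludes it by construction.
* **Degenerate inputs** fail loudly: constant series cannot be
  standardized or serve as cross-map targets, too-short series report the
  minimum length, insufficient past neighbors report the earliest
  admissible query time, rank-deficient GC designs raise a singular-fit
  error, and a conditioning set that already explains the target perfectly
  (zero error variance) is rejected rather than divided by.

## What the generators emulate — and what they do not

`simulate_system()` reproduces the benchmark suite exactly as specified:
coupled logistic maps iterated with the printed arithmetic grouping and
initial conditions; AR(1) pairs with $N(0, 0.05^2)$ innovations from
$X(0)=Y(0)=1.5$; tone-in-noise processes on their printed time grids;
FIR systems driven by white noise with zero pre-history; independent
pairs for the repetition artifact; and the confounded trio
$X = 0.7X_0 + 10Z$, $Y = 0.4Y_0 + 12Z$. Generator defaults *are* the
benchmark conditions (lengths 1000–2048, the printed coefficients and
grids); where a benchmark leaves a knob open it is an explicit parameter.
The sinusoid grid step differs between two benchmark variants (0.01 vs
$0.01\pi$), so the step is a parameter and each use states its own.

Two deliberate departures from literal "random" reproduction: draws use
R's RNG, so stochastic benchmark values are matched *in distribution*
(multi-seed means with the printed value inside the seed spread), never
draw-for-draw; and the sign function maps 0 to 0 for determinism.

The suite does **not** emulate experimental neuroimaging data: no
hemodynamic response, physiological noise, inter-subject variability or
scanner artifacts. The pipeline entry points (`read_series_csv()`,
spline upsampling by a factor of 2 before analysis, `pairwise_matrix()`,
`conditional_matrix()`, subject-level `average_matrices()`) mirror the
shape of such an analysis on any multichannel CSV, but passing the
synthetic suite demonstrates correctness of the estimators, not
performance on BOLD signals.

## Problem sizes

All validation runs are desk-scale by design: the neighbor search is
$O(n^2)$ per direction, and a single direction at $n = 2048$ takes well
under a second. The test and acceptance runs use the benchmark lengths
themselves ($n$ = 201–3000) with 20 seeds for stochastic means, 10 for
orderings and sweeps, and 5 for auxiliary contrasts — enough that the
multi-seed standard error is an order of magnitude below every tolerance
band used.

## Known limitations

* $O(n^2)$ memory and time in the series length (a full distance matrix is
  materialized); fine to $n \sim 10^4$, not intended for long recordings.
* The conditional causality ratio is a *relative variance reduction*; an
  irrelevant source can produce a strongly negative ratio (its coordinate
  block dilutes the joint neighbor search), which should be read as "no
  positive causal contribution", not as a meaningful magnitude.
* No surrogate-data significance test for $\rho$ is provided, and no
  sliding-window (time-varying) analysis.
* Sampling below the Nyquist rate of the underlying signals invalidates
  the analysis — in the extreme case an aliased tone collapses to a
  constant and is rejected, but moderate undersampling simply yields
  untrustworthy skills that the package cannot flag.
* Direction labels follow the cross-map definition ($\rho(X \to Y)$
  reconstructs $Y$ from $M_X$); which generative direction produces the
  larger value depends on the system, so matrices should always be read
  with their "rows = source" orientation note.
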