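---
title: "Latency structure of resting-state BOLD: models, estimators and design choices"
author: "latstruct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latency structure of resting-state BOLD: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latstruct)
```

## What this package estimates

Spontaneous BOLD fluctuations do not rise and fall simultaneously across the
brain: activity propagates, and the pairwise temporal offsets at which two
regions' signals are maximally cross-covariant form a reproducible *latency
structure*. `latstruct` implements that analysis chain end to end:

1. **Time-delay matrix.** For regions $i, j$ the lagged cross-covariance
   $C_{x_i x_j}(\tau) = \tfrac{1}{T}\int x_i(t+\tau)\,x_j(t)\,dt$ is evaluated
   on the TR grid within a latency threshold (5 s by default, with 3 s and
   1.5 s as sensitivity settings); the extremizing lag, refined by
   three-point parabolic interpolation, fills the antisymmetric matrix
   $\tau_{ij}$.
2. **Latency eigenvectors.** PCA of the column-centered delay matrix (or,
   alternatively, a diffusion-map embedding) yields a few per-region maps
   summarizing dominant propagation modes; individuals are matched to a
   group template by orthogonal Procrustes alignment, with a chained
   (two-stage) variant for matching one dataset's template to another's.
3. **Biophysical interpretation.** A two-population (excitatory/inhibitory)
   neural-mass model with per-region feedback inhibition control, driven on a
   structural connectome with myelin- and gradient-informed parameter
   surfaces, generates synthetic gating trajectories and — through a
   Balloon–Windkessel forward model — BOLD, letting latency maps be related
   to recurrent connection strengths and the E/I ratio.
4. **Temporal and spatial context.** Per-region intrinsic neural timescales
   (INT) come from an offset-exponential fit
   $R(k\Delta) = A e^{-k\Delta/T} + B$ to the autocorrelation function;
   functional-connectivity gradients come from Fisher-z FC, a sparsified
   cosine-similarity affinity and diffusion-map embedding.
5. **Inference.** Map associations use spherical spin permutation tests;
   group contrasts use per-region Hotelling $T^2$ with label permutation;
   multiple comparisons use Benjamini–Hochberg FDR; INT prediction from
   eigenvectors uses five-fold cross-validated OLS.

Real cohort data of this kind are access-gated, so the package ships
generators with *known ground truth* for every stage, and its tests are
recovery and calibration properties on those generators.

## Sign and orientation conventions

The covariance curve returned by `lagged_cross_covariance(x, y, ...)` at lag
$+k\,\mathrm{TR}$ pairs $x(t + k\,\mathrm{TR})$ with $y(t)$; if $x$ leads $y$
by $d$ seconds the curve therefore peaks at $-d$. `time_delay_matrix()`
negates the extremizing lag so that $\tau_{ij} > 0$ always means *region $i$
leads region $j$*. The synthetic generator uses the same orientation: a
larger lag-projection value $l_i$ means an earlier (leading) region, and the
realized pairwise lag is $l_i - l_j$. PCA component signs are intrinsically
arbitrary; each component's largest-magnitude loading is made positive, and
individual maps inherit their orientation from Procrustes alignment to the
template.

Because the extremum search runs on the correlation-normalized curve while
the stored peak magnitude comes from the covariance curve, anticorrelated
pairs are handled by taking the extremum of the absolute curve: a trough
selects the lag and is flagged `"trough"`. Grid ties break toward the
smaller absolute lag; an extremum on the search boundary cannot be
interpolated and is flagged `"clipped"`.

## Parameters that matter

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `tr_seconds` | data-defined | s | all lags are multiples of it before interpolation |
| `latency_threshold_seconds` | 5 | s | lag search bound; 3 and 1.5 as sensitivity settings |
| `n_components` | 3 | – | retained eigenvectors/gradients |
| `sparsity_keep_fraction` | 0.10 | – | per-row survivors of the FC matrix |
| `alpha` (embedding) | 0.5 | – | density normalization of the diffusion kernel |
| `diffusion_time` | 0 | – | 0 selects the $\lambda/(1-\lambda)$ scaling |
| `n_permutations` | 1000 | – | spin and label permutations |
| INT cap | 5 | s | lag range entering the autocorrelation fit |
| FIC target rate | 3 | Hz | low single-digit regime of the model family |
| integration `dt` | 5e-4 | s | Euler–Maruyama step |

The threshold is applied as a *search bound* (`max_lag`), with a post-hoc
clipping mode available (`search_bound = FALSE`) since either reading of "a
threshold was applied" is defensible. The INT section's 5 s figure is read
as a cap on the lag range entering the fit, mirroring the latency threshold;
this is an interpretation, and the cap is a plain argument.

## The biophysical model

Per region $j$, the excitatory current sums baseline drive $w_E I_0$, local
recurrence $W_{EE}\,J\,S_E$, long-range input $G\,J \sum_k C_{jk} S_{E,k}$
and feedback inhibition $-W_{IE} S_I$; the inhibitory current sums
$w_I I_0 + W_{EI} J S_E - W_{II} S_I$. Currents map to rates through
$r = (aI - b)/(1 - e^{-d(aI-b)})$ (the removable singularity at $aI = b$ is
evaluated by its limit $1/d$), and rates drive first-order gating kinetics
with per-region additive noise $\sigma_j$. The spatially heterogeneous
parameters are linear in two standardized surrogate maps:
$W_{EE,j} = a + b\,\mathrm{myelin}_j + c\,\mathrm{grad}_j$, and analogously
for $W_{EI,j}$ and $\sigma_j$; assembled values must be strictly positive.
The kinetic and transfer constants (310/125/0.16 and 615/177/0.087 for E/I,
$\tau_E = 0.1$ s, $\tau_I = 0.01$ s, $\gamma = 0.641$, $J = 0.15$ nA,
$I_0 = 0.382$ nA, $w_E = 1$, $w_I = 0.7$) and the hemodynamic constants
($\kappa = 0.65$, $\gamma_h = 0.41$, $\tau_h = 0.98$ s, $\alpha = 0.32$,
$\rho = 0.34$, $V_0 = 0.02$) follow the dynamic mean-field and
Balloon–Windkessel literature this model family derives from; all live in
`pfic_constants()` and are overridable.

**Feedback-inhibition calibration.** Because the target excitatory rate is
uniform, the noise-free fixed point is solvable in closed form rather than
by damped iteration: invert the transfer function once for $I_E^\*$, get
$S_E^\* = \gamma r \tau_E / (1 + \gamma r \tau_E)$, solve one scalar root
per region for $S_I^\*$, and read off
$W_{IE,j} = (w_E I_0 + W_{EE,j} J S_E^\* + G J \sum_k C_{jk} S_E^\* -
I_E^\*) / S_{I,j}^\*$. The solution is exact (tests verify the simulated
noise-free network settles on the target rate to machine precision) and
negative solutions are reported as infeasibility per region.

Integration is Euler–Maruyama at $dt = 0.5$ ms with gating clipped to
$[0,1]$ (a reflecting wall for the additive noise); hemodynamics integrate
at the same step by explicit Euler. Step-halving changes the deterministic
terminal state by far less than $10^{-4}$ relative in the shipped tests.
Empirical fitting of the nine surface coefficients to real FC is out of
scope; `assemble_parameters()` takes them as inputs.

## What the generators emulate — and what they do not

* `make_propagating_bold()` realizes a shared infra-slow signal (white noise
  band-passed to 0.01–0.1 Hz, the regime in which BOLD latency is
  physiologically meaningful) on a 10x-oversampled grid, shifts it per
  region (so sub-TR ground-truth lags exist exactly), decimates, and adds
  white noise at a specified shared-to-noise variance ratio. It does *not*
  emulate head motion, physiological nuisance, hemodynamic variability
  across regions, or multi-path propagation — so lag-recovery results bound
  estimator error, not preprocessing robustness.
* `make_ar1()` gives the exact analytic INT oracle $T = -\Delta/\ln\phi$.
* `make_modular_timeseries()` builds block-correlated signals from shared
  factors with analytically chosen weights; gradient block-separation is
  then checkable by spectral reasoning.
* `make_toy_connectome()` produces a distance-decaying, symmetric, connected
  structural matrix and smooth standardized myelin/gradient *surrogates* on
  a Fibonacci sphere — synthetic stand-ins, not empirical maps.
* `make_region_table()` gives each hemisphere its own full sphere of parcel
  centroids (the per-hemisphere spherical-registration convention), which
  matters for spin tests: restricted to a half-sphere, rotations push
  boundary parcels onto their neighbours and inflate duplicate assignments,
  measurably distorting the null.
* `make_two_group_cohort()` injects a known additive group effect into
  component 1 of per-subject maps with age/sex/site confounds acting
  identically in both groups.

## Numerical and inferential choices

* **Overlap normalization.** Each lag's cross-covariance divides by the
  overlap length, and the correlation curve normalizes by the windowed
  second moments; edges are plain truncation, never circular wrap.
* **Resampling** is whole-record Whittaker–Shannon (sinc) interpolation;
  edge error is confined to about one kernel width, and tests measure
  reconstruction on the interior of the record.
* **PCA centering**: columns of $\tau$ are mean-centered, no variance
  scaling — the convention under which the rank-2 structure
  $\tau_{ij} = l_i - l_j$ collapses to a single recoverable component. For
  an antisymmetric matrix, row- versus column-centering changes only signs.
* **Diffusion embedding** uses $\alpha = 0.5$ and diffusion time 0; the
  trivial eigenvector is dropped and components scale by
  $\lambda/(1-\lambda)$. A disconnected affinity is an error by default;
  the `epsilon` argument (and the pipeline's automatic retry) adds a small
  uniform off-diagonal mass to reconnect it — logged, never silent.
* **Sparsify-then-kernel**: the cosine kernel is computed between rows of
  the top-fraction-sparsified z-matrix. The opposite order is defensible;
  this one follows the toolbox convention of the gradient literature.
* **INT fitting** is bounded multistart Levenberg–Marquardt
  ($A \in [0,2]$, $B \in [-1,1]$, $T \in (0,100]$ s, starts at
  $T_0 \in \{0.5, 2, 10\}$ s). Fits pinned at a box bound are flagged
  non-converged rather than returned as estimates.
* **Permutation p-values** always use the $+1$ convention; spins are
  defined for cortical parcels only (subcortical values can be appended
  unspun, off by default); all tests are two-sided; each analysis grid is
  one FDR family.
* **Hotelling $T^2$** at one component reduces to the squared pooled-variance
  two-sample $t$, which the tests verify against `t.test()`.

## Known limitations

* With the 5 s lag cap and TR 0.72 s, only seven autocorrelation points
  enter the INT fit, and timescales longer than the window (e.g.
  $\phi = 0.9$, $T = 6.8$ s) are weakly identified: $A$, $B$ and $T$ become
  nearly collinear and single-scan estimates carry large variance even
  though the median over the tested ground-truth grid stays within the
  recovery bands. Rank ordering of timescales is far more stable than their
  absolute values.
* The parcel-spin variant (nearest-neighbour reassignment, duplicates
  allowed) is exactly the field's common procedure, and calibrates cleanly
  for exchangeable maps; for strongly smooth maps it is known to be mildly
  anticonservative because duplicated assignments shrink the null variance.
  Sensitivity analyses with the unspun-subcortex option or different
  parcel densities are recommended for borderline findings.
* Latency estimation assumes a common hemodynamic response; regionally
  varying hemodynamic delay is indistinguishable from neural latency in
  this framework.

## Problem sizes used by the shipped tests

Recovery and calibration checks run at deliberately small, fixed sizes
chosen as the package's own test design: 10-region propagating cohorts with
1200 time points over 20 seeds; AR(1) grids at 20 000 and 1200 points;
10-region toy connectomes for the biophysical fixed point; 100-parcel,
200-spin, 500-repetition spin calibration; 30-per-group Hotelling power at
100 seeds; and a 20-subject end-to-end pipeline with the fast-TR readout
comparison (0.72/0.36/0.18/0.09 s) over 20 seeds. The same computations, at
the same sizes, are what `scripts/acceptance.R` re-runs and reports.
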