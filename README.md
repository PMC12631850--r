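# latstruct

Latency structure analysis of resting-state BOLD signals, for computational
neuroimaging researchers who want the full chain — lag estimation, latency
eigenvectors, biophysical interpretation, timescales, gradients and
permutation inference — as one tested R package with synthetic ground truth
for every stage.

## The model

Spontaneous BOLD activity propagates: region pairs are maximally
cross-covariant at non-zero temporal offsets. For regions *i*, *j* the lagged
cross-covariance

&nbsp;&nbsp;&nbsp;&nbsp;*C*<sub>*x<sub>i</sub>x<sub>j</sub>*</sub>(τ) = (1/*T*) ∫ *x<sub>i</sub>*(*t* + τ) · *x<sub>j</sub>*(*t*) d*t*

is maximized (on the TR grid within a 5 s threshold, refined by parabolic
interpolation to sub-TR resolution) to give the latency τ<sub>*i*,*j*</sub>;
these fill an antisymmetric time-delay matrix whose principal components —
the **latency eigenvectors** — are compact per-region maps of dominant
propagation modes. The package links those maps to:

* a **biophysical excitatory/inhibitory neural-mass model** with per-region
  feedback inhibition control (recurrent weights and noise amplitudes are
  linear in standardized myelin/gradient maps), integrated by
  Euler–Maruyama in compiled code and passed through a Balloon–Windkessel
  hemodynamic forward model to produce BOLD at any TR;
* the **intrinsic neural timescale** *R*(*k*Δ) = *A* e<sup>−*k*Δ/*T*</sup> + *B*
  fitted per region to the autocorrelation function;
* **functional-connectivity gradients** (Fisher-z FC → top-10% row
  sparsification → cosine affinity → diffusion-map embedding → Procrustes
  alignment);
* **inference**: spherical spin permutation tests, Hotelling T² group
  comparison with label permutation, Benjamini–Hochberg FDR, and five-fold
  cross-validated regression.

Real cohorts of this kind are access-gated, so every input has a synthetic
generator with recoverable ground truth (known lags, known timescales, known
group effects); the test suite consists of recovery, calibration and oracle
properties on those generators.

## Worked example

```r
library(latstruct)

# 1. simulate a propagating BOLD cohort with a known lag projection
l_true <- seq(-1.2, 1.2, length.out = 10)          # seconds; larger = leads
sim <- make_propagating_bold(n_regions = 10, lag_projection = l_true,
                             tr = 0.72, n_timepoints = 1200,
                             snr = 10, seed = 1)
sim$ts
#> <parcellated_ts> 10 regions x 1200 timepoints, TR = 0.72 s (864.0 s total)

# 2. time-delay matrix at the 5 s threshold
td <- time_delay_matrix(sim$ts, threshold = 5)
td
#> <time_delay_matrix> 10 x 10, threshold 5 s, max |tau| = 2.463 s, 0 clipped pair(s)
round(td$tau[1:4, 1:4], 2)
#>      [,1]  [,2]  [,3]  [,4]
#> [1,] 0.00 -0.24 -0.58 -0.76
#> [2,] 0.24  0.00 -0.22 -0.46
#> [3,] 0.58  0.22  0.00 -0.16
#> [4,] 0.76  0.46  0.16  0.00

# 3. latency eigenvectors
eig <- latency_eigenvectors(td, n_components = 3)
eig
#> <eigen_set> 10 regions x 3 components (pca)
#>   explained variance: 99.9%, 0.0%, 0.0%
cor(eig$vectors[, 1], l_true)
#> [1] 0.9991829
```

`tau[1, 2] = -0.24` s says region 1 trails region 2 by about a quarter
second — the ground truth is `l_true[1] - l_true[2] = -0.27` s — and the
first eigenvector recovers the injected propagation axis almost perfectly
(r = 0.999) because an ideal lag-projection delay matrix is rank two, with a
single component after centering.

```r
# 4. intrinsic timescales of AR(1) signals with a known oracle
ar <- make_ar1(c(0.5, 0.7, 0.9), n_timepoints = 20000, tr = 0.72, seed = 2)
int_map(ar)
#>   region_id         A           B        T          rss converged
#> 1         0 0.9957574 0.003586993 1.053837 2.299543e-05      TRUE
#> 2         1 0.9666113 0.032105344 1.980421 3.189287e-05      TRUE
#> 3         2 0.9814308 0.018683509 7.166124 5.959147e-07      TRUE
```

The analytic truths are T = −Δ/ln φ = 1.04, 2.02 and 6.83 s; the fitted
timescales land within a few percent, and their ordering tracks φ.

```r
# 5. spin-permutation association between two maps sharing a spatial axis
rt <- make_region_table(100)
null <- build_spin_null(rt, n_perm = 1000, seed = 3)
map_a <- rt$z + 0.2 * rnorm(100)
map_b <- rt$z + 0.2 * rnorm(100)
st <- spin_test_correlation(map_a, map_b, null)
c(r = st$r, p_spin = st$p)
#>           r      p_spin
#> 0.907811412 0.005994006
```

The whole chain (latency → eigenvectors → INT → gradients → statistics, with
a JSON run manifest) runs over a cohort of files via `run_pipeline()`, or
from a shell through the thin CLI at `inst/cli/latstruct.R`
(`simulate | pfic | latency | eigen | int | gradient | compare | all`).

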