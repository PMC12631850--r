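#' Synthetic propagating BOLD with known regional lags
#'
#' Emulates the lag structure that the latency estimator measures: a shared
#' infra-slow signal (Gaussian noise band-passed to 0.01-0.1 Hz, the regime in
#' which BOLD latency is meaningful) is realized on a fine internal grid
#' (`oversample` times the TR), shifted per region by its lag projection
#' `l[i]` — larger `l` means earlier/leading — decimated to the TR, and
#' corrupted with independent Gaussian noise at the requested SNR
#' (shared-signal variance over noise variance). The implied pairwise lag is
#' `tau[i, j] = l[i] - l[j]`, antisymmetric by construction, and the
#' cross-covariance peak lag approaches it as `snr -> Inf`.
#'
#' @param n_regions number of regions (length of `lag_projection`).
#' @param lag_projection per-region lag vector `l` in seconds; keep
#'   `max(l) - min(l)` strictly below the latency threshold used downstream,
#'   otherwise those pairs are clipped there.
#' @param tr output sampling interval (seconds).
#' @param n_timepoints output length (>= 200).
#' @param snr shared-signal-to-noise variance ratio; `Inf` disables noise.
#' @param seed integer seed; the generator is a pure function of its
#'   arguments.
#' @param oversample internal grid refinement factor (>= 10) so sub-TR lags
#'   exist exactly on the fine grid.
#' @param band passband of the shared signal in Hz (default `c(0.01, 0.1)`).
#' @return list with `ts` (a [parcellated_ts()]) and `truth` (list with
#'   `lag_projection`, `band`, `noise_sd`).
#' @export
make_propagating_bold <- function(n_regions, lag_projection, tr, n_timepoints,
                                  snr = Inf, seed = 1L, oversample = 10L,
                                  band = c(0.01, 0.1)) {
  stopifnot(length(lag_projection) == n_regions, n_timepoints >= 200,
            oversample >= 10L, tr > 0)
  withr::with_seed(seed, {
    dt <- tr / oversample
    margin <- ceiling(max(abs(lag_projection)) / dt) + oversample
    n_fine <- n_timepoints * oversample + 2L * margin
    shared <- bandpass_white(n_fine, dt, band)
    sd_shared <- stats::sd(shared)
    noise_sd <- if (is.finite(snr)) sd_shared / sqrt(snr) else 0
    out <- matrix(0, n_regions, n_timepoints)
    base_idx <- margin + seq(1L, n_timepoints * oversample, by = oversample)
    for (i in seq_len(n_regions)) {
      # larger l -> signal advanced (region sees the waveform earlier)
      shift <- round(lag_projection[i] / dt)
      out[i, ] <- shared[base_idx + shift]
    }
    if (noise_sd > 0)
      out <- out + matrix(stats::rnorm(length(out), sd = noise_sd),
                          n_regions, n_timepoints)
    list(ts = parcellated_ts(out, tr = tr),
         truth = list(lag_projection = lag_projection, band = band,
                      noise_sd = noise_sd))
  })
}

# white Gaussian noise band-passed by FFT masking; unit variance output
bandpass_white <- function(n, dt, band) {
  w <- stats::rnorm(n)
  f <- stats::fft(w)
  freq <- c(0, seq_len(n - 1)) / (n * dt)
  freq <- pmin(freq, 1 / dt - freq)   # two-sided frequency magnitude
  keep <- freq >= band[1] & freq <= band[2]
  f[!keep] <- 0
  x <- Re(stats::fft(f, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) stop("degenerate passband", call. = FALSE)
  x / s
}

#' Stationary AR(1) series with known intrinsic timescale
#'
#' Generates first-order autoregressive signals whose population
#' autocorrelation at lag `k * tr` is `phi^k`, so the true intrinsic neural
#' timescale is `T = -tr / log(phi)` — the analytic oracle for the
#' autocorrelation-decay fit. Initialization is drawn from the stationary
#' distribution.
#'
#' @param phi AR coefficient(s) in (0, 1); one region per element.
#' @param n_timepoints series length.
#' @param tr sampling interval (seconds).
#' @param seed integer seed.
#' @return a [parcellated_ts()] with `length(phi)` regions; attribute
#'   `true_T` carries `-tr / log(phi)`.
#' @export
make_ar1 <- function(phi, n_timepoints, tr, seed = 1L) {
  if (any(phi <= 0) || any(phi >= 1))
    stop("phi must lie strictly in (0, 1)", call. = FALSE)
  withr::with_seed(seed, {
    mat <- t(vapply(phi, function(p) {
      x <- numeric(n_timepoints)
      x[1L] <- stats::rnorm(1L, sd = 1 / sqrt(1 - p^2))
      innov <- stats::rnorm(n_timepoints - 1L)
      for (t in 2L:n_timepoints) x[t] <- p * x[t - 1L] + innov[t - 1L]
      x
    }, numeric(n_timepoints)))
    ts <- parcellated_ts(mat, tr = tr)
    attr(ts, "true_T") <- -tr / log(phi)
    ts
  })
}

#' Modular (block-correlated) time series
#'
#' Regions fall into equally sized blocks; a shared global factor, per-block
#' factors and idiosyncratic noise are mixed with analytically chosen weights
#' so the expected Pearson correlation is `within_r` inside a block and
#' `between_r` across blocks. The implied covariance must be positive
#' semidefinite (`within_r >= between_r >= 0`, `within_r <= 1`).
#'
#' @param n_regions total regions (multiple of `n_blocks`).
#' @param n_blocks number of blocks.
#' @param within_r,between_r target correlations.
#' @param n_timepoints series length.
#' @param seed integer seed.
#' @return a [parcellated_ts()]; attribute `block` gives block membership.
#' @export
make_modular_timeseries <- function(n_regions, n_blocks, within_r, between_r,
                                    n_timepoints, seed = 1L) {
  if (n_regions %% n_blocks != 0)
    stop("n_regions must be a multiple of n_blocks", call. = FALSE)
  if (within_r < between_r)
    stop("within_r must be >= between_r", call. = FALSE)
  if (between_r < 0 || within_r > 1)
    stop("infeasible correlation targets (implied covariance not PSD)",
         call. = FALSE)
  a2 <- between_r; b2 <- within_r - between_r; c2 <- 1 - within_r
  withr::with_seed(seed, {
    block <- rep(seq_len(n_blocks), each = n_regions / n_blocks)
    g <- stats::rnorm(n_timepoints)
    f <- matrix(stats::rnorm(n_blocks * n_timepoints), n_blocks)
    eps <- matrix(stats::rnorm(n_regions * n_timepoints), n_regions)
    mat <- sqrt(a2) * matrix(g, n_regions, n_timepoints, byrow = TRUE) +
      sqrt(b2) * f[block, , drop = FALSE] + sqrt(c2) * eps
    ts <- parcellated_ts(mat, tr = 1)
    attr(ts, "block") <- block
    ts
  })
}

#' Toy connectome with smooth myelin/gradient surrogates
#'
#' A stand-in for the structural inputs of the biophysical model: parcel
#' centroids on a Fibonacci lattice (quasi-uniform on the unit sphere), a
#' symmetric nonnegative zero-diagonal structural matrix with
#' distance-decaying weights (dense positive, hence connected), and smooth
#' synthetic myelin / first-gradient maps standardized to zero mean and unit
#' variance. All outputs are synthetic surrogates, not empirical maps.
#'
#' @param n_regions number of parcels (>= 4).
#' @param seed integer seed.
#' @param decay length scale (radians of arc) of the connectivity decay.
#' @return list with `C` (structural matrix), `myelin`, `fgrad1` (standardized
#'   maps) and `regions` (a [region_table()] with cyclic seven-network
#'   labels).
#' @export
make_toy_connectome <- function(n_regions, seed = 1L, decay = 0.5) {
  stopifnot(n_regions >= 4)
  withr::with_seed(seed, {
    cen <- fibonacci_sphere(n_regions)
    ang <- acos(pmin(pmax(tcrossprod(cen), -1), 1))
    C <- exp(-ang / decay) * (1 + 0.1 * abs(stats::rnorm(n_regions^2)))
    C <- (C + t(C)) / 2
    diag(C) <- 0
    myelin <- scale_map(-cen[, 3L] + 0.2 * stats::rnorm(n_regions))
    fgrad1 <- scale_map(cen[, 1L] + 0.2 * stats::rnorm(n_regions))
    nets <- c("visual", "somatomotor", "dorsal_attention", "ventral_attention",
              "limbic", "frontoparietal", "default_mode")
    regions <- region_table(data.frame(
      region_id = seq_len(n_regions) - 1L,
      name = sprintf("parcel_%03d", seq_len(n_regions) - 1L),
      hemisphere = ifelse(cen[, 1L] < 0, "left", "right"),
      network = nets[(seq_len(n_regions) - 1L) %% 7L + 1L],
      is_cortical = TRUE,
      x = cen[, 1L], y = cen[, 2L], z = cen[, 3L],
      stringsAsFactors = FALSE))
    list(C = C, myelin = myelin, fgrad1 = fgrad1, regions = regions)
  })
}

scale_map <- function(v) as.numeric(scale(v))

# quasi-uniform points on the unit sphere (golden-angle spiral)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Region table with cortical and subcortical parcels
#'
#' Convenience generator for tests and demos. Following the per-hemisphere
#' spherical-registration convention of surface-based analysis, each
#' hemisphere's parcels cover their own full unit sphere (a Fibonacci
#' lattice; the right hemisphere's is the mirror image of the left's), so
#' spherical rotations of one hemisphere are closed. `n_subcortical`
#' structures get hemisphere `"none"` and are not cortical.
#'
#' @param n_cortical cortical parcel count (split evenly between
#'   hemispheres; must be even).
#' @param n_subcortical subcortical structure count.
#' @return a [region_table()].
#' @export
make_region_table <- function(n_cortical, n_subcortical = 0L) {
  if (n_cortical %% 2L != 0L)
    stop("n_cortical must be even (split over two hemispheres)", call. = FALSE)
  half <- n_cortical %/% 2L
  cen_l <- fibonacci_sphere(half)
  cen_r <- cen_l %*% diag(c(-1, 1, 1))      # mirror across the L-R axis
  cen_s <- fibonacci_sphere(max(n_subcortical, 1L))
  cen <- rbind(cen_l, cen_r,
               cen_s[seq_len(n_subcortical), , drop = FALSE])
  nets <- c("visual", "somatomotor", "dorsal_attention", "ventral_attention",
            "limbic", "frontoparietal", "default_mode")
  sub_names <- c("thalamus", "caudate", "putamen", "pallidum", "hippocampus",
                 "amygdala", "accumbens")
  n <- n_cortical + n_subcortical
  is_ctx <- seq_len(n) <= n_cortical
  region_table(data.frame(
    region_id = seq_len(n) - 1L,
    name = ifelse(is_ctx, sprintf("parcel_%03d", seq_len(n) - 1L),
                  sprintf("%s_%d", sub_names[(seq_len(n) - 1L) %% 7L + 1L],
                          seq_len(n))),
    hemisphere = c(rep("left", half), rep("right", half),
                   rep("none", n_subcortical)),
    network = ifelse(is_ctx, nets[(seq_len(n) - 1L) %% 7L + 1L],
                     sub_names[(seq_len(n) - 1L) %% 7L + 1L]),
    is_cortical = is_ctx,
    x = cen[, 1L], y = cen[, 2L], z = cen[, 3L],
    stringsAsFactors = FALSE))
}

#' Two-group cohort of per-subject component maps with an injected effect
#'
#' Emulates a case/control comparison of aligned eigenvector maps: every
#' subject's region x component map is a shared smooth group template plus
#' covariate contributions (age, sex, site — identical mechanisms in both
#' groups) plus subject noise; group 2 additionally receives `effect_map`
#' added to component 1. The expected group difference therefore equals
#' `effect_map` and the covariates are recoverable confounds.
#'
#' @param n_per_group subjects per group (>= 3).
#' @param effect_map per-region additive effect (units of the subject-noise
#'   SD, which is 1).
#' @param n_components components per subject map (default 3).
#' @param n_sites number of acquisition sites (default 2).
#' @param seed integer seed.
#' @return list with `maps` (subject x region x component array, groups
#'   stacked: first `n_per_group` rows group 1), `group` (factor),
#'   `covariates` (data.frame of age/sex/site) and `effect_map`.
#' @export
make_two_group_cohort <- function(n_per_group, effect_map, n_components = 3L,
                                  n_sites = 2L, seed = 1L) {
  if (n_per_group < 3) stop("need at least 3 subjects per group", call. = FALSE)
  n_reg <- length(effect_map)
  withr::with_seed(seed, {
    n_sub <- 2L * n_per_group
    template <- matrix(stats::rnorm(n_reg * n_components), n_reg)
    age <- stats::runif(n_sub, 8, 40)
    sex <- factor(sample(c("F", "M"), n_sub, replace = TRUE))
    site <- factor(sample(sprintf("site%02d", seq_len(n_sites)), n_sub,
                          replace = TRUE))
    beta_age <- stats::rnorm(n_reg, sd = 0.02)
    beta_sex <- stats::rnorm(n_reg, sd = 0.2)
    beta_site <- matrix(stats::rnorm(n_reg * n_sites, sd = 0.2), n_reg)
    maps <- array(0, dim = c(n_sub, n_reg, n_components))
    for (s in seq_len(n_sub)) {
      covar_shift <- beta_age * age[s] + beta_sex * (sex[s] == "M") +
        beta_site[, as.integer(site[s])]
      noise <- matrix(stats::rnorm(n_reg * n_components), n_reg)
      maps[s, , ] <- template + covar_shift + noise
      if (s > n_per_group) maps[s, , 1L] <- maps[s, , 1L] + effect_map
    }
    list(maps = maps,
         group = factor(rep(c("A", "B"), each = n_per_group)),
         covariates = data.frame(age = age, sex = sex, site = site),
         effect_map = effect_map)
  })
}
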