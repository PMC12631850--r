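#' Construct a pFIC system
#'
#' Bundles the structural connectome with every neural-mass parameter. The
#' model couples per-region excitatory (E) and inhibitory (I) populations:
#' the E input current sums baseline drive `w_E * I_0`, local recurrent
#' excitation `W_EE * J_NMDA * S_E`, long-range input
#' `G * J_NMDA * sum_k C[j,k] * S_E[k]` and feedback inhibition
#' `-W_IE * S_I`; the I current sums `w_I * I_0`, `W_EI * J_NMDA * S_E` and
#' `-W_II * S_I`. Currents map to rates through a soft-rectifying sigmoid and
#' rates drive the first-order gating kinetics, with per-region Gaussian
#' noise of amplitude `sigma` on both gating equations.
#'
#' @param C symmetric nonnegative structural connectivity matrix with zero
#'   diagonal.
#' @param G global coupling scaling factor (dimensionless, >= 0).
#' @param W_EE,W_EI per-region recurrent E-to-E and E-to-I weights (positive;
#'   scalars are recycled).
#' @param sigma per-region noise amplitude in nA (nonnegative; recycled).
#' @param W_IE per-region feedback-inhibition weight (nonnegative; recycled);
#'   typically set by [calibrate_fic()].
#' @param constants output of [pfic_constants()].
#' @return object of class `pfic_system`.
#' @export
pfic_system <- function(C, G, W_EE = 1, W_EI = 1, sigma = 0.01, W_IE = 1,
                        constants = pfic_constants()) {
  C <- as.matrix(C)
  n <- nrow(C)
  if (ncol(C) != n) stop("C must be square", call. = FALSE)
  if (max(abs(C - t(C))) > 1e-10 * max(1, max(abs(C))))
    stop("C must be symmetric", call. = FALSE)
  if (any(C < 0)) stop("C must be nonnegative", call. = FALSE)
  if (any(diag(C) != 0)) stop("C must have a zero diagonal", call. = FALSE)
  rec <- function(v, nm, min_ok = 0, strict = FALSE) {
    v <- rep_len(as.numeric(v), n)
    if (any(!is.finite(v)) || any(if (strict) v <= min_ok else v < min_ok))
      stop(nm, " must be ", if (strict) "strictly positive" else "nonnegative",
           call. = FALSE)
    v
  }
  structure(list(C = C, G = G,
                 W_EE = rec(W_EE, "W_EE", 0, TRUE),
                 W_EI = rec(W_EI, "W_EI", 0, TRUE),
                 W_IE = rec(W_IE, "W_IE"),
                 sigma = rec(sigma, "sigma"),
                 constants = constants),
            class = "pfic_system")
}

#' @export
print.pfic_system <- function(x, ...) {
  cat(sprintf("<pfic_system> %d regions, G = %g, W_EE in [%.3g, %.3g], sigma in [%.3g, %.3g]\n",
              nrow(x$C), x$G, min(x$W_EE), max(x$W_EE), min(x$sigma),
              max(x$sigma)))
  invisible(x)
}

#' Assemble region-wise parameters from myelin and gradient maps
#'
#' The spatially heterogeneous parameters are linear combinations of a
#' standardized myelin surrogate and the first functional gradient:
#' `W_EE[j] = a + b * myelin[j] + c * fgrad1[j]`, `W_EI[j]` analogously with
#' `(d, e, f)` and `sigma[j]` with `(g, h, i)`. Every assembled value must
#' come out strictly positive.
#'
#' @param coeff_wee,coeff_wei,coeff_sigma numeric coefficient triples.
#' @param myelin,fgrad1 per-region maps, standardized to zero mean and unit
#'   variance (checked to 1e-6).
#' @param C,G,constants passed through to [pfic_system()].
#' @param W_IE initial feedback-inhibition weights (default 1; run
#'   [calibrate_fic()] afterwards).
#' @return a `pfic_system`.
#' @export
assemble_parameters <- function(coeff_wee, coeff_wei, coeff_sigma,
                                myelin, fgrad1, C, G,
                                W_IE = 1, constants = pfic_constants()) {
  stopifnot(length(coeff_wee) == 3L, length(coeff_wei) == 3L,
            length(coeff_sigma) == 3L, length(myelin) == length(fgrad1))
  for (nm in c("myelin", "fgrad1")) {
    v <- get(nm)
    if (abs(mean(v)) > 1e-6 || abs(stats::sd(v) - 1) > 1e-6)
      stop(nm, " map must be standardized (zero mean, unit variance)",
           call. = FALSE)
  }
  lin <- function(cf, nm) {
    v <- cf[1L] + cf[2L] * myelin + cf[3L] * fgrad1
    if (any(v <= 0))
      stop(sprintf("%s non-positive at region(s) %s for coefficients (%g, %g, %g)",
                   nm, paste(which(v <= 0) - 1L, collapse = ", "),
                   cf[1L], cf[2L], cf[3L]), call. = FALSE)
    v
  }
  pfic_system(C, G,
              W_EE = lin(coeff_wee, "W_EE"),
              W_EI = lin(coeff_wei, "W_EI"),
              sigma = lin(coeff_sigma, "sigma"),
              W_IE = W_IE, constants = constants)
}

#' Population transfer function (current to firing rate)
#'
#' `rate = (a*I - b) / (1 - exp(-d*(a*I - b)))`, the soft-rectifying sigmoid of
#' the reduced two-population mean-field model. The removable singularity at
#' `a*I = b` is handled by its analytic limit `1/d`; the function is defined,
#' positive and strictly increasing for all real currents.
#'
#' @param current input current (nA); vectorized.
#' @param population `"E"` or `"I"` (selects the constant triple).
#' @param constants output of [pfic_constants()].
#' @return firing rate in Hz.
#' @export
transfer_function <- function(current, population = c("E", "I"),
                              constants = pfic_constants()) {
  population <- match.arg(population)
  a <- constants[[paste0("a_", population)]]
  b <- constants[[paste0("b_", population)]]
  d <- constants[[paste0("d_", population)]]
  x <- a * current - b
  r <- numeric(length(x))
  small <- abs(d * x) < 1e-8
  # series of x / (1 - exp(-d x)) about x = 0
  r[small] <- 1 / d + x[small] / 2 + d * x[small]^2 / 12
  r[!small] <- x[!small] / (1 - exp(-d * x[!small]))
  r
}

# inverse of the transfer function: current with phi(I) = rate
inverse_transfer <- function(rate, population, constants) {
  a <- constants[[paste0("a_", population)]]
  b <- constants[[paste0("b_", population)]]
  d <- constants[[paste0("d_", population)]]
  if (rate <= 0) stop("target rate must be positive", call. = FALSE)
  f <- function(I) transfer_function(I, population, constants) - rate
  lo <- (b - 1e4) / a; hi <- (b + 1e4 + rate) / a
  stats::uniroot(f, c(lo, hi), tol = 1e-14)$root
}

#' Calibrate feedback inhibition to a target excitatory rate
#'
#' Solves the per-region inhibitory-to-excitatory weights `W_IE` such that
#' the noise-free network fixed point holds every region's excitatory firing
#' rate at `target_rate`. Because the target is uniform, the fixed point is
#' available in closed form: the excitatory current `I_E*` solving
#' `phi_E(I_E*) = target_rate` and the gating steady state
#' `S_E* = gamma * r * tau_E / (1 + gamma * r * tau_E)` are shared by all
#' regions; each region's inhibitory gating `S_I*[j]` solves a scalar fixed
#' point of its I-population balance, and `W_IE[j]` then follows from the
#' E-current balance. Weights must come out nonnegative, else the target is
#' infeasible for that region.
#'
#' @param system a [pfic_system()].
#' @param target_rate target excitatory rate in Hz (default 3, the low
#'   single-digit regime of the feedback-inhibition-control literature).
#' @return the system with solved `W_IE` and attributes `fixed_point`
#'   (list `S_E`, `S_I`, `I_E`, `r_E`, `r_I`) and `target_rate`.
#' @export
calibrate_fic <- function(system, target_rate = 3) {
  stopifnot(inherits(system, "pfic_system"))
  k <- system$constants
  n <- nrow(system$C)
  I_E_star <- inverse_transfer(target_rate, "E", k)
  g <- k$gamma * target_rate * k$tau_E
  S_E_star <- g / (1 + g)
  # per-region inhibitory balance: S_I = tau_I * phi_I(w_I I_0 + W_EI J S_E* - W_II S_I)
  S_I_star <- numeric(n); r_I_star <- numeric(n)
  for (j in seq_len(n)) {
    drive <- k$w_I * k$I_0 + system$W_EI[j] * k$J_NMDA * S_E_star
    h <- function(S_I)
      k$tau_I * transfer_function(drive - k$W_II * S_I, "I", k) - S_I
    S_I_star[j] <- stats::uniroot(h, c(0, 10), tol = 1e-14)$root
    r_I_star[j] <- S_I_star[j] / k$tau_I
  }
  net <- system$G * k$J_NMDA * as.numeric(system$C %*% rep(S_E_star, n))
  W_IE <- (k$w_E * k$I_0 + system$W_EE * k$J_NMDA * S_E_star + net -
             I_E_star) / S_I_star
  if (any(W_IE < 0)) {
    bad <- which(W_IE < 0) - 1L
    stop("no nonnegative W_IE attains the target rate in region(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  system$W_IE <- W_IE
  attr(system, "fixed_point") <- list(
    S_E = rep(S_E_star, n), S_I = S_I_star,
    I_E = rep(I_E_star, n), r_E = rep(target_rate, n), r_I = r_I_star)
  attr(system, "target_rate") <- target_rate
  system
}

#' Integrate the neural-mass equations
#'
#' Euler-Maruyama integration of the coupled gating equations with currents
#' and rates recomputed every step; gating variables are clipped to `[0, 1]`.
#' With `sigma = 0` the dynamics are deterministic and converge to the model
#' fixed point. Non-finite states abort with the blow-up time.
#'
#' @param system a [pfic_system()] (usually calibrated).
#' @param duration stored duration in seconds (>= 10 recommended); the
#'   burn-in is simulated on top and discarded.
#' @param dt integration step in seconds (<= 1e-3).
#' @param seed integer seed (drives R's RNG; identical seeds give identical
#'   trajectories).
#' @param burn_in discarded initial period (seconds, default 10).
#' @param store_every store every k-th step (default 1).
#' @param init optional list with `S_E`, `S_I` initial values (defaults
#'   0.1648 / 0.05).
#' @return object of class `neural_trajectory`: matrices `S_E`, `S_I`,
#'   `r_E`, `r_I`, `I_E`, `I_I` (region x stored-time) plus `dt` (the stored
#'   step, `dt * store_every`).
#' @export
simulate_neural <- function(system, duration, dt = 5e-4, seed = 1L,
                            burn_in = 10, store_every = 1L, init = NULL) {
  stopifnot(inherits(system, "pfic_system"))
  if (dt > 1e-3) stop("dt must be <= 1 ms", call. = FALSE)
  n <- nrow(system$C)
  if (is.null(init))
    init <- list(S_E = rep(0.1648, n), S_I = rep(0.05, n))
  k <- system$constants
  res <- withr::with_seed(seed,
    pfic_integrate_cpp(system$C, system$G, system$W_EE, system$W_EI,
                       system$W_IE, k$W_II, system$sigma,
                       k$w_E, k$w_I, k$I_0, k$J_NMDA,
                       k$a_E, k$b_E, k$d_E, k$a_I, k$b_I, k$d_I,
                       k$tau_E, k$tau_I, k$gamma,
                       init$S_E, init$S_I,
                       duration, dt, burn_in, as.integer(store_every)))
  res$dt <- dt * store_every
  class(res) <- "neural_trajectory"
  res
}

#' @export
print.neural_trajectory <- function(x, ...) {
  cat(sprintf("<neural_trajectory> %d regions x %d samples at %g s; mean r_E = %.2f Hz\n",
              nrow(x$S_E), ncol(x$S_E), x$dt, mean(x$r_E)))
  invisible(x)
}

#' Excitation/inhibition ratio of a trajectory
#'
#' Per region, the ratio of the temporal means of the excitatory and
#' inhibitory synaptic gating variables (burn-in is already excluded by
#' [simulate_neural()]).
#'
#' @param traj a `neural_trajectory`.
#' @return per-region numeric vector.
#' @export
ei_ratio <- function(traj) {
  me <- rowMeans(traj$S_E)
  mi <- rowMeans(traj$S_I)
  if (any(mi == 0)) stop("mean inhibitory gating is zero in region(s): ",
                         paste(which(mi == 0) - 1L, collapse = ", "),
                         call. = FALSE)
  me / mi
}

#' Hemodynamic forward model (Balloon-Windkessel)
#'
#' Drives the standard four-state hemodynamic system (vasodilatory signal,
#' inflow, venous volume, deoxyhemoglobin) with the excitatory gating
#' variable and emits the canonical nonlinear BOLD readout
#' `V0 * (k1*(1-q) + k2*(1-q/v) + k3*(1-v))`, decimated to the output TR.
#'
#' @param S_E region x time drive matrix sampled at `dt`.
#' @param dt input sampling step (seconds).
#' @param tr_out output sampling interval (seconds, >= `dt`); must be close
#'   to an integer multiple of `dt`. The fast-TR experiment uses
#'   `tr_out` of 0.72, 0.36, 0.18 or 0.09 s.
#' @param constants output of [pfic_constants()].
#' @param burn_in initial seconds of BOLD discarded after integration
#'   (default 0).
#' @return a [parcellated_ts()] at `tr_out`.
#' @export
hemodynamic_bold <- function(S_E, dt, tr_out, constants = pfic_constants(),
                             burn_in = 0) {
  S_E <- as.matrix(S_E)
  if (any(!is.finite(S_E))) stop("non-finite drive", call. = FALSE)
  if (tr_out < dt) stop("tr_out must be >= dt", call. = FALSE)
  dec <- tr_out / dt
  if (abs(dec - round(dec)) > 1e-6)
    stop("tr_out must be an integer multiple of dt", call. = FALSE)
  k <- constants
  bold <- bw_integrate_cpp(S_E, dt, k$kappa, k$gamma_h, k$tau_h, k$alpha,
                           k$rho, k$V0, k$k1, k$k2, k$k3)
  idx <- seq(1L, ncol(bold), by = as.integer(round(dec)))
  bold <- bold[, idx, drop = FALSE]
  if (burn_in > 0) {
    drop <- floor(burn_in / tr_out)
    if (drop >= ncol(bold)) stop("burn_in exceeds the record", call. = FALSE)
    bold <- bold[, -seq_len(drop), drop = FALSE]
  }
  parcellated_ts(bold, tr = tr_out)
}

#' Simulate a BOLD dataset from a pFIC system
#'
#' Composition of [simulate_neural()] and [hemodynamic_bold()]:
#' end-to-end deterministic given the seed, returning a [parcellated_ts()]
#' ready for the latency module. A single neural trajectory can be read out
#' at several TRs (`tr_out` vectorized), which is how the fast-TR
#' reliability comparison re-samples one simulation at 0.72/0.36/0.18/0.09 s;
#' alternatively call with different seeds to re-simulate.
#'
#' @param system a calibrated [pfic_system()].
#' @param duration usable BOLD duration in seconds.
#' @param tr_out output TR(s) in seconds (each an integer multiple of `dt`).
#' @param seed integer seed.
#' @param dt integration step (default 5e-4 s).
#' @param burn_in neural burn-in (s, default 10); an additional
#'   `bold_burn_in` (default 20 s) of BOLD is discarded to pass the
#'   hemodynamic transient.
#' @param bold_burn_in see above.
#' @return a [parcellated_ts()], or a named list of them when `tr_out` has
#'   length > 1.
#' @export
simulate_bold_dataset <- function(system, duration, tr_out = 0.72, seed = 1L,
                                  dt = 5e-4, burn_in = 10, bold_burn_in = 20) {
  traj <- simulate_neural(system, duration = duration + bold_burn_in,
                          dt = dt, seed = seed, burn_in = burn_in)
  out <- lapply(tr_out, function(tr)
    hemodynamic_bold(traj$S_E, dt = dt, tr_out = tr,
                     constants = system$constants, burn_in = bold_burn_in))
  if (length(tr_out) == 1L) out[[1L]] else
    stats::setNames(out, sprintf("tr_%g", tr_out))
}
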