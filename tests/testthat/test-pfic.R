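test_that("parameter surfaces assemble by the stated linear combinations", {
  my <- c(-1, 0, 1); fg <- c(1, 0, -1)
  C <- matrix(0.5, 3, 3); diag(C) <- 0
  sys <- assemble_parameters(c(1, 0.5, -0.2), c(1, 0, 0), c(0.01, 0, 0),
                             my, fg, C, G = 1)
  expect_equal(sys$W_EE, c(0.3, 1.0, 1.7))       # hand arithmetic
  expect_equal(sys$W_EI, rep(1, 3))              # degenerate combination
  expect_equal(sys$sigma, rep(0.01, 3))
  # collinear maps: identical maps act through the coefficient sum
  sys2 <- assemble_parameters(c(1, 0.5, 0.25), c(1, 0, 0), c(0.01, 0, 0),
                              my, my, C, G = 1)
  expect_equal(sys2$W_EE, 1 + 0.75 * my)
  expect_error(assemble_parameters(c(0.1, 5, 0), c(1, 0, 0), c(0.01, 0, 0),
                                   my, fg, C, G = 1), "region")
  expect_error(assemble_parameters(c(1, 0, 0), c(1, 0, 0), c(0.01, 0, 0),
                                   my + 1, fg, C, G = 1), "standardized")
})

test_that("transfer function handles its removable singularity and asymptote", {
  k <- pfic_constants()
  # a*I = b: the analytic limit is 1/d
  expect_equal(transfer_function(k$b_E / k$a_E, "E", k), 1 / k$d_E)
  expect_equal(transfer_function(k$b_I / k$a_I, "I", k), 1 / k$d_I)
  # continuity across the singularity
  eps <- 1e-10
  expect_equal(transfer_function(k$b_E / k$a_E + eps, "E", k),
               transfer_function(k$b_E / k$a_E - eps, "E", k),
               tolerance = 1e-6)
  # asymptotic linearity: r -> a*I - b for large drive
  x <- 1e3 / k$d_E
  I_big <- (x + k$b_E) / k$a_E
  expect_equal(transfer_function(I_big, "E", k), x, tolerance = 1e-6)
  # strict monotonicity over a current grid
  grid <- seq(-0.5, 1.5, length.out = 400)
  expect_true(all(diff(transfer_function(grid, "E", k)) > 0))
})

test_that("single-region FIC calibration matches a 1-D root-finding oracle", {
  k <- pfic_constants()
  C <- matrix(0, 1, 1)
  sys <- pfic_system(C, G = 0, W_EE = 1.1, W_EI = 1.3, sigma = 0)
  cal <- calibrate_fic(sys, target_rate = 3)
  # independent oracle: solve the full steady state numerically for W_IE
  oracle_rate <- function(W_IE) {
    res <- stats::optim(par = c(0.2, 0.05), fn = function(s) {
      S_E <- s[1]; S_I <- s[2]
      I_E <- k$w_E * k$I_0 + 1.1 * k$J_NMDA * S_E - W_IE * S_I
      I_I <- k$w_I * k$I_0 + 1.3 * k$J_NMDA * S_E - k$W_II * S_I
      r_E <- transfer_function(I_E, "E", k)
      r_I <- transfer_function(I_I, "I", k)
      (-S_E / k$tau_E + (1 - S_E) * k$gamma * r_E)^2 +
        (-S_I / k$tau_I + r_I)^2
    }, method = "Nelder-Mead",
    control = list(reltol = 1e-14, maxit = 5000))
    S_E <- res$par[1]; S_I <- res$par[2]
    transfer_function(k$w_E * k$I_0 + 1.1 * k$J_NMDA * S_E - W_IE * S_I,
                      "E", k)
  }
  expect_equal(oracle_rate(cal$W_IE), 3, tolerance = 0.02)

  # uniform system with G = 0: all W_IE equal
  C4 <- matrix(0, 4, 4)
  cal4 <- calibrate_fic(pfic_system(C4, G = 0, W_EE = 1, W_EI = 1, sigma = 0))
  expect_equal(max(cal4$W_IE) - min(cal4$W_IE), 0, tolerance = 1e-12)
})

test_that("raising local excitation demands more feedback inhibition", {
  toy <- make_toy_connectome(6, seed = 3)
  base <- pfic_system(toy$C, G = 1, W_EE = 1, W_EI = 1, sigma = 0)
  cal <- calibrate_fic(base)
  up <- base; up$W_EE[2] <- 2
  cal_up <- calibrate_fic(up)
  expect_gt(cal_up$W_IE[2], cal$W_IE[2])
  expect_equal(cal_up$W_IE[-2], cal$W_IE[-2], tolerance = 1e-10)
  # infeasible target below the transfer floor
  expect_error(calibrate_fic(base, target_rate = -1), "positive")
})

test_that("noise-free integration settles on the calibrated fixed point", {
  cal <- calibrated_toy_system(n = 6, G = 1.5, seed = 5)
  traj <- simulate_neural(cal, duration = 20, dt = 5e-4, seed = 1,
                          burn_in = 10)
  last <- ncol(traj$r_E)
  expect_lt(max(abs(traj$r_E[, last] - 3)), 0.05)
  fp <- attr(cal, "fixed_point")
  expect_equal(traj$S_E[, last], fp$S_E, tolerance = 1e-3)
  expect_true(all(traj$S_E >= 0 & traj$S_E <= 1))
  expect_true(all(traj$S_I >= 0 & traj$S_I <= 1))
})

test_that("decoupled regions ignore the connectome and seeds reproduce", {
  toy <- make_toy_connectome(5, seed = 6)
  sysA <- pfic_system(toy$C, G = 0, W_EE = 1, W_EI = 1, sigma = 0.01,
                      W_IE = 1.5)
  perm <- c(3, 1, 5, 2, 4)
  sysB <- pfic_system(toy$C[perm, perm], G = 0, W_EE = 1, W_EI = 1,
                      sigma = 0.01, W_IE = 1.5)
  tA <- simulate_neural(sysA, duration = 2, dt = 5e-4, seed = 7, burn_in = 1)
  tB <- simulate_neural(sysB, duration = 2, dt = 5e-4, seed = 7, burn_in = 1)
  expect_identical(tA$S_E, tB$S_E)
  tA2 <- simulate_neural(sysA, duration = 2, dt = 5e-4, seed = 7, burn_in = 1)
  expect_identical(tA$S_E, tA2$S_E)
  expect_error(simulate_neural(sysA, 2, dt = 5e-3), "1 ms")
})

test_that("halving the step barely moves the deterministic terminal state", {
  cal <- calibrated_toy_system(n = 5, G = 1, seed = 8)
  t1 <- simulate_neural(cal, duration = 50, dt = 5e-4, seed = 1, burn_in = 10)
  t2 <- simulate_neural(cal, duration = 50, dt = 2.5e-4, seed = 1,
                        burn_in = 10)
  s1 <- t1$S_E[, ncol(t1$S_E)]; s2 <- t2$S_E[, ncol(t2$S_E)]
  expect_lt(max(abs(s1 - s2) / abs(s1)), 1e-4)
})

test_that("E/I ratio is the ratio of gating means and tracks the weights", {
  traj <- structure(list(S_E = matrix(0.2, 3, 10), S_I = matrix(0.1, 3, 10)),
                    class = "neural_trajectory")
  expect_equal(ei_ratio(traj), rep(2, 3))
  traj$S_I[1, ] <- 0
  expect_error(ei_ratio(traj), "zero")

  # monotone response over a stable sweep (W_IE held at its calibrated value)
  cal <- calibrated_toy_system(n = 4, G = 1, seed = 9)
  sweep_ratio <- function(field, value) {
    s <- cal
    s[[field]][2] <- value
    tr <- simulate_neural(s, duration = 10, dt = 5e-4, seed = 1, burn_in = 10)
    ei_ratio(tr)[2]
  }
  wee <- vapply(c(0.9, 1.0, 1.1) * cal$W_EE[2], function(v)
    sweep_ratio("W_EE", v), 0)
  expect_true(all(diff(wee) > 0))
  wei <- vapply(c(0.9, 1.0, 1.1) * cal$W_EI[2], function(v)
    sweep_ratio("W_EI", v), 0)
  expect_true(all(diff(wei) < 0))
})

test_that("hemodynamics: constant drive flattens, impulses peak late and undershoot", {
  dt <- 5e-4
  const_drive <- matrix(0.16, 1, 60 / dt)
  bold <- hemodynamic_bold(const_drive, dt, tr_out = 0.72)
  t_b <- (seq_len(n_timepoints(bold)) - 1) * 0.72
  expect_lt(sd(bold$data[1, t_b > 40]), 1e-6)

  imp <- matrix(0.02, 1, 40 / dt)
  imp[1, seq(10 / dt, 10.5 / dt)] <- 0.6
  bb <- hemodynamic_bold(imp, dt, tr_out = 0.18)
  tt <- (seq_len(n_timepoints(bb)) - 1) * 0.18
  base <- mean(bb$data[1, tt < 9])
  peak_t <- tt[which.max(bb$data[1, ])]
  expect_gt(peak_t, 12)          # peaks seconds after the impulse
  expect_lt(peak_t, 25)
  expect_gt(max(bb$data[1, ]), base)
  post <- bb$data[1, tt > peak_t & tt < peak_t + 15]
  expect_lt(min(post), base)     # post-peak undershoot below baseline
  # decimation at tr_out = dt is the identity in length
  expect_equal(n_timepoints(hemodynamic_bold(imp, dt, tr_out = dt)),
               ncol(imp))
})

test_that("end-to-end BOLD simulation feeds the latency module deterministically", {
  cal <- calibrated_toy_system(n = 10, G = 2, seed = 4)
  sys <- cal
  sys$sigma[] <- 0.01
  bold <- simulate_bold_dataset(sys, duration = 90, tr_out = 0.72, seed = 2)
  expect_s3_class(bold, "parcellated_ts")
  expect_gte(n_timepoints(bold), 100)
  td <- time_delay_matrix(bold, threshold = 5)
  expect_equal(td$tau, -t(td$tau))
  bold2 <- simulate_bold_dataset(sys, duration = 90, tr_out = 0.72, seed = 2)
  expect_identical(bold$data, bold2$data)
})
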