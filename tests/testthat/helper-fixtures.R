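# shared fixtures and independent oracles, built in code at test time

# brute-force lagged cross-covariance: shift-and-dot-product double loop,
# independent of the package implementation
brute_lagged_cov <- function(x, y, max_lag_samples) {
  x <- x - mean(x); y <- y - mean(y)
  n <- length(x)
  lags <- (-max_lag_samples):max_lag_samples
  cov_curve <- cor_curve <- numeric(length(lags))
  for (i in seq_along(lags)) {
    k <- lags[i]
    s <- 0; sx <- 0; sy <- 0; m <- 0
    for (t in seq_len(n)) {
      tk <- t + k
      if (tk >= 1 && tk <= n) {
        s <- s + x[tk] * y[t]
        sx <- sx + x[tk]^2
        sy <- sy + y[t]^2
        m <- m + 1
      }
    }
    cov_curve[i] <- s / m
    cor_curve[i] <- if (sx * sy > 0) s / sqrt(sx * sy) else 0
  }
  list(lags = lags, cov = cov_curve, cor = cor_curve)
}

# brute-force time-delay matrix: double loop over pairs using the oracle
# curve plus an independently coded parabolic vertex
brute_time_delay_matrix <- function(mat, tr, threshold) {
  n <- nrow(mat)
  L <- floor(threshold / tr + 1e-9)
  tau <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    cc <- brute_lagged_cov(mat[i, ], mat[j, ], L)
    idx <- order(-abs(cc$cor), abs(cc$lags))[1]
    if (idx == 1 || idx == length(cc$cor)) {
      tau[i, j] <- -cc$lags[idx] * tr
    } else {
      y1 <- cc$cor[idx - 1]; y2 <- cc$cor[idx]; y3 <- cc$cor[idx + 1]
      den <- y1 - 2 * y2 + y3
      off <- if (abs(den) < 1e-300) 0 else 0.5 * (y1 - y3) / den
      tau[i, j] <- -(cc$lags[idx] + max(-1, min(1, off))) * tr
    }
  }
  tau
}

# step-up FDR oracle written from the definition (sort, cummin from the top)
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# small valid region-table data.frame (4 regions, unit centroids)
tiny_region_df <- function() {
  s2 <- 1 / sqrt(2)
  data.frame(
    region_id = 0:3,
    name = paste0("r", 0:3),
    hemisphere = c("left", "left", "right", "right"),
    network = c("visual", "default_mode", "visual", "default_mode"),
    is_cortical = TRUE,
    x = c(-s2, -s2, s2, s2),
    y = c(s2, -s2, s2, -s2),
    z = 0,
    stringsAsFactors = FALSE)
}

# deterministic 3 x 3 rotation about an axis
rotation_about_z <- function(theta) {
  matrix(c(cos(theta), -sin(theta), 0,
           sin(theta),  cos(theta), 0,
           0, 0, 1), 3, 3, byrow = TRUE)
}

random_orthogonal <- function(k, seed) {
  withr::with_seed(seed, {
    q <- qr.Q(qr(matrix(rnorm(k * k), k)))
    q
  })
}

# tiny calibrated noise-free pFIC system shared by several tests
calibrated_toy_system <- function(n = 10, G = 2, target_rate = 3, seed = 4) {
  toy <- make_toy_connectome(n, seed = seed)
  sys <- assemble_parameters(c(1, 0.2, -0.1), c(1.2, 0.1, 0.05),
                             c(0.01, 0.002, -0.001),
                             toy$myelin, toy$fgrad1, toy$C, G = G)
  sys$sigma[] <- 0
  calibrate_fic(sys, target_rate = target_rate)
}
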