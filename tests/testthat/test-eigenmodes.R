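test_that("a rank-2 lag-projection matrix is summarized by one component", {
  l <- c(-1.2, -0.4, 0.1, 0.3, 1.2)
  tau <- outer(l, l, `-`)
  e <- latency_eigenvectors(tau, n_components = 3)
  expect_equal(abs(cor(e$vectors[, 1], l)), 1, tolerance = 1e-10)
  expect_equal(sum(e$explained_variance[1:2]), 1, tolerance = 1e-10)
  expect_false(e$degenerate)
})

test_that("PCA path equals a dense eigendecomposition of the centered covariance", {
  for (seed in 1:3) {
    withr::with_seed(seed, {
      A <- matrix(rnorm(64), 8)
      tau <- A - t(A)
    })
    e <- latency_eigenvectors(tau, n_components = 4)
    xc <- sweep(tau, 2, colMeans(tau))
    eg <- eigen(tcrossprod(xc), symmetric = TRUE)  # independent oracle
    for (k in 1:4) {
      expect_equal(abs(cor(e$vectors[, k], eg$vectors[, k])), 1,
                   tolerance = 1e-8)
      expect_equal(sum(e$vectors[, k]^2), eg$values[k], tolerance = 1e-8)
    }
    expect_equal(e$explained_variance,
                 (eg$values / sum(eg$values))[1:4], tolerance = 1e-10)
  }
})

test_that("zero and permuted inputs behave as contracts demand", {
  z <- latency_eigenvectors(matrix(0, 5, 5), n_components = 2)
  expect_true(z$degenerate)
  expect_equal(z$explained_variance, c(0, 0))
  expect_equal(z$vectors, matrix(0, 5, 2))

  l <- c(-1, 0, 0.5, 1.5)
  tau <- outer(l, l, `-`)
  p <- c(3, 1, 4, 2)
  e1 <- latency_eigenvectors(tau, 2)
  e2 <- latency_eigenvectors(tau[p, p], 2)
  # permutation equivariance up to component sign
  expect_equal(abs(e2$vectors[, 1]), abs(e1$vectors[p, 1]), tolerance = 1e-10)
  expect_error(latency_eigenvectors(tau, 10), "rank")
})

test_that("Procrustes alignment recovers reflections and rotations", {
  withr::with_seed(7, V <- qr.Q(qr(matrix(rnorm(30), 10))))
  template <- eigen_set(V, c(0.5, 0.3, 0.2), "pca")
  flipped <- eigen_set(V %*% diag(c(-1, 1, -1)), c(0.5, 0.3, 0.2), "pca")
  al <- procrustes_align(flipped, template)
  expect_equal(al$vectors, V, tolerance = 1e-10)
  expect_equal(al$explained_variance, template$explained_variance)

  R <- random_orthogonal(3, seed = 8)
  rotated <- eigen_set(V %*% R, c(0.5, 0.3, 0.2), "pca")
  al2 <- procrustes_align(rotated, template)
  expect_equal(al2$vectors, V, tolerance = 1e-10)
  Rhat <- attr(al2, "rotation")
  expect_equal(crossprod(Rhat), diag(3), tolerance = 1e-10)
  expect_error(procrustes_align(template,
                                eigen_set(V[, 1:2], c(0.5, 0.3), "pca")),
               "shape")
})

test_that("alignment cannot improve an orthogonal-subspace source", {
  # source columns orthogonal to the template's span: any orthogonal mix of
  # source columns leaves the Frobenius distance unchanged
  withr::with_seed(9, Q <- qr.Q(qr(matrix(rnorm(12 * 6), 12))))
  template <- eigen_set(Q[, 1:3], c(0.5, 0.3, 0.2), "pca")
  source <- eigen_set(Q[, 4:6], c(0.5, 0.3, 0.2), "pca")
  d0 <- norm(source$vectors - template$vectors, "F")
  al <- procrustes_align(source, template)
  d1 <- norm(al$vectors - template$vectors, "F")
  # brute force over many random orthogonal mixes never beats it either
  d_rand <- vapply(1:50, function(s)
    norm(source$vectors %*% random_orthogonal(3, s) - template$vectors, "F"),
    0)
  expect_equal(d1, d0, tolerance = 1e-8)
  expect_gte(min(d_rand) + 1e-8, d1)
})

test_that("chained alignment composes two orthogonal maps exactly", {
  withr::with_seed(10, V <- qr.Q(qr(matrix(rnorm(24), 8))))
  ref <- eigen_set(V, c(0.6, 0.3, 0.1), "pca")
  R1 <- random_orthogonal(3, 11); R2 <- random_orthogonal(3, 12)
  local_t <- eigen_set(V %*% R2, c(0.6, 0.3, 0.1), "pca")
  ind <- eigen_set(V %*% R2 %*% R1, c(0.6, 0.3, 0.1), "pca")
  out <- chained_alignment(list(ind), local_t, ref)
  expect_equal(out[[1]]$vectors, V, tolerance = 1e-8)
  # local = reference collapses to single-stage alignment
  out2 <- chained_alignment(list(ind), ref, ref)
  single <- procrustes_align(ind, ref)
  expect_equal(out2[[1]]$vectors, single$vectors, tolerance = 1e-10)
  expect_identical(chained_alignment(list(), local_t, ref), list())
})

test_that("group template averages matrices and denoises the first component", {
  l <- c(-1, -0.5, 0, 0.5, 1, 1.5)
  tau <- outer(l, l, `-`)
  same <- group_template(list(tau, tau, tau), n_components = 2)
  solo <- latency_eigenvectors(tau, n_components = 2)
  expect_equal(same$vectors, solo$vectors, tolerance = 1e-10)
  cancel <- group_template(list(tau, -tau), n_components = 2)
  expect_true(cancel$degenerate)

  # noise averaging: template E1 at least as close to truth as the mean
  # individual, across seeds
  gains <- vapply(1:20, function(seed) {
    withr::with_seed(seed, noisy <- lapply(1:10, function(i) {
      N <- matrix(rnorm(36, sd = 1.5), 6)
      tau + (N - t(N))
    }))
    tmpl <- group_template(noisy, n_components = 1)
    r_t <- abs(cor(tmpl$vectors[, 1], l))
    r_i <- mean(vapply(noisy, function(m)
      abs(cor(latency_eigenvectors(m, 1)$vectors[, 1], l)), 0))
    r_t - r_i
  }, 0)
  expect_gt(mean(gains), 0)
  expect_error(group_template(list()), "empty")
})

test_that("network stratification reproduces hand-computed summaries", {
  df <- rbind(tiny_region_df(), tiny_region_df())
  df$region_id <- 0:7
  df$name <- paste0("r", 0:7)
  rt <- region_table(df)
  map <- c(1, 2, 3, 4, 5, 6, 7, 8)
  out <- stratify_by_network(map, rt)
  expect_equal(out$mean[out$network == "visual"], mean(c(1, 3, 5, 7)))
  expect_equal(out$sd[out$network == "default_mode"], sd(c(2, 4, 6, 8)))
  expect_equal(out$n, c(4L, 4L))

  ind <- as.numeric(rt$network == "visual")
  out2 <- stratify_by_network(ind, rt)
  expect_equal(out2$mean[out2$network == "visual"], 1)
  expect_equal(out2$mean[out2$network == "default_mode"], 0)
  const <- stratify_by_network(rep(3, 8), rt)
  expect_equal(const$mean, c(3, 3))
  expect_equal(const$sd, c(0, 0))
  expect_error(stratify_by_network(1:3, rt), "length")
})
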