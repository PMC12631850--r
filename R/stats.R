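#' Spin-permutation null for parcellated brain maps
#'
#' Builds the spatial-autocorrelation-preserving null used to compare
#' parcel-level maps: for each permutation a uniform random 3D rotation is
#' applied to one hemisphere's parcel centroids and its mirror image (across
#' the left-right axis) to the other hemisphere's; each rotated centroid is
#' then reassigned to the nearest original centroid within its hemisphere
#' (greedy nearest neighbour — duplicate assignments are allowed, as in the
#' standard parcel-spin procedure). Spins are defined for cortical parcels
#' only; subcortical regions keep their identity.
#'
#' @param regions a [region_table()] with at least 4 cortical parcels per
#'   hemisphere.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed; rotations are identical across runs given the
#'   seed.
#' @return object of class `spin_null`: list with `rotations` (n_perm x
#'   n_cortical index matrix into the cortical index vector), `cortical_idx`,
#'   `n_perm`, `seed`.
#' @export
build_spin_null <- function(regions, n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(regions, "region_table"))
  ctx <- which(regions$is_cortical)
  hemi <- regions$hemisphere[ctx]
  if (sum(hemi == "left") < 4L || sum(hemi == "right") < 4L)
    stop("need at least 4 cortical regions per hemisphere", call. = FALSE)
  cen <- centroids(regions)[ctx, , drop = FALSE]
  left <- hemi == "left"
  perms <- withr::with_seed(seed, {
    t(vapply(seq_len(n_perm), function(p)
      spin_assign(cen, left, random_rotation()),
      integer(length(ctx))))
  })
  structure(list(rotations = perms, cortical_idx = ctx, n_perm = n_perm,
                 seed = seed),
            class = "spin_null")
}

# one spin: rotate the left hemisphere's centroids by R, the right's by the
# mirrored rotation, and reassign each rotated centroid to the nearest
# original centroid within its hemisphere (duplicates allowed)
spin_assign <- function(cen, left, R) {
  M <- diag(c(-1, 1, 1))
  Rm <- M %*% R %*% M
  out <- integer(nrow(cen))
  for (side in c(TRUE, FALSE)) {
    sel <- if (side) left else !left
    rot <- cen[sel, , drop = FALSE] %*% t(if (side) R else Rm)
    # on the unit sphere argmin distance = argmax dot product
    dots <- rot %*% t(cen[sel, , drop = FALSE])
    out[sel] <- which(sel)[max.col(dots, ties.method = "first")]
  }
  out
}

# uniform random rotation (QR of a Gaussian matrix, det corrected to +1)
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9L), 3L))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

#' Spin permutation test of the correlation between two maps
#'
#' Pearson correlation between two per-region maps with a two-sided
#' permutation p-value from the spin null: the first map is spun, the second
#' kept intact, and `p = (1 + #{|r_null| >= |r_obs|}) / (1 + n_perm)` (never
#' exactly zero). By default only cortical parcels enter the correlation;
#' `cortical_only = FALSE` appends unspun subcortical values.
#'
#' @param map_a,map_b numeric per-region maps aligned to the region table
#'   the null was built from (full length, or already cortex-only with
#'   `regions = NULL`).
#' @param null a [build_spin_null()] object.
#' @param regions the [region_table()]; needed when maps are full-length.
#' @param cortical_only restrict the correlation to cortex (default TRUE).
#' @return list with `r` (observed), `p`, and `r_null` (the null sample).
#' @export
spin_test_correlation <- function(map_a, map_b, null, regions = NULL,
                                  cortical_only = TRUE) {
  stopifnot(inherits(null, "spin_null"))
  ctx <- null$cortical_idx
  n_ctx <- length(ctx)
  if (length(map_a) == n_ctx && length(map_b) == n_ctx) {
    a_ctx <- map_a; b_ctx <- map_b
    a_sub <- b_sub <- numeric(0)
  } else {
    a_ctx <- map_a[ctx]; b_ctx <- map_b[ctx]
    a_sub <- map_a[-ctx]; b_sub <- map_b[-ctx]
  }
  if (stats::sd(a_ctx) == 0 || stats::sd(b_ctx) == 0)
    stop("constant map", call. = FALSE)
  keep_sub <- !cortical_only && length(a_sub)
  glue <- function(a, b) {
    if (keep_sub) stats::cor(c(a, a_sub), c(b, b_sub)) else stats::cor(a, b)
  }
  r_obs <- glue(a_ctx, b_ctx)
  # rotations index within the cortical vector
  local_idx <- match(null$rotations, ctx)
  dim(local_idx) <- dim(null$rotations)
  spun <- matrix(a_ctx[local_idx], nrow = null$n_perm)
  r_null <- apply(spun, 1L, function(av) {
    if (stats::sd(av) == 0) return(0)
    glue(av, b_ctx)
  })
  p <- (1 + sum(abs(r_null) >= abs(r_obs))) / (1 + null$n_perm)
  list(r = r_obs, p = p, r_null = r_null)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment (monotone-enforced, capped at 1).
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted q-values, same order as the input.
#' @export
fdr_bh <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Residualize subject maps on nuisance covariates
#'
#' Per-region ordinary least squares of the subject x region map matrix on
#' age, sex and site (dummy-coded with an intercept); residuals are returned
#' with the per-region grand mean added back, so the maps stay on their
#' original scale but are orthogonal to the covariates.
#'
#' @param maps subject x region numeric matrix.
#' @param covariates data.frame with columns `age` (numeric), `sex`
#'   (factor), `site` (factor); additional columns are included as given.
#' @return residualized subject x region matrix.
#' @export
residualize_covariates <- function(maps, covariates) {
  maps <- as.matrix(maps)
  X <- stats::model.matrix(~ ., data = covariates)
  if (qr(X)$rank < ncol(X)) {
    ali <- qr(X)
    collinear <- colnames(X)[setdiff(seq_len(ncol(X)), ali$pivot[seq_len(ali$rank)])]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(collinear, collapse = ", "), call. = FALSE)
  }
  H <- X %*% solve(crossprod(X), t(X))
  res <- maps - H %*% maps
  sweep(res, 2L, colMeans(maps), `+`)
}

#' Hotelling T-squared group comparison with label permutation
#'
#' Per region, the two-sample Hotelling T-squared statistic on the subjects'
#' component vectors, with significance from random reassignment of subjects
#' to groups (`p = (1 + #{T2_perm >= T2_obs}) / (1 + n_perm)`) and
#' Benjamini-Hochberg q-values across regions. Regions with a singular
#' pooled covariance are flagged and excluded (their count is logged).
#'
#' @param group_a,group_b subject x region x component arrays.
#' @param n_perm label permutations (default 1000).
#' @param seed integer seed.
#' @return data.frame with columns `region`, `T2`, `p`, `q`, `ok`.
#' @export
hotelling_t2_permutation <- function(group_a, group_b, n_perm = 1000L,
                                     seed = 1L) {
  stopifnot(length(dim(group_a)) == 3L, length(dim(group_b)) == 3L,
            dim(group_a)[2L] == dim(group_b)[2L],
            dim(group_a)[3L] == dim(group_b)[3L])
  n_a <- dim(group_a)[1L]; n_b <- dim(group_b)[1L]
  n_reg <- dim(group_a)[2L]; k <- dim(group_a)[3L]
  if (n_a < k + 2L || n_b < k + 2L)
    stop("need at least components + 2 subjects per group", call. = FALSE)
  pooled <- array(0, dim = c(n_a + n_b, n_reg, k))
  pooled[seq_len(n_a), , ] <- group_a
  pooled[n_a + seq_len(n_b), , ] <- group_b
  t2_all <- function(idx_a) {
    idx_b <- setdiff(seq_len(n_a + n_b), idx_a)
    vapply(seq_len(n_reg), function(r) {
      A <- pooled[idx_a, r, , drop = FALSE]; dim(A) <- c(length(idx_a), k)
      B <- pooled[idx_b, r, , drop = FALSE]; dim(B) <- c(length(idx_b), k)
      d <- colMeans(A) - colMeans(B)
      S <- (crossprod(sweep(A, 2L, colMeans(A))) +
              crossprod(sweep(B, 2L, colMeans(B)))) / (n_a + n_b - 2L)
      sol <- tryCatch(solve(S, d), error = function(e) NULL)
      if (is.null(sol)) return(NA_real_)
      (n_a * n_b / (n_a + n_b)) * sum(d * sol)
    }, 0)
  }
  t2_obs <- t2_all(seq_len(n_a))
  ok <- is.finite(t2_obs)
  if (any(!ok))
    log_stage("hotelling", sprintf("%d region(s) excluded (singular pooled covariance)",
                                   sum(!ok)))
  exceed <- numeric(n_reg)
  withr::with_seed(seed, {
    for (p in seq_len(n_perm)) {
      idx_a <- sample.int(n_a + n_b, n_a)
      t2p <- t2_all(idx_a)
      exceed <- exceed + as.numeric(!is.na(t2p) & t2p >= t2_obs)
    }
  })
  pv <- (1 + exceed) / (1 + n_perm)
  pv[!ok] <- NA_real_
  qv <- rep(NA_real_, n_reg)
  qv[ok] <- fdr_bh(pv[ok])
  data.frame(region = seq_len(n_reg) - 1L, T2 = t2_obs, p = pv, q = qv,
             ok = ok)
}

#' Cross-validated linear regression of one map on component maps
#'
#' Five-fold cross-validated ordinary least squares predicting a per-region
#' target map (e.g. the intrinsic-timescale map) from region x component
#' predictors (e.g. the latency eigenvectors): regions are shuffled once
#' into folds, each fold is predicted from a model fit on the others, and
#' the held-out Pearson correlation is reported per fold.
#'
#' @param predictors region x k numeric matrix.
#' @param target per-region numeric vector.
#' @param n_folds folds (default 5).
#' @param seed integer seed for the fold shuffle.
#' @return list with `fold_r`, `mean_r`, `sd_r`, `folds` (assignments).
#' @export
cv_regress <- function(predictors, target, n_folds = 5L, seed = 1L) {
  predictors <- as.matrix(predictors)
  n <- nrow(predictors)
  stopifnot(length(target) == n)
  if (floor(n / n_folds) < ncol(predictors) + 2L)
    stop("folds too small for the number of predictors", call. = FALSE)
  folds <- withr::with_seed(seed,
    sample(rep_len(seq_len(n_folds), n)))
  fold_r <- vapply(seq_len(n_folds), function(f) {
    test <- folds == f
    fit <- stats::lm.fit(cbind(1, predictors[!test, , drop = FALSE]),
                         target[!test])
    pred <- cbind(1, predictors[test, , drop = FALSE]) %*% fit$coefficients
    stats::cor(as.numeric(pred), target[test])
  }, 0)
  list(fold_r = fold_r, mean_r = mean(fold_r), sd_r = stats::sd(fold_r),
       folds = folds)
}
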