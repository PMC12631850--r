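#' Fisher-z functional connectivity matrix
#'
#' Pairwise Pearson correlation between region time courses, r-to-z
#' (arctanh) transformed, with the diagonal set to zero. Correlations are
#' clipped to `1 - 1e-7` in magnitude before the transform so duplicated
#' regions yield a finite z of about 8.4 rather than infinity.
#'
#' @param ts a [parcellated_ts()] with at least 3 timepoints.
#' @return n x n numeric matrix.
#' @export
fc_matrix <- function(ts) {
  stopifnot(inherits(ts, "parcellated_ts"))
  if (n_timepoints(ts) < 3L) stop("need at least 3 timepoints", call. = FALSE)
  v <- apply(ts$data, 1L, stats::sd)
  if (any(v == 0))
    stop("zero-variance region id(s): ",
         paste(ts$region_ids[v == 0], collapse = ", "), call. = FALSE)
  r <- stats::cor(t(ts$data))
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  diag(z) <- 0
  dimnames(z) <- NULL
  z
}

#' Sparse cosine-similarity affinity matrix
#'
#' Per row of the FC matrix, only the top `keep_fraction` of entries (by
#' value) are retained and the rest zeroed; cosine similarity between the
#' sparsified rows forms the affinity, negatives are floored at zero, and
#' the result is symmetrized as `(W + t(W)) / 2`. The default keeps the top
#' 10% of each row.
#'
#' @param fc square FC matrix (e.g. from [fc_matrix()]).
#' @param keep_fraction fraction of row entries kept (default 0.10); must
#'   retain at least one entry.
#' @return object of class `affinity_matrix`: list with `W` and
#'   `keep_fraction`.
#' @export
build_affinity <- function(fc, keep_fraction = 0.10) {
  fc <- as.matrix(fc)
  n <- nrow(fc)
  if (ncol(fc) != n) stop("FC matrix must be square", call. = FALSE)
  if (keep_fraction <= 0 || keep_fraction > 1)
    stop("keep_fraction must retain between one entry and the full row",
         call. = FALSE)
  k <- ceiling(keep_fraction * n)
  sp <- fc
  if (k < n) {
    for (i in seq_len(n)) {
      row <- fc[i, ]
      # deterministic ties: larger value first, then smaller column index
      ord <- order(-row, seq_len(n))
      sp[i, ord[-seq_len(k)]] <- 0
    }
  }
  nr <- sqrt(rowSums(sp^2))
  nr[nr == 0] <- 1
  W <- tcrossprod(sp / nr)
  W[W < 0] <- 0
  diag(W) <- 0
  W <- (W + t(W)) / 2
  structure(list(W = W, keep_fraction = keep_fraction),
            class = "affinity_matrix")
}

#' @export
print.affinity_matrix <- function(x, ...) {
  cat(sprintf("<affinity_matrix> %d x %d, keep_fraction = %g, density = %.2f\n",
              nrow(x$W), ncol(x$W), x$keep_fraction,
              mean(x$W[upper.tri(x$W)] > 0)))
  invisible(x)
}

# connected components of a nonnegative symmetric matrix (label propagation)
graph_components <- function(W) {
  n <- nrow(W)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- which(W[v, ] > 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Diffusion map embedding of an affinity matrix
#'
#' Density-normalized diffusion maps: the kernel is re-normalized as
#' `W_alpha = D^-alpha W D^-alpha` (default `alpha = 0.5`, halfway between
#' graph Laplacian and Laplace-Beltrami normalization), converted to a
#' row-stochastic transition matrix and eigendecomposed. The trivial
#' constant eigenvector is dropped; component k is the k-th nontrivial right
#' eigenvector scaled by the diffusion-time convention — `lambda / (1 -
#' lambda)` at `t = 0`, `lambda^t` otherwise. Explained-variance shares are
#' the nontrivial eigenvalue shares. A disconnected affinity graph is an
#' error (regularize with a small epsilon before calling if needed).
#'
#' @param W an `affinity_matrix` (or bare nonnegative symmetric matrix).
#' @param n_components number of nontrivial components (default 3).
#' @param alpha density-normalization exponent (default 0.5).
#' @param diffusion_time diffusion time t; 0 (default) selects the
#'   `lambda / (1 - lambda)` scaling.
#' @param epsilon optional off-diagonal regularization added to `W` to
#'   reconnect an affinity whose sparsification severed all between-module
#'   edges (default 0: a disconnected graph is an error).
#' @return an [eigen_set()] with `method = "diffusion_map"`.
#' @export
diffusion_embedding <- function(W, n_components = 3L, alpha = 0.5,
                                diffusion_time = 0, epsilon = 0) {
  W <- if (inherits(W, "affinity_matrix")) W$W else as.matrix(W)
  n <- nrow(W)
  if (n_components > n - 1L)
    stop(sprintf("n_components must be <= n - 1 = %d", n - 1L), call. = FALSE)
  if (any(W < 0)) stop("affinity must be nonnegative", call. = FALSE)
  if (epsilon > 0) {
    W <- W + epsilon
    diag(W) <- 0
  }
  comp <- graph_components(W)
  if (max(comp) > 1L)
    stop("affinity graph is disconnected (components: ",
         paste(tabulate(comp), collapse = ", "),
         "); regularize before embedding", call. = FALSE)
  d <- rowSums(W)
  Wa <- W / outer(d^alpha, d^alpha)
  da <- rowSums(Wa)
  # transition matrix P = Da^-1 Wa; symmetrize as M = Da^-1/2 Wa Da^-1/2
  M <- Wa / outer(sqrt(da), sqrt(da))
  M <- (M + t(M)) / 2
  eg <- eigen(M, symmetric = TRUE)
  lam <- eg$values
  psi <- eg$vectors / sqrt(da)            # right eigenvectors of P
  # normalize against the trivial (constant) eigenvector
  psi <- psi / psi[1L, 1L]
  lam_k <- lam[2L:(n_components + 1L)]
  vecs <- psi[, 2L:(n_components + 1L), drop = FALSE]
  degenerate <- any(abs(lam_k) < 1e-12)
  scale_k <- if (diffusion_time == 0) {
    ifelse(abs(1 - lam_k) < 1e-12, 0, lam_k / (1 - lam_k))
  } else {
    lam_k^diffusion_time
  }
  vecs <- sweep(vecs, 2L, scale_k, `*`)
  pos <- pmax(lam[-1L], 0)
  ev <- if (sum(pos) > 0) pmax(lam_k, 0) / sum(pos) else rep(0, n_components)
  eigen_set(fix_component_signs(vecs), ev, method = "diffusion_map",
            degenerate = degenerate)
}

#' Functional gradients of a parcellated time series
#'
#' End-to-end gradient pipeline: Fisher-z FC ([fc_matrix()]), top-fraction
#' row sparsification with a cosine-similarity kernel ([build_affinity()]),
#' diffusion map embedding ([diffusion_embedding()]), and optional
#' Procrustes alignment to a template ([procrustes_align()]).
#'
#' @param ts a [parcellated_ts()].
#' @param keep_fraction row sparsity (default 0.10).
#' @param n_components gradients to keep (default 3).
#' @param alpha,diffusion_time embedding parameters.
#' @param template optional [eigen_set()] template to align to.
#' @return an [eigen_set()].
#' @export
gradients <- function(ts, keep_fraction = 0.10, n_components = 3L,
                      alpha = 0.5, diffusion_time = 0, template = NULL) {
  g <- diffusion_embedding(build_affinity(fc_matrix(ts), keep_fraction),
                           n_components = n_components, alpha = alpha,
                           diffusion_time = diffusion_time)
  if (!is.null(template)) g <- procrustes_align(g, template)
  g
}
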