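#' Latency eigenvectors of a time-delay matrix
#'
#' Reduces the antisymmetric latency matrix to a small set of per-region
#' component maps. With `method = "pca"` the columns of `tau` are
#' mean-centered (no variance scaling) and decomposed by SVD; component i is
#' the region-score vector of the i-th right singular direction and
#' explained-variance shares come from the squared singular values. For an
#' ideal lag-projection matrix `tau[i, j] = l[i] - l[j]` the centered matrix
#' is rank one and the first component reproduces `l` up to sign and scale.
#' With `method = "diffusion_map"` the rows of `tau` are converted to a
#' nonnegative cosine-similarity affinity (shifted by +1 so it is
#' nonnegative) and embedded as in [diffusion_embedding()].
#'
#' @param td a [time_delay_matrix_obj()] (or bare square matrix).
#' @param n_components number of components to keep (default 3).
#' @param method `"pca"` (default) or `"diffusion_map"`.
#' @return an [eigen_set()]. A zero input yields zero vectors with the
#'   `degenerate` flag set.
#' @export
latency_eigenvectors <- function(td, n_components = 3L,
                                 method = c("pca", "diffusion_map")) {
  method <- match.arg(method)
  tau <- if (inherits(td, "time_delay_matrix")) td$tau else as.matrix(td)
  n <- nrow(tau)
  if (n_components > n)
    stop(sprintf("n_components (%d) exceeds achievable rank (%d)",
                 n_components, n), call. = FALSE)
  if (max(abs(tau)) == 0) {
    return(eigen_set(matrix(0, n, n_components), rep(0, n_components),
                     method = if (method == "pca") "pca" else "diffusion_map",
                     degenerate = TRUE))
  }
  if (method == "pca") {
    xc <- sweep(tau, 2L, colMeans(tau))
    sv <- svd(xc, nu = n_components, nv = 0)
    d2 <- sv$d^2
    scores <- sv$u %*% diag(sv$d[seq_len(n_components)], n_components)
    scores <- fix_component_signs(scores)
    eigen_set(scores, d2[seq_len(n_components)] / sum(d2), method = "pca",
              degenerate = sum(d2) == 0)
  } else {
    aff <- tau_affinity(tau)
    diffusion_embedding(aff, n_components = n_components)
  }
}

# cosine similarity between rows of tau, shifted to nonnegative
tau_affinity <- function(tau) {
  nr <- sqrt(rowSums(tau^2))
  nr[nr == 0] <- 1
  cs <- tcrossprod(tau / nr)
  W <- cs + 1          # cosine in [-1,1] -> [0,2]
  diag(W) <- 0
  structure(list(W = (W + t(W)) / 2, keep_fraction = 1), class = "affinity_matrix")
}

# deterministic sign fix: the largest-|loading| region of each component is
# made positive
fix_component_signs <- function(scores) {
  for (k in seq_len(ncol(scores))) {
    i <- which.max(abs(scores[, k]))
    if (scores[i, k] < 0) scores[, k] <- -scores[, k]
  }
  scores
}

#' Orthogonal Procrustes alignment of component maps
#'
#' Rotates/reflects the source component matrix by the orthogonal matrix
#' minimizing the Frobenius distance to the template (no scaling, no
#' translation beyond the column centering already implicit in the
#' decompositions). Explained-variance shares are untouched: an orthogonal
#' mix of components redistributes, but never changes, the subspace.
#'
#' @param source,template [eigen_set()] objects with matching shapes.
#' @return the aligned `eigen_set` (with `aligned_to` recorded).
#' @export
procrustes_align <- function(source, template) {
  stopifnot(inherits(source, "eigen_set"), inherits(template, "eigen_set"))
  if (!all(dim(source$vectors) == dim(template$vectors)))
    stop("source and template shapes differ", call. = FALSE)
  R <- procrustes_rotation(source$vectors, template$vectors)
  out <- source
  out$vectors <- source$vectors %*% R
  out$aligned_to <- if (is.null(template$aligned_to)) "template" else
    template$aligned_to
  attr(out, "rotation") <- R
  out
}

# orthogonal matrix R minimizing ||S R - T||_F
procrustes_rotation <- function(S, T_) {
  sv <- svd(crossprod(S, T_))
  sv$u %*% t(sv$v)
}

#' Two-stage (chained) alignment of individuals across datasets
#'
#' Aligns each individual to a local (dataset-level) template, then re-targets
#' the composition to a reference template from another dataset — the scheme
#' used to match one cohort's eigenvectors to another's. Two successive
#' orthogonal maps compose into a single orthogonal map, applied in one
#' multiplication.
#'
#' @param individuals list of [eigen_set()] objects.
#' @param local_template,reference_template [eigen_set()] templates.
#' @return list of aligned `eigen_set` objects (empty input gives empty list).
#' @export
chained_alignment <- function(individuals, local_template, reference_template) {
  if (!length(individuals)) return(list())
  stopifnot(all(dim(local_template$vectors) == dim(reference_template$vectors)))
  R2 <- procrustes_rotation(local_template$vectors, reference_template$vectors)
  lapply(individuals, function(ind) {
    if (!all(dim(ind$vectors) == dim(local_template$vectors)))
      stop("individual/template shape mismatch", call. = FALSE)
    R1 <- procrustes_rotation(ind$vectors, local_template$vectors)
    out <- ind
    out$vectors <- ind$vectors %*% (R1 %*% R2)
    out$aligned_to <- "reference_template"
    out
  })
}

#' Group-template eigenvectors from averaged time-delay matrices
#'
#' Entrywise mean of the cohort's latency matrices (the mean of antisymmetric
#' matrices is antisymmetric, which is asserted) followed by
#' [latency_eigenvectors()].
#'
#' @param td_list nonempty list of [time_delay_matrix_obj()] of equal shape.
#' @param n_components,method passed to [latency_eigenvectors()].
#' @return an [eigen_set()].
#' @export
group_template <- function(td_list, n_components = 3L, method = "pca") {
  if (!length(td_list)) stop("empty time-delay matrix list", call. = FALSE)
  taus <- lapply(td_list, function(td)
    if (inherits(td, "time_delay_matrix")) td$tau else as.matrix(td))
  dims <- vapply(taus, nrow, 1L)
  if (length(unique(dims)) != 1L)
    stop("all time-delay matrices must share one shape", call. = FALSE)
  m <- Reduce(`+`, taus) / length(taus)
  stopifnot(max(abs(m + t(m))) <= 1e-10 * max(1, max(abs(m))))
  latency_eigenvectors(m, n_components = n_components, method = method)
}

#' Stratify a per-region map by functional network
#'
#' Summarizes a map over the seven intrinsic functional networks (and any
#' subcortical structure labels) of a [region_table()].
#'
#' @param map numeric vector, one value per region.
#' @param regions a [region_table()] of the same length.
#' @return data.frame with columns `network`, `mean`, `sd`, `n`, one row per
#'   label, ordered by label.
#' @export
stratify_by_network <- function(map, regions) {
  if (length(map) != nrow(regions))
    stop("map length must equal the region table length", call. = FALSE)
  labs <- regions$network
  out <- data.frame(
    network = sort(unique(labs)),
    stringsAsFactors = FALSE)
  out$mean <- vapply(out$network, function(l) mean(map[labs == l]), 0)
  out$sd <- vapply(out$network, function(l) {
    v <- map[labs == l]
    if (length(v) > 1L) stats::sd(v) else 0
  }, 0)
  out$n <- vapply(out$network, function(l) sum(labs == l), 0L)
  rownames(out) <- NULL
  out
}
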