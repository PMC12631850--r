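#' Parcellated BOLD time-series container
#'
#' The universal signal container of the package: a region x time real matrix
#' together with its sampling interval (TR, seconds). Rows are regions, columns
#' are time points; this region-major convention is used everywhere.
#'
#' @param data numeric matrix, regions in rows, time points in columns.
#' @param tr sampling interval in seconds (positive scalar).
#' @param region_ids optional integer vector of 0-based region ids aligned to a
#'   [region_table()]; defaults to `0:(nrow(data) - 1)`.
#' @return An object of class `parcellated_ts`: a list with elements `data`,
#'   `tr` and `region_ids`.
#' @examples
#' ts <- parcellated_ts(matrix(rnorm(40), 4, 10), tr = 0.72)
#' dim(ts)
#' @export
parcellated_ts <- function(data, tr, region_ids = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0)
    stop("`tr` must be a positive scalar (seconds)", call. = FALSE)
  if (anyNA(data) || any(!is.finite(data))) {
    bad <- which(apply(data, 1L, function(r) any(!is.finite(r)))) - 1L
    stop("time series contains non-finite values in region id(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(region_ids)) region_ids <- seq_len(nrow(data)) - 1L
  region_ids <- as.integer(region_ids)
  if (length(region_ids) != nrow(data))
    stop("`region_ids` length must equal the number of rows", call. = FALSE)
  structure(list(data = data, tr = tr, region_ids = region_ids),
            class = "parcellated_ts")
}

#' @export
dim.parcellated_ts <- function(x) dim(x$data)

#' @export
print.parcellated_ts <- function(x, ...) {
  cat(sprintf("<parcellated_ts> %d regions x %d timepoints, TR = %g s (%.1f s total)\n",
              nrow(x$data), ncol(x$data), x$tr, x$tr * ncol(x$data)))
  invisible(x)
}

#' Number of regions / timepoints of a time-series object
#' @param ts a `parcellated_ts`.
#' @return integer scalar.
#' @export
n_regions <- function(ts) nrow(ts$data)

#' @rdname n_regions
#' @export
n_timepoints <- function(ts) ncol(ts$data)

#' Parcel metadata table
#'
#' Validates and classes a parcel metadata table: region id, name, hemisphere,
#' intrinsic functional network, cortical flag, and a unit-sphere centroid used
#' by the spin permutation machinery.
#'
#' @param df a data.frame with columns `region_id` (0-based, consecutive),
#'   `name`, `hemisphere` (`"left"`, `"right"` or `"none"`), `network`,
#'   `is_cortical` (logical) and centroid columns `x`, `y`, `z`.
#' @return the validated data.frame with class `region_table` prepended.
#'   Centroids within `1e-6` of unit norm are re-normalized; larger deviations
#'   are an error.
#' @export
region_table <- function(df) {
  req <- c("region_id", "name", "hemisphere", "network", "is_cortical",
           "x", "y", "z")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("region table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df$region_id <- as.integer(df$region_id)
  if (anyDuplicated(df$region_id))
    stop("duplicate region_id values", call. = FALSE)
  if (!identical(sort(df$region_id), seq_len(nrow(df)) - 1L))
    stop("region_id values must be 0..n-1 with no gaps", call. = FALSE)
  df <- df[order(df$region_id), , drop = FALSE]
  if (!all(df$hemisphere %in% c("left", "right", "none")))
    stop("hemisphere must be one of left/right/none", call. = FALSE)
  df$is_cortical <- as.logical(df$is_cortical)
  if (any(df$is_cortical & !(df$hemisphere %in% c("left", "right"))))
    stop("every cortical region needs hemisphere left or right", call. = FALSE)
  cen <- as.matrix(df[, c("x", "y", "z")])
  nrm <- sqrt(rowSums(cen^2))
  if (any(abs(nrm - 1) > 1e-6)) {
    bad <- df$region_id[abs(nrm - 1) > 1e-6]
    stop("centroid norm deviates from 1 by more than 1e-6 for region id(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  df[, c("x", "y", "z")] <- cen / nrm
  rownames(df) <- NULL
  class(df) <- c("region_table", "data.frame")
  df
}

#' @export
print.region_table <- function(x, ...) {
  cat(sprintf("<region_table> %d regions (%d cortical), networks: %s\n",
              nrow(x), sum(x$is_cortical),
              paste(sort(unique(x$network)), collapse = ", ")))
  NextMethod()
}

#' Centroid coordinates of a region table
#' @param regions a `region_table`.
#' @return n x 3 numeric matrix of unit-sphere centroids.
#' @export
centroids <- function(regions) {
  as.matrix(regions[, c("x", "y", "z")])
}

#' Time-delay matrix container
#'
#' @param tau antisymmetric n x n latency matrix (seconds); `tau[i, j] > 0`
#'   means region i's signal leads region j's.
#' @param peak_cov symmetric n x n matrix of peak lagged cross-covariances
#'   (signal units squared).
#' @param threshold latency search bound (seconds).
#' @param flags optional n x n character matrix marking `"clipped"` or
#'   `"trough"` pairs (`""` otherwise).
#' @return object of class `time_delay_matrix`.
#' @export
time_delay_matrix_obj <- function(tau, peak_cov, threshold, flags = NULL) {
  tau <- as.matrix(tau)
  if (nrow(tau) != ncol(tau)) stop("tau must be square", call. = FALSE)
  if (max(abs(tau + t(tau))) > 1e-12 * max(1, max(abs(tau))))
    stop("tau must be antisymmetric", call. = FALSE)
  diag(tau) <- 0
  if (is.null(flags)) flags <- matrix("", nrow(tau), ncol(tau))
  structure(list(tau = tau, peak_cov = as.matrix(peak_cov),
                 threshold = threshold, flags = flags),
            class = "time_delay_matrix")
}

#' @export
print.time_delay_matrix <- function(x, ...) {
  cat(sprintf("<time_delay_matrix> %d x %d, threshold %g s, max |tau| = %.3f s, %d clipped pair(s)\n",
              nrow(x$tau), ncol(x$tau), x$threshold, max(abs(x$tau)),
              sum(x$flags == "clipped") %/% 2L))
  invisible(x)
}

#' Ordered eigenvector set
#'
#' Shared container for latency eigenvectors and functional-connectivity
#' gradients: a region x component score matrix with per-component
#' explained-variance shares.
#'
#' @param vectors region x component numeric matrix.
#' @param explained_variance numeric vector of per-component variance shares
#'   (non-increasing, each in `[0, 1]`, summing to at most 1).
#' @param method `"pca"` or `"diffusion_map"`.
#' @param aligned_to optional template identifier string.
#' @param degenerate logical; TRUE when the decomposition was degenerate
#'   (e.g. a zero input matrix).
#' @return object of class `eigen_set`.
#' @export
eigen_set <- function(vectors, explained_variance, method,
                      aligned_to = NULL, degenerate = FALSE) {
  vectors <- as.matrix(vectors)
  ev <- as.numeric(explained_variance)
  if (length(ev) != ncol(vectors))
    stop("one explained-variance entry per component required", call. = FALSE)
  if (any(ev < -1e-12) || any(ev > 1 + 1e-12) || sum(ev) > 1 + 1e-9)
    stop("explained_variance entries must lie in [0,1] and sum to <= 1",
         call. = FALSE)
  if (is.unsorted(rev(ev), strictly = FALSE) && any(diff(ev) > 1e-12))
    stop("explained_variance must be non-increasing", call. = FALSE)
  method <- match.arg(method, c("pca", "diffusion_map"))
  structure(list(vectors = vectors, explained_variance = pmin(pmax(ev, 0), 1),
                 method = method, aligned_to = aligned_to,
                 degenerate = isTRUE(degenerate)),
            class = "eigen_set")
}

#' @export
print.eigen_set <- function(x, ...) {
  cat(sprintf("<eigen_set> %d regions x %d components (%s)%s\n  explained variance: %s\n",
              nrow(x$vectors), ncol(x$vectors), x$method,
              if (x$degenerate) " [degenerate]" else "",
              paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", ")))
  invisible(x)
}
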