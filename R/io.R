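#' Read a parcellated time-series matrix from disk
#'
#' Accepts tab-delimited text (regions as rows, time as columns, no header) or
#' the binary array container written by [write_time_series()] (an `.rds`
#' file). Non-numeric cells and non-finite rows are hard errors naming the
#' offending cells.
#'
#' @param path file path (`.tsv`/`.txt` text or `.rds` binary).
#' @param tr sampling interval in seconds.
#' @return a [parcellated_ts()].
#' @export
read_time_series <- function(path, tr) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    mat <- readRDS(path)
    if (!is.matrix(mat)) stop("binary container does not hold a matrix", call. = FALSE)
    return(parcellated_ts(mat, tr = tr))
  }
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", comment.char = "")
  mat <- matrix(NA_real_, nrow(raw), ncol(raw))
  for (j in seq_len(ncol(raw))) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v) & !(raw[[j]] %in% c("NA", "NaN")))
    if (length(bad))
      stop(sprintf("non-numeric token %s at row %d, column %d of %s",
                   dQuote(raw[bad[1L], j]), bad[1L], j, path), call. = FALSE)
    mat[, j] <- v
  }
  bad_rows <- which(apply(mat, 1L, function(r) any(!is.finite(r))))
  if (length(bad_rows))
    stop("rows with NaN/NA values for region id(s): ",
         paste(bad_rows - 1L, collapse = ", "), call. = FALSE)
  parcellated_ts(mat, tr = tr)
}

#' Write a parcellated time-series matrix
#'
#' Text output keeps 15 significant digits so a text round-trip agrees to at
#' least 12 significant digits; the `.rds` container round-trips bit-exactly.
#'
#' @param ts a [parcellated_ts()] or bare matrix.
#' @param path destination; `.rds` selects the binary container, anything else
#'   tab-delimited text.
#' @return `path`, invisibly.
#' @export
write_time_series <- function(ts, path) {
  mat <- if (inherits(ts, "parcellated_ts")) ts$data else as.matrix(ts)
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    saveRDS(mat, path)
  } else {
    txt <- apply(mat, 1L, function(r) paste(sprintf("%.15g", r), collapse = "\t"))
    writeLines(txt, path)
  }
  invisible(path)
}

#' Read a parcel metadata table
#'
#' Tab-delimited with header; requires columns `region_id`, `name`,
#' `hemisphere`, `network`, `is_cortical`, `x`, `y`, `z` (unit-sphere
#' centroid). All [region_table()] invariants are enforced.
#'
#' @param path file path.
#' @return a [region_table()].
#' @export
read_region_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, comment.char = "")
  region_table(df)
}

#' @rdname read_region_table
#' @param regions a `region_table` to write.
#' @export
write_region_table <- function(regions, path) {
  utils::write.table(as.data.frame(regions), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a square matrix (tau, FC, affinity, ...) as TSV
#' @param mat numeric matrix.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  write_time_series(as.matrix(mat), path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  read_time_series(path, tr = 1)$data
}

#' Pipeline configuration
#'
#' Bundles every tunable of the analysis chain with the study defaults: a 5 s
#' latency threshold, three retained components, PCA reduction, top-10%
#' affinity sparsification and 1000 permutations.
#'
#' @param tr_seconds sampling interval (seconds).
#' @param latency_threshold_seconds latency search bound (seconds, default 5).
#' @param n_components components to retain (default 3).
#' @param reduction_method `"pca"` (default) or `"diffusion_map"`.
#' @param sparsity_keep_fraction per-row fraction of FC entries kept when
#'   building the affinity matrix (default 0.10).
#' @param n_permutations permutations for spin / label-permutation tests
#'   (default 1000).
#' @param rng_seed integer seed controlling every stochastic step.
#' @return object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(tr_seconds,
                            latency_threshold_seconds = 5,
                            n_components = 3L,
                            reduction_method = c("pca", "diffusion_map"),
                            sparsity_keep_fraction = 0.10,
                            n_permutations = 1000L,
                            rng_seed = 1L) {
  reduction_method <- match.arg(reduction_method)
  stopifnot(is.numeric(tr_seconds), tr_seconds > 0,
            latency_threshold_seconds > 0,
            n_components >= 1, sparsity_keep_fraction > 0,
            sparsity_keep_fraction <= 1, n_permutations >= 1)
  if (latency_threshold_seconds < tr_seconds)
    stop("latency_threshold_seconds must be >= tr_seconds", call. = FALSE)
  structure(list(tr_seconds = tr_seconds,
                 latency_threshold_seconds = latency_threshold_seconds,
                 n_components = as.integer(n_components),
                 reduction_method = reduction_method,
                 sparsity_keep_fraction = sparsity_keep_fraction,
                 n_permutations = as.integer(n_permutations),
                 rng_seed = as.integer(rng_seed)),
            class = "pipeline_config")
}

#' Read a YAML or JSON pipeline configuration file
#' @param path `.yaml`/`.yml` or `.json` file whose keys match the
#'   [pipeline_config()] arguments.
#' @param ... overrides applied on top of the file values.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  vals <- utils::modifyList(vals, list(...))
  do.call(pipeline_config, vals)
}

# one-line stage log; no silent defaults
log_stage <- function(stage, ..., t0 = NULL) {
  msg <- sprintf("[latstruct] %s: %s", stage, paste0(..., collapse = ""))
  if (!is.null(t0))
    msg <- sprintf("%s (%.2f s)", msg, as.numeric(proc.time()[3L]) - t0)
  message(msg)
  invisible(NULL)
}

#' Run the full latency-structure pipeline on a cohort
#'
#' Chains every stage on a set of subject time-series files: per-subject
#' time-delay matrices, a group-template eigendecomposition with Procrustes
#' alignment of individuals, per-subject intrinsic-timescale maps, functional
#' gradients aligned to a group template, spin-permutation association
#' statistics between the first latency eigenvector and the INT / gradient
#' maps, and a JSON run manifest sufficient to re-run identically.
#'
#' @param config a [pipeline_config()].
#' @param time_series_paths character vector of per-subject matrix files
#'   (see [read_time_series()]).
#' @param region_table_path path to the parcel metadata table.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly. Side effect: writes
#'   `tau_mean.tsv`, `peak_cov_mean.tsv`, `eigenvectors.tsv`,
#'   `explained_variance.tsv`, `int_map.tsv`, `gradients.tsv`,
#'   `stats.tsv`, `network_stratified.tsv` and `manifest.json`.
#' @export
run_pipeline <- function(config, time_series_paths, region_table_path, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  missing_in <- time_series_paths[!file.exists(time_series_paths)]
  if (length(missing_in))
    stop("missing input file(s): ", paste(missing_in, collapse = ", "),
         call. = FALSE)
  regions <- read_region_table(region_table_path)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  run_stage <- function(stage, expr) {
    t0 <- as.numeric(proc.time()[3L])
    res <- tryCatch(force(expr), error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE))
    log_stage(stage, "done", t0 = t0)
    res
  }

  cohort <- run_stage("read", lapply(time_series_paths, read_time_series,
                                     tr = config$tr_seconds))

  tds <- run_stage("latency", lapply(cohort, time_delay_matrix,
                                     threshold = config$latency_threshold_seconds))
  tau_mean <- Reduce(`+`, lapply(tds, `[[`, "tau")) / length(tds)
  write_matrix_tsv(tau_mean, file.path(out_dir, "tau_mean.tsv"))
  pk_mean <- Reduce(`+`, lapply(tds, `[[`, "peak_cov")) / length(tds)
  write_matrix_tsv(pk_mean, file.path(out_dir, "peak_cov_mean.tsv"))

  eig <- run_stage("eigen", {
    template <- group_template(tds, n_components = config$n_components,
                               method = config$reduction_method)
    aligned <- lapply(tds, function(td) {
      e <- latency_eigenvectors(td, n_components = config$n_components,
                                method = config$reduction_method)
      procrustes_align(e, template)
    })
    list(template = template, aligned = aligned)
  })
  write_matrix_tsv(eig$template$vectors, file.path(out_dir, "eigenvectors.tsv"))
  writeLines(sprintf("%.15g", eig$template$explained_variance),
             file.path(out_dir, "explained_variance.tsv"))

  int_tab <- run_stage("int", {
    fits <- lapply(cohort, int_map, cap = config$latency_threshold_seconds)
    t_mat <- sapply(fits, function(f) ifelse(f$converged, f$T, NA_real_))
    data.frame(region_id = regions$region_id,
               T_mean = rowMeans(t_mat, na.rm = TRUE),
               n_converged = rowSums(!is.na(t_mat)))
  })
  utils::write.table(int_tab, file.path(out_dir, "int_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  grad <- run_stage("gradient", {
    fc_mean <- Reduce(`+`, lapply(cohort, fc_matrix)) / length(cohort)
    aff <- build_affinity(fc_mean, keep_fraction = config$sparsity_keep_fraction)
    tryCatch(diffusion_embedding(aff, n_components = config$n_components),
             error = function(e) {
               if (!grepl("disconnected", conditionMessage(e))) stop(e)
               # sparsification severed all between-module edges; take the
               # documented epsilon-regularization path
               log_stage("gradient", "affinity disconnected; retrying with epsilon = 1e-6")
               diffusion_embedding(aff, n_components = config$n_components,
                                   epsilon = 1e-6)
             })
  })
  write_matrix_tsv(grad$vectors, file.path(out_dir, "gradients.tsv"))

  stats_tab <- run_stage("stats", {
    null <- build_spin_null(regions, n_perm = config$n_permutations,
                            seed = config$rng_seed)
    e1 <- eig$template$vectors[, 1L]
    rows <- lapply(list(int = int_tab$T_mean, gradient1 = grad$vectors[, 1L]),
                   function(map) {
                     ok <- is.finite(map)
                     st <- spin_test_correlation(e1, map, null,
                                                 cortical_only = TRUE,
                                                 regions = regions)
                     c(r = st$r, p = st$p)
                   })
    data.frame(map = names(rows),
               r = sapply(rows, `[[`, "r"),
               p_spin = sapply(rows, `[[`, "p"))
  })
  utils::write.table(stats_tab, file.path(out_dir, "stats.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  strat <- stratify_by_network(eig$template$vectors[, 1L], regions)
  utils::write.table(strat, file.path(out_dir, "network_stratified.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- list(
    package = "latstruct",
    version = as.character(utils::packageVersion("latstruct")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = unclass(config),
    inputs = list(time_series = basename(time_series_paths),
                  region_table = basename(region_table_path)),
    n_subjects = length(cohort))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
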