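# Delimited-text interchange: datasets with sidecar metadata, covariance
# matrices, and fit reports.

#' Read and write generated datasets
#'
#' Datasets are stored as CSV (header = variable names) with a JSON sidecar
#' (`<path>.meta.json`) recording the condition, seed and realized marginal
#' moments.
#'
#' @param dataset a `sem_dataset` from [generate_data()].
#' @param path CSV file path.
#' @return `read_dataset()` returns a `sem_dataset` (with a `NULL` condition
#'   if no sidecar is present).
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "sem_dataset"))
  utils::write.csv(as.data.frame(dataset$values), path, row.names = FALSE)
  meta <- list(condition = unclass(dataset$condition),
               realized_moments = dataset$realized_moments)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  values <- as.matrix(utils::read.csv(path, check.names = FALSE))
  meta_path <- paste0(path, ".meta.json")
  condition <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    condition <- condition_spec(meta$condition$source,
                                meta$condition$kurtosis,
                                meta$condition$N,
                                meta$condition$specification,
                                meta$condition$reps,
                                meta$condition$seed)
  }
  structure(list(values = values, condition = condition,
                 realized_moments = marginal_moments(values)),
            class = "sem_dataset")
}

#' Read or write a covariance matrix as CSV
#'
#' @param sigma covariance matrix.
#' @param path CSV file path.
#' @export
write_covariance <- function(sigma, path) {
  utils::write.csv(as.data.frame(sigma), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_covariance
#' @export
read_covariance <- function(path) {
  m <- as.matrix(utils::read.csv(path, check.names = FALSE))
  rownames(m) <- colnames(m)
  m
}

#' Fit report as key-value text
#'
#' Serializes an [analyze_sample()] result to a JSON report with parameter
#' estimates, discrepancy, statistics table and convergence diagnostics.
#'
#' @param analysis an [analyze_sample()] result.
#' @param path output file path.
#' @export
write_fit_report <- function(analysis, path) {
  fit <- analysis$fit
  rep <- list(
    converged = fit$converged,
    heywood = fit$heywood,
    iterations = fit$iterations,
    grad_norm = fit$grad_norm,
    F_ml = fit$F_ml, T_ml = fit$T_ml, df = fit$df, N = fit$N,
    loadings = fit$lambda, factor_corr = fit$phi,
    residual_vars = fit$psi,
    statistics = if (!is.null(analysis$table)) analysis$table)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
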