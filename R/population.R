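#' Population factor model
#'
#' Constructs the three-factor population model used throughout the package:
#' 15 standardized indicators loading on three correlated factors, with six
#' nonzero secondary loadings. Residual variances are defined so that every
#' indicator has unit variance, hence the population covariance matrix
#' \eqn{\Sigma_0 = \Lambda \Phi \Lambda' + \Theta} is a correlation matrix.
#'
#' @param loadings optional p x h loading matrix; defaults to the built-in
#'   15 x 3 pattern.
#' @param factor_corr optional h x h factor correlation matrix (unit
#'   diagonal, positive definite); defaults to the built-in 3 x 3 matrix.
#' @return An object of class `sem_population` with components `loadings`,
#'   `factor_corr`, `residual_vars`, `sigma0`.
#' @examples
#' pop <- population_model()
#' round(pop$sigma0[1, 2], 4)  # 0.4375
#' @export
population_model <- function(loadings = default_loadings(),
                             factor_corr = default_factor_corr()) {
  stopifnot(is.matrix(loadings), is.matrix(factor_corr),
            ncol(loadings) == nrow(factor_corr))
  sigma0 <- build_sigma0(loadings, factor_corr)
  structure(list(
    loadings = loadings,
    factor_corr = factor_corr,
    residual_vars = 1 - diag(loadings %*% factor_corr %*% t(loadings)),
    sigma0 = sigma0), class = "sem_population")
}

#' @rdname population_model
#' @export
default_loadings <- function() {
  lt <- rbind(
    c(.70, .70, .50, .45, .40,   0, .25,   0,   0,   0,   0,   0, -.25,   0,   0),
    c(  0, -.25,  0,   0,   0, .80, .65, .55, .50, .40,   0,   0,    0, .25,   0),
    c(  0,   0, .25,   0,   0,   0,   0,   0, -.25,  0, .70, .60,  .55, .50, .45))
  lam <- t(lt)
  dimnames(lam) <- list(paste0("x", 1:15), paste0("f", 1:3))
  lam
}

#' Load a population model from delimited text
#'
#' Reads the loading matrix and factor correlation matrix from CSV files
#' (first column: row labels; remaining columns: factors). The package ships
#' its built-in model in this format under `inst/extdata/`.
#'
#' @param loadings_path CSV with the p x h loading matrix.
#' @param factor_corr_path CSV with the h x h factor correlation matrix.
#' @return A [population_model()] object.
#' @examples
#' pop <- population_model_from_csv(
#'   system.file("extdata", "population_loadings.csv", package = "semlrt"),
#'   system.file("extdata", "population_factor_corr.csv", package = "semlrt"))
#' @export
population_model_from_csv <- function(loadings_path, factor_corr_path) {
  lam <- utils::read.csv(loadings_path, check.names = FALSE)
  phi <- utils::read.csv(factor_corr_path, check.names = FALSE)
  lam_m <- as.matrix(lam[, -1, drop = FALSE])
  rownames(lam_m) <- lam[[1]]
  phi_m <- as.matrix(phi[, -1, drop = FALSE])
  rownames(phi_m) <- phi[[1]]
  population_model(lam_m, phi_m)
}

#' @rdname population_model
#' @export
default_factor_corr <- function() {
  phi <- matrix(c(1, .3, .2,
                  .3, 1, .3,
                  .2, .3, 1), 3, 3)
  dimnames(phi) <- list(paste0("f", 1:3), paste0("f", 1:3))
  phi
}

#' Implied population covariance matrix
#'
#' \eqn{\Sigma_0 = \Lambda \Phi \Lambda' + \Theta} with \eqn{\Theta} diagonal
#' chosen so that all marginal variances are exactly one. Errors out if any
#' communality reaches one (a residual variance would be nonpositive).
#'
#' @inheritParams population_model
#' @return p x p covariance (here: correlation) matrix.
#' @export
build_sigma0 <- function(loadings, factor_corr) {
  ev <- eigen(factor_corr, symmetric = TRUE, only.values = TRUE)$values
  if (any(abs(diag(factor_corr) - 1) > 1e-12) || min(ev) <= 0)
    stop("factor_corr must be positive definite with unit diagonal")
  common <- loadings %*% factor_corr %*% t(loadings)
  if (any(diag(common) >= 1))
    stop("invalid model: communality >= 1 implies nonpositive residual variance")
  sigma0 <- common + diag(1 - diag(common))
  dimnames(sigma0) <- list(rownames(loadings), rownames(loadings))
  sigma0
}

#' Analysis model specifications
#'
#' A `cfa_spec` describes which loadings of a confirmatory factor model are
#' freely estimated. Factor variances are fixed to one for identification;
#' factor correlations and all residual variances are always free. The
#' built-in variants are
#' \describe{
#'   \item{`"correct"`}{all 21 nonzero population loadings free (q = 39,
#'     df = 81),}
#'   \item{`"misspecified"`}{only the 15 primary loadings free, no secondary
#'     loadings (q = 33, df = 87),}
#'   \item{`"null"`}{the independence model: no factors, free variances only
#'     (q = 15, df = 105).}
#' }
#'
#' @param specification one of `"correct"`, `"misspecified"`, `"null"`, or a
#'   logical p x h mask of free loadings.
#' @param p number of observed variables (only used for `"null"` / custom).
#' @return An object of class `cfa_spec` with fields `loading_mask`, `h`,
#'   `p`, `q`, `df`, `label`.
#' @examples
#' model_spec("misspecified")$df  # 87
#' @export
model_spec <- function(specification = c("correct", "misspecified", "null"),
                       p = 15) {
  if (is.matrix(specification)) {
    mask <- specification
    storage.mode(mask) <- "logical"
    label <- "custom"
  } else {
    specification <- match.arg(specification)
    label <- specification
    lam <- default_loadings()
    mask <- switch(specification,
      correct = lam != 0,
      misspecified = {
        m <- matrix(FALSE, 15, 3)
        m[cbind(1:15, rep(1:3, each = 5))] <- TRUE
        m
      },
      null = matrix(FALSE, p, 0))
  }
  p <- nrow(mask)
  h <- ncol(mask)
  q <- sum(mask) + h * (h - 1) / 2 + p
  df <- p * (p + 1) / 2 - q
  if (df <= 0) stop("model has nonpositive degrees of freedom")
  structure(list(loading_mask = mask, h = h, p = p, q = q, df = df,
                 label = label), class = "cfa_spec")
}

#' @export
print.cfa_spec <- function(x, ...) {
  cat(sprintf("cfa_spec '%s': p = %d, h = %d, q = %d, df = %d\n",
              x$label, x$p, x$h, x$q, x$df))
  invisible(x)
}

#' Population minimum of the ML discrepancy
#'
#' Minimizes the maximum-likelihood discrepancy of a model specification
#' against a population covariance matrix (the sample matrix is replaced by
#' \eqn{\Sigma_0}). Zero when the specification nests the population model;
#' positive under misspecification (the population misfit \eqn{F_0}).
#'
#' @param spec a [model_spec()] object.
#' @param sigma0 population covariance matrix.
#' @return Nonnegative scalar \eqn{F_0}.
#' @examples
#' pop <- population_model()
#' round(population_minimum(model_spec("misspecified"), pop$sigma0), 3)  # 0.328
#' @export
population_minimum <- function(spec, sigma0) {
  fit <- fit_cfa(spec, sigma0, N = 1000L)
  if (!fit$converged)
    stop("estimation failure in population minimization; gradient norm = ",
         format(fit$grad_norm))
  fit$F_ml
}

#' Population RMSEA
#'
#' \eqn{RMSEA_0 = \sqrt{F_0 / df}}.
#'
#' @param F0 population discrepancy (nonnegative).
#' @param df model degrees of freedom.
#' @export
rmsea0 <- function(F0, df) {
  if (F0 < 0) stop("F0 must be nonnegative")
  if (df <= 0) stop("df must be positive")
  sqrt(F0 / df)
}

#' Population CFI
#'
#' \eqn{CFI_0 = (F_{nm} - F_0) / F_{nm}} where \eqn{F_{nm}} is the population
#' discrepancy of the independence (null) model.
#'
#' @inheritParams rmsea0
#' @param F_nm population discrepancy of the null model (positive).
#' @export
cfi0 <- function(F0, F_nm) {
  if (F_nm <= 0) stop("null-model discrepancy must be positive")
  (F_nm - F0) / F_nm
}

#' Expected power of the likelihood-ratio test
#'
#' Survival probability of a noncentral chi-square with `df` degrees of
#' freedom and noncentrality \eqn{F_0 (N-1)} at the central chi-square
#' critical value. The (N-1) multiplier matches the Wishart likelihood-ratio
#' statistic \eqn{T_{ML} = \hat F (N-1)}.
#'
#' @inheritParams rmsea0
#' @param N sample size.
#' @param alpha nominal significance level.
#' @examples
#' pop <- population_model()
#' F0 <- population_minimum(model_spec("misspecified"), pop$sigma0)
#' round(expected_power(F0, 87, 200, .05), 3)  # 0.986
#' @export
expected_power <- function(F0, df, N, alpha = .05) {
  stopifnot(alpha > 0, alpha < 1, N > 1, df > 0, F0 >= 0)
  crit <- stats::qchisq(1 - alpha, df)
  stats::pchisq(crit, df, ncp = F0 * (N - 1), lower.tail = FALSE)
}
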