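# Asymptotic machinery for the corrected test statistics: the ADF fourth-
# moment matrix Gamma, the normal-theory weight matrix W, the residual
# weight matrix U, the eigenvalue weights of U Gamma, and the six test
# statistics with their p-values.

#' Asymptotic (ADF) covariance matrix of the sample covariances
#'
#' Estimates \eqn{\Gamma}, the asymptotic covariance matrix of
#' \eqn{\sqrt{N-1}(s - \sigma_0)}, from centered fourth moments:
#' \eqn{\hat\Gamma_{(ij),(kl)} = \hat m_{ijkl} - s_{ij} s_{kl}} with all
#' moments using the conventional biased divisor N. The result lives in the
#' shared vech basis and is positive semidefinite by construction.
#'
#' @param data N x p numeric matrix of raw observations.
#' @return p* x p* symmetric matrix.
#' @export
gamma_adf <- function(data) {
  data <- as.matrix(data)
  N <- nrow(data); p <- ncol(data)
  if (N <= p) warning("N <= p: the fourth-moment matrix will be singular")
  Y <- sweep(data, 2, colMeans(data))
  idx <- vech_index(p)
  Z <- Y[, idx[, 1], drop = FALSE] * Y[, idx[, 2], drop = FALSE]
  zbar <- colMeans(Z)
  crossprod(Z) / N - tcrossprod(zbar)
}

#' Normal-theory weight matrix
#'
#' The matrix with elements
#' \eqn{w_{(ij),(kl)} = \sigma_{ik}\sigma_{jl} + \sigma_{il}\sigma_{jk}}
#' in the shared vech basis, evaluated at a model-implied (or any positive
#' definite) covariance matrix. Under multivariate normality this is the
#' asymptotic covariance of the sample covariances, and its inverse is the
#' weight matrix whose WLS fit function is asymptotically equivalent to ML.
#'
#' @param sigma p x p positive definite covariance matrix.
#' @return p* x p* symmetric positive definite matrix.
#' @export
normal_theory_weight <- function(sigma) {
  p <- nrow(sigma)
  idx <- vech_index(p)
  i <- idx[, 1]; j <- idx[, 2]
  sigma[i, i] * sigma[j, j] + sigma[i, j] * sigma[j, i]
}

#' Residual weight matrix U
#'
#' \eqn{U = W^{-1} - W^{-1}\Delta(\Delta'W^{-1}\Delta)^{-1}\Delta'W^{-1}}.
#' U annihilates the model tangent space (\eqn{U\Delta = 0}) and has rank
#' \eqn{p^* - q}.
#'
#' @param w_hat normal-theory weight matrix ([normal_theory_weight()]).
#' @param delta_hat p* x q Jacobian ([delta_jacobian()]); may have zero
#'   columns (saturated-complement case), giving \eqn{U = W^{-1}}.
#' @return p* x p* symmetric positive semidefinite matrix.
#' @export
residual_u <- function(w_hat, delta_hat) {
  Wi <- chol2inv(chol(w_hat))
  if (is.null(delta_hat) || ncol(delta_hat) == 0) return(Wi)
  WiD <- Wi %*% delta_hat
  A <- crossprod(delta_hat, WiD)
  Ai <- tryCatch(solve(A), error = function(e)
    stop("Delta' W^-1 Delta is singular: model not identified"))
  U <- Wi - WiD %*% Ai %*% t(WiD)
  (U + t(U)) / 2
}

#' Eigenvalue weights of U Gamma
#'
#' The weights of the limiting chi-square mixture of the likelihood-ratio
#' statistic: the df largest eigenvalues of \eqn{\hat U \hat\Gamma}, computed
#' from the symmetric form
#' \eqn{\hat\Gamma^{1/2}\hat U\hat\Gamma^{1/2}}. Small negative eigenvalues
#' (numerical noise from a near-singular \eqn{\hat\Gamma}) are clipped at
#' zero with a warning.
#'
#' @param u_hat residual weight matrix ([residual_u()]).
#' @param gamma_hat ADF covariance matrix ([gamma_adf()]) or any symmetric
#'   positive semidefinite matrix in the same basis.
#' @param df number of weights to return (the model degrees of freedom).
#' @return Nonincreasing vector of df nonnegative weights.
#' @export
eigen_weights <- function(u_hat, gamma_hat, df) {
  eg <- eigen((gamma_hat + t(gamma_hat)) / 2, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  Gh <- eg$vectors %*% (sqrt(lam) * t(eg$vectors))   # symmetric sqrt
  M <- Gh %*% u_hat %*% Gh
  w <- sort(eigen((M + t(M)) / 2, symmetric = TRUE,
                  only.values = TRUE)$values, decreasing = TRUE)
  w <- w[seq_len(df)]
  clip <- 1e-10 * max(abs(w), 1)
  nneg <- sum(w < -clip)
  if (nneg > 0)
    warning(sprintf("%d negative eigenvalue weight(s) clipped at zero", nneg))
  if (sum(w > clip) < df)
    warning("fewer than df numerically nonzero eigenvalue weights")
  pmax(w, 0)
}

#' Traces of powers of U Gamma
#'
#' Computes \eqn{tr(UG)}, \eqn{tr[(UG)^2]}, \eqn{tr[(UG)^3]} directly from
#' matrix products, independently of the eigenvalue route.
#'
#' @inheritParams eigen_weights
#' @return Named list `t1`, `t2`, `t3`.
#' @export
ug_traces <- function(u_hat, gamma_hat) {
  A <- u_hat %*% gamma_hat
  A2 <- A %*% A
  list(t1 = sum(diag(A)), t2 = sum(diag(A2)), t3 = sum(A2 * t(A)))
}

# ---- corrected statistics ------------------------------------------------

#' Satorra-Bentler scaled statistic
#'
#' \eqn{T_M = T_{ML}/c} with \eqn{c = tr(\hat U\hat\Gamma)/df}, referred to a
#' central chi-square with df degrees of freedom.
#'
#' @param T_ml uncorrected likelihood-ratio statistic.
#' @param trace_ug trace of \eqn{\hat U \hat\Gamma}.
#' @param df model degrees of freedom.
#' @return List with `statistic`, `df`, `p_value`, and the scaling factor `c`.
#' @export
t_m <- function(T_ml, trace_ug, df) {
  if (trace_ug <= 0) stop("trace of U Gamma must be positive")
  cc <- trace_ug / df
  stat <- T_ml / cc
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE), c = cc)
}

#' Satorra-Bentler scaled statistic with Bartlett correction
#'
#' \eqn{T_{MB} = T_M\,[1 - (2p + 4h + 5) / (6(N-1))]}, referred to
#' chi-square(df).
#'
#' @param T_m_stat value of the scaled statistic \eqn{T_M}.
#' @param p number of observed variables.
#' @param h number of latent factors.
#' @param N sample size.
#' @inheritParams t_m
#' @export
t_mb <- function(T_m_stat, p, h, N, df) {
  fac <- 1 - (2 * p + 4 * h + 5) / (6 * (N - 1))
  if (fac <= 0) stop("Bartlett factor nonpositive: N too small")
  stat <- T_m_stat * fac
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE), bartlett = fac)
}

#' Mean-and-variance adjusted statistic (adjusted df)
#'
#' \eqn{T_{MV1} = d\,T_{ML}/tr(\hat U\hat\Gamma)} with
#' \eqn{d = [tr(\hat U\hat\Gamma)]^2 / tr[(\hat U\hat\Gamma)^2]}, referred to
#' chi-square(d); d is generally fractional.
#'
#' @inheritParams t_m
#' @param trace_ug2 trace of \eqn{(\hat U\hat\Gamma)^2}.
#' @export
t_mv1 <- function(T_ml, trace_ug, trace_ug2) {
  if (trace_ug <= 0 || trace_ug2 <= 0) stop("traces must be positive")
  d <- trace_ug^2 / trace_ug2
  stat <- d / trace_ug * T_ml
  list(statistic = stat, df = d,
       p_value = stats::pchisq(stat, d, lower.tail = FALSE), d = d)
}

#' Scale-and-shift adjusted statistic
#'
#' \eqn{T_{MV2} = T_{ML}\sqrt{df/tr[(\hat U\hat\Gamma)^2]} + df -
#' \sqrt{df\,[tr(\hat U\hat\Gamma)]^2 / tr[(\hat U\hat\Gamma)^2]}}, referred
#' to chi-square(df). The statistic can be negative for small \eqn{T_{ML}};
#' the upper-tail p-value is then close to one.
#'
#' @inheritParams t_mv1
#' @param df model degrees of freedom.
#' @export
t_mv2 <- function(T_ml, df, trace_ug, trace_ug2) {
  if (trace_ug <= 0 || trace_ug2 <= 0) stop("traces must be positive")
  stat <- T_ml * sqrt(df / trace_ug2) + df - sqrt(df * trace_ug^2 / trace_ug2)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       a = sqrt(trace_ug2 / df))
}

#' Third-moment adjusted statistic
#'
#' \eqn{T_{MS} = v\,T_{ML}/tr(\hat U\hat\Gamma)} with
#' \eqn{v = tr[(\hat U\hat\Gamma)^2]^3 / tr[(\hat U\hat\Gamma)^3]^2},
#' referred to chi-square(v): mean and skewness match the reference
#' distribution.
#'
#' @inheritParams t_mv1
#' @param trace_ug3 trace of \eqn{(\hat U\hat\Gamma)^3}.
#' @export
t_ms <- function(T_ml, trace_ug, trace_ug2, trace_ug3) {
  if (trace_ug <= 0 || trace_ug2 <= 0 || trace_ug3 <= 0)
    stop("traces must be positive")
  v <- trace_ug2^3 / trace_ug3^2
  stat <- v / trace_ug * T_ml
  list(statistic = stat, df = v,
       p_value = stats::pchisq(stat, v, lower.tail = FALSE), v = v)
}

#' Upper tail of a weighted chi-square mixture
#'
#' Survival function of \eqn{\sum_j w_j \chi^2_1} at `q`, evaluated by
#' numerical inversion of the characteristic function (Imhof's method). When
#' all weights are (numerically) equal the exact scaled chi-square tail is
#' returned; if the integration fails, a Monte Carlo fallback with `mc_draws`
#' draws is used.
#'
#' @param q quantile (the observed statistic).
#' @param weights nonnegative mixture weights, at least one positive.
#' @param mc_draws number of draws for the Monte Carlo fallback.
#' @return Upper-tail probability in `[0, 1]`.
#' @export
mixture_pvalue <- function(q, weights, mc_draws = 1e6) {
  w <- weights[weights > 0]
  if (length(w) == 0) stop("all mixture weights are zero")
  if (q <= 0) return(1)
  if (diff(range(w)) <= 1e-12 * max(w))    # equal weights: exact tail
    return(stats::pchisq(q / w[1], length(w), lower.tail = FALSE))
  integrand <- function(u) {
    th <- 0.5 * colSums(atan(outer(w, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(w^2, u^2))))
    sin(th) / (u * rho)
  }
  val <- tryCatch({
    I <- stats::integrate(integrand, 0, Inf, abs.tol = 1e-9,
                          rel.tol = 1e-8, subdivisions = 500L)
    0.5 + I$value / pi
  }, error = function(e) NA_real_)
  if (is.na(val) || val < -1e-6 || val > 1 + 1e-6) {
    acc <- numeric(mc_draws)
    for (wj in w) acc <- acc + wj * stats::rchisq(mc_draws, 1)
    val <- mean(acc >= q)
  }
  min(max(val, 0), 1)
}

#' All test statistics for one fitted model
#'
#' Computes the asymptotic matrices and the complete set of statistics
#' (ML, M, MB, MV1, MV2, MS, mix) with reference degrees of freedom,
#' p-values, and the scaling quantities used by the robust fit indices.
#'
#' @param fit a converged [fit_cfa()] result.
#' @param data the N x p raw data the covariance matrix was computed from.
#' @param gamma_hat optionally a precomputed [gamma_adf()] matrix (so the
#'   model and null model can share it).
#' @return An object of class `sem_tests`: data frame `table` (statistic,
#'   value, df_ref, p_value per test), plus `traces`, `weights`, `c`, `d`,
#'   `v`, `a`, `b`, `g`, `u_hat`, `gamma_hat`.
#' @export
test_statistics <- function(fit, data, gamma_hat = NULL) {
  stopifnot(inherits(fit, "cfa_fit"))
  if (is.null(gamma_hat)) gamma_hat <- gamma_adf(data)
  W <- normal_theory_weight(fit$sigma_hat)
  D <- delta_jacobian(fit$spec, fit$theta)
  U <- residual_u(W, D)
  tr <- ug_traces(U, gamma_hat)
  df <- fit$df; N <- fit$N; Tml <- fit$T_ml
  w <- eigen_weights(U, gamma_hat, df)

  m <- t_m(Tml, tr$t1, df)
  mb <- t_mb(m$statistic, fit$spec$p, fit$spec$h, N, df)
  mv1 <- t_mv1(Tml, tr$t1, tr$t2)
  mv2 <- t_mv2(Tml, df, tr$t1, tr$t2)
  ms <- t_ms(Tml, tr$t1, tr$t2, tr$t3)
  pmix <- mixture_pvalue(Tml, w)

  tab <- data.frame(
    statistic = c("ML", "M", "MB", "MV1", "MV2", "MS", "mix"),
    value = c(Tml, m$statistic, mb$statistic, mv1$statistic,
              mv2$statistic, ms$statistic, Tml),
    df_ref = c(df, df, df, mv1$d, df, ms$v, tr$t1),
    p_value = c(stats::pchisq(Tml, df, lower.tail = FALSE),
                m$p_value, mb$p_value, mv1$p_value, mv2$p_value,
                ms$p_value, pmix),
    row.names = NULL)
  structure(list(
    table = tab, traces = tr, weights = w,
    c = m$c, d = mv1$d, v = ms$v,
    a = mv2$a, b = tr$t1 / mv1$d, g = tr$t1 / ms$v,
    df = df, N = N, T_ml = Tml,
    u_hat = U, gamma_hat = gamma_hat), class = "sem_tests")
}

#' @export
print.sem_tests <- function(x, ...) {
  cat(sprintf("sem_tests: T_ml = %.3f, df = %d, c = %.4f\n",
              x$T_ml, x$df, x$c))
  print(transform(x$table, value = round(value, 3),
                  df_ref = round(df_ref, 2),
                  p_value = signif(p_value, 4)))
  invisible(x)
}
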