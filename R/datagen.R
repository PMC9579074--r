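# Non-normal multivariate data generation.
#
# Every indicator is the sum X_i = L_i + E_i of a correlated part L and an
# independent part E. The population covariance Sigma0 is preserved exactly
# in expectation under all four sources:
#
#   normal   -- multivariate normal via spectral factorization of Sigma0;
#   latent   -- L_i non-normal (NORTA with a quantile-mixture marginal and
#               the correlation structure of the common parts), E_i normal;
#   error    -- L_i normal with covariance Lambda Phi Lambda', E_i non-normal
#               independent (inverse-CDF transform);
#   marginal -- non-normality induced directly in the indicators by the
#               Vale-Maurelli (Fleishman polynomial) approach.
#
# Variance split: in the error condition Var(E_i) is exactly the residual
# variance theta_i. In the latent condition L_i carries
# v_i = max(communality_i + 0.1, 0.5): at least half the unit variance
# (keeping the required component kurtosis 3 + (k-3)/v_i^2 <= 59 for all
# printed component sets -- the communality split alone would demand up to
# ~550, beyond any printed component) and strictly more than the
# communality, so Cov(L) = Lambda Phi Lambda' + diag(v - c) is well
# conditioned and the NORTA intermediate correlations stay away from the
# comonotone boundary.

.semlrt_cache <- new.env(parent = emptyenv())

#' Simulation condition
#'
#' Bundles one cell of the simulation design: the source of non-normality,
#' the target marginal kurtosis (Pearson convention, normal = 3), the sample
#' size, the analysis-model specification status, the replication count and
#' the seed. `source = "marginal"` with `kurtosis = 3` is the multivariate
#' normal control and is normalized to `source = "normal"`.
#'
#' @param source one of `"latent"`, `"error"`, `"marginal"`, `"normal"`.
#' @param kurtosis target marginal kurtosis: 3, 10 or 17 in the study design
#'   (other values >= 3 are allowed).
#' @param N sample size per replication.
#' @param specification `"correct"` or `"misspecified"`.
#' @param reps number of Monte Carlo replications.
#' @param seed integer seed for the condition.
#' @return Object of class `condition_spec`.
#' @export
condition_spec <- function(source = c("latent", "error", "marginal", "normal"),
                           kurtosis = 3, N = 200,
                           specification = c("correct", "misspecified"),
                           reps = 1000L, seed = 1L) {
  source <- match.arg(source)
  specification <- match.arg(specification)
  stopifnot(kurtosis >= 3, N > 1, reps >= 0)
  if (source == "marginal" && kurtosis == 3) source <- "normal"
  if (source == "normal" && kurtosis != 3)
    stop("source = 'normal' requires kurtosis = 3")
  structure(list(source = source, kurtosis = kurtosis, N = as.integer(N),
                 specification = specification, reps = as.integer(reps),
                 seed = as.integer(seed)), class = "condition_spec")
}

#' Component sets per condition
#'
#' The inverse-CDF component lists used for each non-normal cell of the
#' design: t(4.1) + uniform (latent, k = 3); cubed normal + uniform + normal
#' (error, k = 3); log-normal(0,1) + exponential(1) (both sources at k = 10
#' and latent at k = 17); standard normal + a log-normal/negative-log-normal
#' probability mixture (error, k = 17; `signmix_q` sets the positive-branch
#' probability).
#'
#' @param source `"latent"` or `"error"`.
#' @param kurtosis 3, 10 or 17.
#' @param signmix_q positive-branch probability for the k = 17 error
#'   component.
#' @return List of component objects.
#' @export
condition_components <- function(source, kurtosis, signmix_q = 0.5) {
  stopifnot(source %in% c("latent", "error"))
  if (kurtosis == 3) {
    if (source == "latent") list(comp_t(4.1), comp_uniform())
    else list(comp_cubed_normal(), comp_uniform(), comp_normal())
  } else if (source == "latent" || kurtosis == 10) {
    list(comp_lnorm(), comp_exp())
  } else {
    list(comp_normal(), comp_lnorm_signmix(signmix_q))
  }
}

# closed-form kurtosis of the sign-mixture component as a function of q
signmix_kurt <- function(q_pos) {
  a <- exp((1:4)^2 / 2)
  m1 <- (2 * q_pos - 1) * a[1]
  v <- a[2] - m1^2
  m4c <- a[4] - 4 * m1 * (2 * q_pos - 1) * a[3] + 6 * m1^2 * a[2] - 3 * m1^4
  m4c / v^2
}

# smallest positive-branch probability giving ~5% headroom over the target
choose_signmix_q <- function(target_kurt) {
  k_half <- signmix_kurt(0.5)
  if (target_kurt <= k_half) return(0.5)
  k_max <- signmix_kurt(1)
  if (target_kurt > k_max - 0.2)
    stop(sprintf("component kurtosis target %.1f exceeds the log-normal cap %.1f",
                 target_kurt, k_max))
  want <- min(target_kurt * 1.05, k_max - 0.1)
  stats::uniroot(function(q) signmix_kurt(q) - want, c(0.5, 1),
                 tol = 1e-8)$root
}

# ---- NORTA ---------------------------------------------------------------

norta_nodes <- function(n = 48) {
  gh <- pracma::gaussHermite(n)
  list(z = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
}

# E[ qi(Phi(Z1)) qj(Phi(Z2)) ] for standardized quantiles under corr rho
bivariate_product_mean <- function(qi, qj, rho, nodes) {
  z <- nodes$z; w <- nodes$w
  gi <- qi(stats::pnorm(z))
  s <- sqrt(max(1 - rho^2, 0))
  acc <- 0
  for (b in seq_along(z)) {
    z2 <- rho * z + s * z[b]
    acc <- acc + w[b] * sum(w * gi * qj(stats::pnorm(z2)))
  }
  acc
}

#' Intermediate correlation for a NORTA pair
#'
#' Solves \eqn{E[F_i^{-1}(\Phi(Z_1)) F_j^{-1}(\Phi(Z_2))] = r} for the
#' correlation of the underlying bivariate normal, by bisection on a
#' Gauss-Hermite quadrature of the product mean.
#'
#' @param qi,qj standardized quantile functions of the two marginals.
#' @param r target product-moment correlation.
#' @param nodes quadrature nodes (internal).
#' @return Intermediate normal correlation in (-1, 1).
#' @export
norta_intermediate_corr <- function(qi, qj, r, nodes = norta_nodes()) {
  if (abs(r) < 1e-12) return(0)
  f <- function(rho) bivariate_product_mean(qi, qj, rho, nodes) - r
  lo <- -0.999; hi <- 0.999
  flo <- f(lo); fhi <- f(hi)
  if (flo * fhi > 0) {
    # saturate when the target sits just beyond the attainable range (this
    # happens during refinement sweeps for near-comonotone pairs)
    if (fhi < 0 && fhi > -0.05) return(hi)
    if (flo > 0 && flo < 0.05) return(lo)
    stop("intermediate-correlation search failed to bracket the target")
  }
  stats::uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi,
                 tol = 1e-5)$root
}

# nearest correlation by eigenvalue clipping + rescaling
make_psd_corr <- function(R, eps = 1e-8) {
  R <- (R + t(R)) / 2
  eg <- eigen(R, symmetric = TRUE)
  if (min(eg$values) >= eps) return(R)
  lam <- pmax(eg$values, eps)
  M <- eg$vectors %*% (lam * t(eg$vectors))
  d <- sqrt(diag(M))
  M / tcrossprod(d)
}

mvn_factor <- function(S) {
  eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
  eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), nrow(S))
}

#' Sample from a NORTA model
#'
#' Draws N observations whose columns have the supplied standardized
#' marginals and (approximately) the target product-moment correlation
#' matrix: a multivariate normal with pairwise-calibrated intermediate
#' correlations is pushed through the marginal quantile functions.
#' Rank-deficient targets are allowed; the assembled intermediate matrix is
#' repaired to the nearest correlation matrix by eigenvalue clipping.
#'
#' @param target_corr m x m target correlation matrix.
#' @param marginals list of m standardized quantile functions.
#' @param N sample size.
#' @param seed optional integer seed.
#' @param intermediate optional precomputed intermediate correlation matrix
#'   (skips the calibration).
#' @return N x m matrix.
#' @export
norta_sample <- function(target_corr, marginals, N, seed = NULL,
                         intermediate = NULL) {
  m <- nrow(target_corr)
  stopifnot(length(marginals) == m)
  if (is.null(intermediate))
    intermediate <- norta_intermediate_matrix(target_corr, marginals)
  if (!is.null(seed)) set.seed(seed)
  A <- mvn_factor(intermediate)
  Z <- matrix(stats::rnorm(N * m), N, m) %*% t(A)
  U <- stats::pnorm(Z)
  for (j in seq_len(m)) Z[, j] <- marginals[[j]](U[, j])
  Z
}

#' @rdname norta_sample
#' @param max_refine refinement sweeps compensating the positive-definiteness
#'   repair: the repaired matrix's implied product-moment correlations are
#'   evaluated by quadrature and the pairwise targets re-adjusted until the
#'   worst implied error falls below `5e-4` (or the sweeps are exhausted).
#' @export
norta_intermediate_matrix <- function(target_corr, marginals,
                                      max_refine = 4L) {
  m <- nrow(target_corr)
  nodes <- norta_nodes()
  solve_all <- function(tgt) {
    R <- diag(m)
    for (i in seq_len(m - 1)) for (j in seq((i + 1), m)) {
      R[i, j] <- R[j, i] <- norta_intermediate_corr(
        marginals[[i]], marginals[[j]], tgt[i, j], nodes)
    }
    make_psd_corr(R)
  }
  implied <- function(R) {
    out <- diag(m)
    for (i in seq_len(m - 1)) for (j in seq((i + 1), m)) {
      out[i, j] <- out[j, i] <- bivariate_product_mean(
        marginals[[i]], marginals[[j]], R[i, j], nodes)
    }
    out
  }
  tgt <- target_corr
  R <- solve_all(tgt)
  for (sweep in seq_len(max_refine)) {
    err <- implied(R) - target_corr
    if (max(abs(err)) < 5e-4) break
    tgt <- pmin(pmax(tgt - err, -0.999), 0.999)
    diag(tgt) <- 1
    R <- solve_all(tgt)
  }
  R
}

# ---- Vale-Maurelli -------------------------------------------------------

#' Fleishman polynomial coefficients
#'
#' Solves the Fleishman system for coefficients (a, b, c, d) such that
#' \eqn{Y = a + bZ + cZ^2 + dZ^3} (Z standard normal) has mean 0, variance
#' 1, and the requested skewness and kurtosis; a = -c by construction.
#'
#' @param skew target skewness.
#' @param kurt target (Pearson) kurtosis.
#' @return Named vector `c(a, b, c, d)`.
#' @export
fleishman_coefficients <- function(skew, kurt) {
  skew <- unname(skew); kurt <- unname(kurt)
  g2 <- kurt - 3
  eqs <- function(par) {
    b <- par[1]; cc <- par[2]; d <- par[3]
    c(b^2 + 6 * b * d + 2 * cc^2 + 15 * d^2 - 1,
      2 * cc * (b^2 + 24 * b * d + 105 * d^2 + 2) - skew,
      24 * (b * d + cc^2 * (1 + b^2 + 28 * b * d) +
              d^2 * (12 + 48 * b * d + 141 * cc^2 + 225 * d^2)) - g2)
  }
  par <- c(1, 0.15 * skew, 0.05)
  for (it in 1:200) {
    f0 <- eqs(par)
    if (max(abs(f0)) < 1e-12) break
    J <- matrix(0, 3, 3)
    hstep <- 1e-7
    for (k in 1:3) {
      ph <- par; ph[k] <- ph[k] + hstep
      J[, k] <- (eqs(ph) - f0) / hstep
    }
    step <- tryCatch(solve(J, f0), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1
    repeat {
      pn <- par - lam * step
      if (max(abs(eqs(pn))) < max(abs(f0)) || lam < 1e-6) break
      lam <- lam / 2
    }
    par <- pn
  }
  if (max(abs(eqs(par))) > 1e-6)
    stop(sprintf("Fleishman system infeasible for skew %.3f, kurtosis %.3f",
                 skew, kurt))
  c(a = -par[2], b = par[1], c = par[2], d = par[3])
}

# intermediate correlation for a Vale-Maurelli pair: solve the cubic
# r = rho(b1 b2 + 3 b1 d2 + 3 d1 b2 + 9 d1 d2) + rho^2 (2 c1 c2)
#     + rho^3 (6 d1 d2)
vm_intermediate_corr <- function(coef1, coef2, r) {
  k1 <- coef1["b"] * coef2["b"] + 3 * coef1["b"] * coef2["d"] +
    3 * coef1["d"] * coef2["b"] + 9 * coef1["d"] * coef2["d"]
  k2 <- 2 * coef1["c"] * coef2["c"]
  k3 <- 6 * coef1["d"] * coef2["d"]
  f <- function(rho) k1 * rho + k2 * rho^2 + k3 * rho^3 - r
  stats::uniroot(f, c(-1, 1), extendInt = "yes", tol = 1e-10)$root
}

# ---- per-condition calibration (cached) ----------------------------------

latent_variance_share <- function(pop)
  pmax(1 - pop$residual_vars + 0.1, 0.5)

calibrate_condition <- function(source, kurtosis, pop) {
  key <- paste(source, kurtosis, sep = "_")
  if (!is.null(.semlrt_cache[[key]])) return(.semlrt_cache[[key]])
  p <- nrow(pop$sigma0)
  common <- pop$loadings %*% pop$factor_corr %*% t(pop$loadings)
  cal <- switch(source,
    normal = list(factor = mvn_factor(pop$sigma0)),
    latent = {
      v <- latent_variance_share(pop)
      covL <- common; diag(covL) <- v
      RG <- covL / tcrossprod(sqrt(v))
      mixes <- lapply(seq_len(p), function(i)
        fit_mixture_weights(condition_components("latent", kurtosis),
                            kurtosis, variance_share = v[i]))
      RZ <- norta_intermediate_matrix(RG, lapply(mixes, `[[`, "q"))
      list(v = v, mixes = mixes, RG = RG,
           factor = mvn_factor(RZ),
           skew_x = v^1.5 * vapply(mixes, `[[`, 0, "skew"))
    },
    error = {
      th <- pop$residual_vars
      mixes <- lapply(seq_len(p), function(i) {
        comps <- if (kurtosis == 17) {
          kt <- 3 + (kurtosis - 3) / th[i]^2
          condition_components("error", kurtosis,
                               signmix_q = choose_signmix_q(kt))
        } else condition_components("error", kurtosis)
        fit_mixture_weights(comps, kurtosis, variance_share = th[i])
      })
      list(theta = th, mixes = mixes,
           chol_phi = chol(pop$factor_corr),
           skew_x = th^1.5 * vapply(mixes, `[[`, 0, "skew"))
    },
    marginal = {
      lat <- calibrate_condition("latent", kurtosis, pop)
      coefs <- lapply(seq_len(p), function(i)
        fleishman_coefficients(lat$skew_x[i], kurtosis))
      R <- diag(p)
      for (i in seq_len(p - 1)) for (j in seq((i + 1), p))
        R[i, j] <- R[j, i] <- vm_intermediate_corr(
          coefs[[i]], coefs[[j]], pop$sigma0[i, j])
      list(coefs = coefs, factor = mvn_factor(make_psd_corr(R)),
           skew_x = lat$skew_x)
    })
  .semlrt_cache[[key]] <- cal
  cal
}

#' Generate one sample
#'
#' Draws an N x p data set with population covariance \eqn{\Sigma_0} whose
#' non-normality originates from the source named in the condition. Marginal
#' calibration (mixture weights, NORTA intermediate correlations, Fleishman
#' coefficients) is deterministic and cached per (source, kurtosis) cell.
#'
#' @param condition a [condition_spec()].
#' @param pop a [population_model()].
#' @param seed integer seed; identical condition + seed gives an identical
#'   data set.
#' @return Object of class `sem_dataset`: `values` (N x p matrix),
#'   `condition`, and `realized_moments` (per-variable mean, variance,
#'   skewness, kurtosis).
#' @export
generate_data <- function(condition, pop = population_model(),
                          seed = condition$seed) {
  stopifnot(inherits(condition, "condition_spec"))
  p <- nrow(pop$sigma0)
  N <- condition$N
  cal <- calibrate_condition(condition$source, condition$kurtosis, pop)
  set.seed(seed)
  X <- switch(condition$source,
    normal = matrix(stats::rnorm(N * p), N, p) %*% t(cal$factor),
    latent = {
      Z <- matrix(stats::rnorm(N * p), N, p) %*% t(cal$factor)
      U <- stats::pnorm(Z)
      G <- vapply(seq_len(p), function(j) cal$mixes[[j]]$q(U[, j]),
                  numeric(N))
      E <- matrix(stats::rnorm(N * p), N, p)
      G %*% diag(sqrt(cal$v), p) + E %*% diag(sqrt(1 - cal$v), p)
    },
    error = {
      f <- matrix(stats::rnorm(N * ncol(pop$loadings)),
                  N, ncol(pop$loadings)) %*% cal$chol_phi
      L <- f %*% t(pop$loadings)
      U <- matrix(stats::runif(N * p), N, p)
      E <- vapply(seq_len(p), function(j) cal$mixes[[j]]$q(U[, j]),
                  numeric(N))
      L + E %*% diag(sqrt(cal$theta), p)
    },
    marginal = {
      Z <- matrix(stats::rnorm(N * p), N, p) %*% t(cal$factor)
      vapply(seq_len(p), function(j) {
        cf <- cal$coefs[[j]]
        cf["a"] + cf["b"] * Z[, j] + cf["c"] * Z[, j]^2 + cf["d"] * Z[, j]^3
      }, numeric(N))
    })
  if (!all(is.finite(X))) stop("generation error: non-finite draws")
  colnames(X) <- rownames(pop$loadings)
  structure(list(values = X, condition = condition,
                 realized_moments = marginal_moments(X)),
            class = "sem_dataset")
}

#' Per-variable sample moments
#'
#' Mean, variance, skewness and Pearson kurtosis of each column.
#'
#' @param x numeric matrix.
#' @return Data frame with one row per column.
#' @export
marginal_moments <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  m2 <- colMeans(xc^2)
  data.frame(variable = colnames(x) %||% paste0("V", seq_len(ncol(x))),
             mean = mu, variance = m2,
             skewness = colMeans(xc^3) / m2^1.5,
             kurtosis = colMeans(xc^4) / m2^2, row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mardia's multivariate kurtosis
#'
#' \eqn{b_{2,p} = E[(x - \bar x)' S^{-1} (x - \bar x)]^2}; equals
#' \eqn{p(p+2)} under multivariate normality.
#'
#' @param x numeric data matrix.
#' @export
mardia_kurtosis <- function(x) {
  x <- as.matrix(x)
  xc <- sweep(x, 2, colMeans(x))
  S <- crossprod(xc) / nrow(x)
  d <- rowSums((xc %*% solve(S)) * xc)
  mean(d^2)
}
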