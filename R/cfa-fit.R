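# Normal-theory ML estimation of confirmatory factor models.
#
# Parameter vector ordering (shared with delta_jacobian): free loadings
# (column-major over the mask), factor correlations (lower triangle of Phi,
# column-major), residual variances. Factor variances are fixed to 1.

theta_split <- function(spec, theta) {
  nl <- sum(spec$loading_mask)
  h <- spec$h
  nc <- h * (h - 1) / 2
  lam <- matrix(0, spec$p, h)
  lam[spec$loading_mask] <- theta[seq_len(nl)]
  phi <- diag(h)
  if (nc > 0) {
    phi[lower.tri(phi)] <- theta[nl + seq_len(nc)]
    phi[upper.tri(phi)] <- t(phi)[upper.tri(phi)]
  }
  list(lambda = lam, phi = phi, psi = theta[nl + nc + seq_len(spec$p)])
}

sigma_of_theta <- function(spec, theta) {
  pp <- theta_split(spec, theta)
  if (spec$h == 0) return(diag(pp$psi, spec$p))
  pp$lambda %*% pp$phi %*% t(pp$lambda) + diag(pp$psi)
}

start_values <- function(spec, S = NULL) {
  # Primary loadings (largest per row of the mask pattern, read as first free
  # slot) start at .5, further loadings on the same indicator at 0, factor
  # correlations at .2, residual variances at .5.
  mask <- spec$loading_mask
  lam0 <- matrix(0, spec$p, spec$h)
  if (spec$h > 0) {
    prim <- if (spec$p == 15 && spec$h == 3) rep(1:3, each = 5)
            else apply(mask, 1, function(r) which(r)[1])
    for (i in seq_len(spec$p)) {
      j <- prim[i]
      if (!is.na(j) && mask[i, j]) lam0[i, j] <- .5
      else if (any(mask[i, ])) lam0[i, which(mask[i, ])[1]] <- .5
    }
  }
  c(lam0[mask], rep(.2, spec$h * (spec$h - 1) / 2), rep(.5, spec$p))
}

fml_value <- function(spec, theta, S, logdetS) {
  Sg <- sigma_of_theta(spec, theta)
  ch <- tryCatch(chol(Sg), error = function(e) NULL)
  if (is.null(ch)) return(1e10)
  ldSg <- 2 * sum(log(diag(ch)))
  iSg <- chol2inv(ch)
  ldSg - logdetS + sum(S * iSg) - spec$p
}

fml_grad <- function(spec, theta, S, logdetS) {
  pp <- theta_split(spec, theta)
  Sg <- sigma_of_theta(spec, theta)
  ch <- tryCatch(chol(Sg), error = function(e) NULL)
  if (is.null(ch)) return(rep(0, length(theta)))
  iSg <- chol2inv(ch)
  G <- iSg - iSg %*% S %*% iSg          # dF = tr(G dSigma)
  out <- numeric(0)
  if (spec$h > 0) {
    gl <- 2 * (G %*% pp$lambda %*% pp$phi)      # d/d lambda_ij
    gphi <- 2 * (t(pp$lambda) %*% G %*% pp$lambda)
    out <- c(gl[spec$loading_mask], gphi[lower.tri(gphi)])
  }
  c(out, diag(G))
}

#' Fit a confirmatory factor model by maximum likelihood
#'
#' Minimizes the normal-theory ML discrepancy
#' \eqn{F_{ML} = \ln|\Sigma(\theta)| - \ln|S| + tr[S\,\Sigma(\theta)^{-1}] - p}
#' over the free parameters of `spec`, using analytic gradients. Residual
#' variances are bounded below at `1e-6` (an active bound is flagged as a
#' Heywood case), factor correlations at +/- 0.995.
#'
#' @param spec a [model_spec()] object.
#' @param S sample (or population) covariance matrix, positive definite.
#' @param N sample size used to scale the test statistic.
#' @param start optional start vector; defaults to a neutral scheme (primary
#'   loadings 0.5, secondary 0, correlations 0.2, residual variances 0.5) so
#'   refits are reproducible.
#' @param grad_tol gradient infinity-norm required to declare convergence.
#' @param max_iter iteration budget for the optimizer.
#' @return An object of class `cfa_fit`: `theta`, `lambda`, `phi`, `psi`,
#'   `sigma_hat`, `F_ml`, `T_ml`, `df`, `N`, `converged`, `heywood`,
#'   `iterations`, `grad_norm`.
#' @examples
#' pop <- population_model()
#' fit <- fit_cfa(model_spec("correct"), pop$sigma0, N = 200)
#' fit$F_ml  # ~0: the correct specification reproduces sigma0
#' @export
fit_cfa <- function(spec, S, N, start = NULL,
                    grad_tol = 1e-6, max_iter = 500L) {
  stopifnot(inherits(spec, "cfa_spec"), is.matrix(S),
            nrow(S) == spec$p, ncol(S) == spec$p, N > 1)
  if (max(abs(S - t(S))) > 1e-8) stop("S must be symmetric")
  chS <- tryCatch(chol(S), error = function(e)
    stop("S must be positive definite"))
  logdetS <- 2 * sum(log(diag(chS)))

  if (is.null(start)) start <- start_values(spec, S)
  nl <- sum(spec$loading_mask)
  nc <- spec$h * (spec$h - 1) / 2
  lower <- c(rep(-Inf, nl), rep(-.995, nc), rep(1e-6, spec$p))
  upper <- c(rep(Inf, nl), rep(.995, nc), rep(Inf, spec$p))

  proj_grad <- function(theta) {
    g <- fml_grad(spec, theta, S, logdetS)
    # at an active bound the projected gradient is what matters
    ifelse(theta <= lower + 1e-10 & g > 0, 0, g)
  }
  opt <- stats::nlminb(start, fml_value, gradient = fml_grad,
                       spec = spec, S = S, logdetS = logdetS,
                       lower = lower, upper = upper,
                       control = list(iter.max = max_iter,
                                      eval.max = 4L * max_iter,
                                      rel.tol = 1e-12))
  # Newton polish on interior parameters: drives the gradient norm to ~1e-10
  # where nlminb stops at its own precision floor
  iters <- opt$iterations
  theta <- opt$par
  fcur <- opt$objective
  for (polish in 1:10) {
    g <- proj_grad(theta)
    if (max(abs(g)) < 1e-10) break
    interior <- theta > lower + 1e-8 & theta < upper - 1e-8
    if (!any(interior)) break
    gi <- fml_grad(spec, theta, S, logdetS)
    H <- matrix(0, sum(interior), sum(interior))
    hstep <- 1e-6
    ii <- which(interior)
    for (k in seq_along(ii)) {
      tp <- theta; tp[ii[k]] <- tp[ii[k]] + hstep
      H[, k] <- (fml_grad(spec, tp, S, logdetS)[ii] - gi[ii]) / hstep
    }
    H <- (H + t(H)) / 2
    step <- tryCatch(solve(H, gi[ii]), error = function(e) NULL)
    if (is.null(step)) break
    lam <- 1; improved <- FALSE
    repeat {
      tn <- theta; tn[ii] <- tn[ii] - lam * step
      tn <- pmin(pmax(tn, lower), upper)
      fn <- fml_value(spec, tn, S, logdetS)
      if (fn <= fcur + 1e-14) { improved <- TRUE; break }
      lam <- lam / 2
      if (lam < 1e-4) break
    }
    if (!improved) break
    theta <- tn; fcur <- fn; iters <- iters + 1L
  }
  opt$par <- theta
  opt$objective <- fcur
  opt$iterations <- iters
  theta <- opt$par
  psi <- theta_split(spec, theta)$psi
  heywood <- any(psi <= 1e-6 + 1e-10)
  grad_norm <- max(abs(proj_grad(theta)))
  F_ml <- max(0, fml_value(spec, theta, S, logdetS))
  pp <- theta_split(spec, theta)
  structure(list(
    theta = theta, lambda = pp$lambda, phi = pp$phi, psi = pp$psi,
    sigma_hat = sigma_of_theta(spec, theta),
    F_ml = F_ml, T_ml = F_ml * (N - 1), df = spec$df, N = N,
    spec = spec,
    converged = opt$convergence == 0 || grad_norm < grad_tol,
    heywood = heywood, iterations = opt$iterations,
    grad_norm = grad_norm), class = "cfa_fit")
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat(sprintf(
    "cfa_fit (%s): F_ml = %.6f, T_ml = %.3f, df = %d, N = %d, %s%s\n",
    x$spec$label, x$F_ml, x$T_ml, x$df, x$N,
    if (x$converged) "converged" else "NOT converged",
    if (x$heywood) " [Heywood]" else ""))
  invisible(x)
}

#' Likelihood-ratio test statistic
#'
#' \eqn{T_{ML} = \hat F_{ML} (N - 1)}.
#'
#' @param fit a [fit_cfa()] result.
#' @export
t_ml <- function(fit) {
  stopifnot(inherits(fit, "cfa_fit"))
  fit$F_ml * (fit$N - 1)
}

#' Jacobian of the model-implied covariance
#'
#' Analytic derivatives \eqn{\Delta = \partial\sigma/\partial\theta'} of the
#' half-vectorized model-implied covariance with respect to the free
#' parameters, in the shared vech basis.
#'
#' @inheritParams fit_cfa
#' @param theta parameter vector at which to evaluate.
#' @return p* x q matrix.
#' @export
delta_jacobian <- function(spec, theta) {
  p <- spec$p
  pp <- theta_split(spec, theta)
  idx <- vech_index(p)
  cols <- vector("list", spec$q)
  k <- 0L
  if (spec$h > 0) {
    lamphi <- pp$lambda %*% pp$phi
    free <- which(spec$loading_mask, arr.ind = TRUE)
    free <- free[order(free[, 2], free[, 1]), , drop = FALSE]
    for (r in seq_len(nrow(free))) {
      i <- free[r, 1]; j <- free[r, 2]
      d <- matrix(0, p, p)
      a <- lamphi[, j]
      d[i, ] <- d[i, ] + a
      d[, i] <- d[, i] + a
      k <- k + 1L; cols[[k]] <- d[cbind(idx[, 1], idx[, 2])]
    }
    ph <- which(lower.tri(pp$phi), arr.ind = TRUE)
    ph <- ph[order(ph[, 2], ph[, 1]), , drop = FALSE]
    for (r in seq_len(nrow(ph))) {
      lj <- pp$lambda[, ph[r, 2]]; lk <- pp$lambda[, ph[r, 1]]
      d <- tcrossprod(lj, lk) + tcrossprod(lk, lj)
      k <- k + 1L; cols[[k]] <- d[cbind(idx[, 1], idx[, 2])]
    }
  }
  for (i in seq_len(p)) {
    d <- matrix(0, p, p); d[i, i] <- 1
    k <- k + 1L; cols[[k]] <- d[cbind(idx[, 1], idx[, 2])]
  }
  D <- do.call(cbind, cols)
  if (qr(D)$rank < ncol(D))
    warning("Jacobian is rank deficient: model may not be identified")
  D
}
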