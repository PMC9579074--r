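# Quantile-mixture marginal distributions.
#
# A target marginal is built as a weighted sum of inverse cumulative
# distribution functions, F^-1(u) = sum_m beta_m F_m^-1(u) with beta on the
# simplex (a comonotone combination, so F^-1 is nondecreasing). Components
# are standardized to mean 0 / variance 1 before mixing and the mixture is
# standardized again, so only its shape (skewness, kurtosis) is tuned.
#
# Moments of the mixture are polynomial in beta with coefficients given by
# cross moments E[Q_a Q_b ...] of the standardized component quantiles under
# a shared uniform. Pure power moments use closed forms where available --
# essential for the t(4.1) component, whose fourth moment (kurtosis 63) has
# a large share of its mass beyond double-precision quantile range, so any
# quadrature in u- or z-space underestimates it severely. Mixed products
# have milder tails and are integrated adaptively on the z = qnorm(u) scale.

#' Mixture component distributions
#'
#' Constructors for the inverse-CDF components used by the data generator.
#' Each returns a list with a vectorized quantile function `q`, the raw mean
#' and standard deviation used for standardization, and exact standardized
#' third/fourth moments where known (`skew`, `kurt`; `NA` means "compute by
#' quadrature").
#'
#' `comp_lnorm_signmix(q_pos)` is the probability mixture that takes a
#' log-normal(0,1) value with probability `q_pos` and its negative mirror
#' image otherwise; its quantile function is obtained by monotone
#' interpolation of the numerically inverted CDF.
#'
#' @param df degrees of freedom of the t component.
#' @param q_pos probability of the positive (log-normal) branch.
#' @name mixture_components
NULL

#' @rdname mixture_components
#' @export
comp_normal <- function()
  list(name = "normal", q = stats::qnorm, mean = 0, sd = 1, skew = 0, kurt = 3)

#' @rdname mixture_components
#' @export
comp_uniform <- function()
  list(name = "uniform", q = function(u) u, mean = .5, sd = sqrt(1 / 12),
       skew = 0, kurt = 1.8)

#' @rdname mixture_components
#' @export
comp_t <- function(df = 4.1) {
  if (df <= 4) stop("t component needs df > 4 for a finite fourth moment")
  list(name = sprintf("t%g", df), q = function(u) stats::qt(u, df),
       mean = 0, sd = sqrt(df / (df - 2)), skew = 0, kurt = 3 + 6 / (df - 4))
}

#' @rdname mixture_components
#' @export
comp_cubed_normal <- function()
  # Z^3 for standard normal Z; E[Z^6] = 15, E[Z^12] = 10395
  list(name = "cubed_normal", q = function(u) stats::qnorm(u)^3,
       mean = 0, sd = sqrt(15), skew = 0, kurt = 10395 / 225)

#' @rdname mixture_components
#' @export
comp_lnorm <- function() {
  e <- exp(1)
  list(name = "lnorm", q = stats::qlnorm,
       mean = sqrt(e), sd = sqrt(e^2 - e),
       skew = (e + 2) * sqrt(e - 1),
       kurt = e^4 + 2 * e^3 + 3 * e^2 - 3)
}

#' @rdname mixture_components
#' @export
comp_exp <- function()
  list(name = "exp", q = stats::qexp, mean = 1, sd = 1, skew = 2, kurt = 9)

#' @rdname mixture_components
#' @export
comp_lnorm_signmix <- function(q_pos = 0.5) {
  stopifnot(q_pos >= 0, q_pos <= 1)
  a <- exp((1:4)^2 / 2)                     # raw moments of log-normal(0,1)
  m1 <- (2 * q_pos - 1) * a[1]
  m2 <- a[2]
  m3 <- (2 * q_pos - 1) * a[3]
  m4 <- a[4]
  v <- m2 - m1^2
  m3c <- m3 - 3 * m1 * m2 + 2 * m1^3
  m4c <- m4 - 4 * m1 * m3 + 6 * m1^2 * m2 - 3 * m1^4
  cdf <- function(x) q_pos * stats::plnorm(x) +
    (1 - q_pos) * stats::plnorm(-x, lower.tail = FALSE)
  qf <- invert_cdf(cdf, lower = -exp(9), upper = exp(9))
  list(name = sprintf("lnorm_signmix%.4f", q_pos), q = qf,
       mean = m1, sd = sqrt(v), skew = m3c / v^1.5, kurt = m4c / v^2)
}

# Numeric quantile function: monotone interpolation of cdf^-1 on a grid that
# is uniform in z = qnorm(u), dense enough for sampling-grade accuracy.
invert_cdf <- function(cdf, lower, upper, n_grid = 3001L) {
  zg <- seq(-8.2, 8.2, length.out = n_grid)
  ug <- stats::pnorm(zg)
  xg <- vapply(ug, function(u)
    stats::uniroot(function(x) cdf(x) - u, c(lower, upper),
                   tol = 1e-12)$root, 0)
  xg <- cummax(xg)                          # guard monotonicity
  spl <- stats::splinefun(zg, xg, method = "hyman")
  function(u) {
    z <- stats::qnorm(pmin(pmax(u, 1e-16), 1 - 1e-16))
    spl(pmin(pmax(z, -8.2), 8.2))
  }
}

std_quantile <- function(comp)
  function(u) {
    u <- pmin(pmax(u, 1e-16), 1 - 1e-16)   # keep heavy-tail quantiles finite
    (comp$q(u) - comp$mean) / comp$sd
  }

# E[prod_k Qtilde_{idx[k]}(U)] for standardized component quantiles.
# Pure powers come from the components' exact moments when available.
cross_moment <- function(comps, idx) {
  idx <- sort(idx)
  if (length(unique(idx)) == 1) {
    cmp <- comps[[idx[1]]]
    ex <- switch(as.character(length(idx)),
                 "1" = 0, "2" = 1, "3" = cmp$skew, "4" = cmp$kurt)
    if (!is.null(ex) && !is.na(ex)) return(ex)
  }
  qs <- lapply(comps[idx], std_quantile)
  f <- function(z) {
    u <- stats::pnorm(z)
    out <- stats::dnorm(z)
    for (qf in qs) out <- out * qf(u)
    out
  }
  for (rt in c(1e-9, 1e-7, 1e-5)) {
    val <- tryCatch(
      stats::integrate(f, -8.2, 8.2, rel.tol = rt, abs.tol = rt / 10,
                       subdivisions = 500L)$value,
      error = function(e) NULL)
    if (!is.null(val)) return(val)
  }
  stop("cross-moment quadrature failed for components ",
       paste(vapply(comps[idx], `[[`, "", "name"), collapse = " * "))
}

# All cross-moment tensors up to order 4 for a component list.
moment_tensors <- function(comps) {
  l <- length(comps)
  key <- function(ix) paste(sort(ix), collapse = ".")
  cache <- new.env(parent = emptyenv())
  cm <- function(ix) {
    k <- key(ix)
    if (is.null(cache[[k]])) cache[[k]] <- cross_moment(comps, ix)
    cache[[k]]
  }
  grid <- function(r) as.matrix(expand.grid(rep(list(seq_len(l)), r)))
  list(l = l, g2 = grid(2), g3 = grid(3), g4 = grid(4),
       m2 = apply(grid(2), 1, cm), m3 = apply(grid(3), 1, cm),
       m4 = apply(grid(4), 1, cm))
}

mixture_moments_from_tensors <- function(tens, beta) {
  bprod <- function(g) apply(g, 1, function(ix) prod(beta[ix]))
  mu2 <- sum(bprod(tens$g2) * tens$m2)
  mu3 <- sum(bprod(tens$g3) * tens$m3)
  mu4 <- sum(bprod(tens$g4) * tens$m4)
  c(var = mu2, skew = mu3 / mu2^1.5, kurt = mu4 / mu2^2)
}

#' Quantile mixture distribution
#'
#' Builds the standardized quantile mixture
#' \eqn{F^{-1}(u) = \sum_m \beta_m F_m^{-1}(u)} from a component list and a
#' simplex weight vector. The returned object evaluates the standardized
#' (mean 0, variance 1) quantile function and carries the mixture's exact
#' skewness and kurtosis.
#'
#' @param components list of component objects (see [mixture_components]).
#' @param beta nonnegative weights summing to one.
#' @return Object of class `quantile_mixture`: `q` (standardized quantile
#'   function), `beta`, `components`, `skew`, `kurt`.
#' @export
quantile_mixture <- function(components, beta) {
  stopifnot(length(components) == length(beta), all(beta >= -1e-12))
  beta <- pmax(beta, 0); beta <- beta / sum(beta)
  tens <- moment_tensors(components)
  mm <- mixture_moments_from_tensors(tens, beta)
  qs <- lapply(components, std_quantile)
  sdm <- sqrt(mm[["var"]])
  qfun <- function(u) {
    out <- 0
    for (m in seq_along(qs)) if (beta[m] > 0) out <- out + beta[m] * qs[[m]](u)
    out / sdm
  }
  structure(list(q = qfun, beta = beta, components = components,
                 skew = unname(mm["skew"]), kurt = unname(mm["kurt"])),
            class = "quantile_mixture")
}

#' Fit mixture weights to a kurtosis target
#'
#' Finds simplex weights so that an indicator built as the sum of a
#' non-normal part (carrying `variance_share` of the unit variance, with the
#' mixture as its shape) and an independent normal remainder attains the
#' target marginal kurtosis. Since fourth cumulants add over independent
#' summands, the mixture itself must reach component kurtosis
#' \eqn{3 + (k - 3)/\mathrm{share}^2}.
#'
#' Two components: monotone bisection on the single free weight. Three or
#' more: simplex optimization of the squared kurtosis error with a small
#' entropy tie-break (flat solutions prefer even weights).
#'
#' @inheritParams quantile_mixture
#' @param target_kurtosis desired marginal (Pearson) kurtosis of the
#'   indicator variable.
#' @param variance_share fraction of the indicator variance carried by the
#'   non-normal part, in (0, 1].
#' @param tol acceptable absolute kurtosis error.
#' @return A [quantile_mixture()] with attribute `component_kurtosis`.
#' @export
fit_mixture_weights <- function(components, target_kurtosis,
                                variance_share = 1, tol = 0.1) {
  stopifnot(variance_share > 0, variance_share <= 1)
  kt <- 3 + (target_kurtosis - 3) / variance_share^2
  tens <- moment_tensors(components)
  l <- length(components)
  kurt_of <- function(beta)
    mixture_moments_from_tensors(tens, beta)[["kurt"]]
  if (l == 1) {
    beta <- 1
  } else if (l == 2) {
    f <- function(b) kurt_of(c(b, 1 - b)) - kt
    grid <- seq(0, 1, by = 0.02)
    vals <- vapply(grid, f, 0)
    if (all(vals > 0) || all(vals < 0))
      stop(sprintf(
        "infeasible kurtosis target %.2f: achievable range [%.2f, %.2f]",
        kt, min(vals) + kt, max(vals) + kt))
    i <- which(vals[-1] * vals[-length(vals)] <= 0)[1]
    b <- stats::uniroot(f, c(grid[i], grid[i + 1]), tol = 1e-10)$root
    beta <- c(b, 1 - b)
  } else {
    obj <- function(par) {
      e <- exp(c(par, 0)); b <- e / sum(e)
      (kurt_of(b) - kt)^2 + 1e-4 * sum(b * log(pmax(b, 1e-12)))
    }
    opt <- stats::optim(rep(0, l - 1), obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    e <- exp(c(opt$par, 0)); beta <- e / sum(e)
  }
  mix <- quantile_mixture(components, beta)
  if (abs(mix$kurt - kt) > tol)
    stop(sprintf("infeasible kurtosis target %.2f (achieved %.2f)",
                 kt, mix$kurt))
  attr(mix, "component_kurtosis") <- kt
  mix
}
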