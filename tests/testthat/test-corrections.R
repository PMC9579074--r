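test_that("ADF Gamma reproduces known fourth-moment structure", {
  set.seed(71)
  x <- matrix(rnorm(2e5), ncol = 1)
  g <- gamma_adf(x)                       # Var of s^2 is 2 for N(0,1)
  expect_equal(g[1, 1], 2, tolerance = 0.1)
  # constant column gives degenerate rows/columns
  x2 <- cbind(rnorm(500), 1)
  g2 <- gamma_adf(x2)
  idx <- semlrt:::vech_index(2)
  zero_rows <- which(idx[, 1] == 2 | idx[, 2] == 2)
  expect_true(all(abs(g2[zero_rows, ]) < 1e-12))
})

test_that("ADF Gamma converges to the normal-theory weight matrix under normality", {
  set.seed(72)
  A <- semlrt:::mvn_factor(pop$sigma0[1:4, 1:4])
  x <- matrix(rnorm(2e5 * 4), ncol = 4) %*% t(A)
  g <- gamma_adf(x)
  w <- normal_theory_weight(pop$sigma0[1:4, 1:4])
  expect_lt(max(abs(g - w)), 0.08)
})

test_that("normal-theory weight matrix has the element formula", {
  w <- normal_theory_weight(diag(3))
  idx <- semlrt:::vech_index(3)
  is_var <- idx[, 1] == idx[, 2]
  expect_equal(diag(w), ifelse(is_var, 2, 1))
  expect_true(all(w[upper.tri(w)] == 0))
  wf <- normal_theory_weight(pop$sigma0)
  expect_gt(min(eigen(wf, symmetric = TRUE, only.values = TRUE)$values), 0)
})

test_that("residual weight matrix U annihilates the model tangent space", {
  fit <- fit_cfa(spec_mis, pop$sigma0, N = 200)
  W <- normal_theory_weight(fit$sigma_hat)
  D <- delta_jacobian(spec_mis, fit$theta)
  U <- residual_u(W, D)
  expect_lt(max(abs(U %*% D)), 1e-8)
  expect_equal(U, t(U), tolerance = 1e-12)
  # idempotent in the W metric and projection rank identity
  expect_equal(U %*% W %*% U, U, tolerance = 1e-8)
  expect_equal(sum(diag(U %*% W)), spec_mis$df, tolerance = 1e-8)
  # with no parameters U reduces to W^-1
  U0 <- residual_u(W, matrix(0, 120, 0))
  expect_equal(U0, chol2inv(chol(W)), tolerance = 1e-10)
})

test_that("eigenvalue weights satisfy the trace identities", {
  x <- normal_sample(400, seed = 55)
  fit <- fit_cfa(spec_correct, cov(x), 400)
  W <- normal_theory_weight(fit$sigma_hat)
  U <- residual_u(W, delta_jacobian(spec_correct, fit$theta))
  # asymptotic-robustness baseline: Gamma = W gives weights identically one
  w1 <- eigen_weights(U, W, fit$df)
  expect_equal(w1, rep(1, fit$df), tolerance = 1e-6)
  g <- gamma_adf(x)
  w <- eigen_weights(U, g, fit$df)
  tr <- ug_traces(U, g)
  expect_equal(sum(w), tr$t1, tolerance = 1e-8 * abs(tr$t1))
  expect_equal(sum(w^2), tr$t2, tolerance = 1e-8 * abs(tr$t2))
  expect_equal(sum(w^3), tr$t3, tolerance = 1e-7 * abs(tr$t3))
  expect_true(all(diff(w) <= 1e-12))
  expect_true(all(w >= 0))
})

test_that("corrected statistics collapse correctly for degenerate weights", {
  df <- 87; Tml <- 100
  # equal weights w: scaled statistic divides by w, adjusted dfs equal df
  for (w in c(1, 2, 0.5)) {
    t1 <- w * df; t2 <- w^2 * df; t3 <- w^3 * df
    expect_equal(t_m(Tml, t1, df)$statistic, Tml / w)
    expect_equal(t_mv1(Tml, t1, t2)$d, df)
    expect_equal(t_mv1(Tml, t1, t2)$statistic, Tml / w)
    expect_equal(t_ms(Tml, t1, t2, t3)$v, df)
    expect_equal(t_ms(Tml, t1, t2, t3)$statistic, Tml / w)
  }
  # weights all one: every statistic equals T_ML and p-values coincide
  t1 <- df; t2 <- df; t3 <- df
  pml <- pchisq(Tml, df, lower.tail = FALSE)
  expect_equal(t_m(Tml, t1, df)$p_value, pml)
  expect_equal(t_mv2(Tml, df, t1, t2)$statistic, Tml)
  expect_equal(t_mv2(Tml, df, t1, t2)$p_value, pml)
  expect_equal(mixture_pvalue(Tml, rep(1, df)), pml)
})

test_that("Bartlett factor behaves as the formula prescribes", {
  r <- t_mb(100, p = 15, h = 3, N = 200, df = 87)
  expect_equal(r$bartlett, 1 - 47 / 1194)
  expect_equal(r$statistic, 100 * (1 - 47 / 1194))
  facs <- vapply(c(100, 200, 500, 5000), function(n)
    t_mb(100, 15, 3, n, 87)$bartlett, 0)
  expect_true(all(diff(facs) > 0))
  expect_equal(t_mb(100, 15, 3, 1e9, 87)$statistic, 100, tolerance = 1e-6)
  expect_error(t_mb(100, 15, 3, N = 5, df = 87), "Bartlett")
})

test_that("adjusted df never exceeds model df", {
  set.seed(99)
  for (i in 1:25) {
    w <- rexp(87) + 0.01
    t1 <- sum(w); t2 <- sum(w^2)
    expect_lte(t_mv1(100, t1, t2)$d, 87 + 1e-10)
  }
})

test_that("scale-shifted statistic matches mixture mean and variance", {
  # if E[T_ML] = tr(UG) and Var[T_ML] = 2 tr[(UG)^2], then T_MV2 has mean df
  set.seed(101)
  w <- rexp(87) * 1.3
  t1 <- sum(w); t2 <- sum(w^2); df <- 87
  draws <- replicate(4000, sum(w * rchisq(87, 1)))
  tv <- vapply(draws, function(T) t_mv2(T, df, t1, t2)$statistic, 0)
  expect_equal(mean(tv), df, tolerance = 0.03)
  expect_equal(var(tv), 2 * df, tolerance = 0.1)
  # the shift term df - sqrt(df d) is nonnegative because d <= df, so the
  # statistic never goes below zero and tiny T_ML gives p near one
  r <- t_mv2(0.01, df, t1, t2)
  expect_gte(r$statistic, 0)
  expect_gt(r$p_value, 0.999)
})

test_that("mixture p-values agree with exact and Monte Carlo references", {
  # single weight: scaled chi-square(1)
  expect_equal(mixture_pvalue(3.2, 2),
               pchisq(1.6, 1, lower.tail = FALSE))
  # all-equal weights: exact scaled chi-square(df)
  expect_equal(mixture_pvalue(120, rep(1.5, 80)),
               pchisq(80, 80, lower.tail = FALSE))
  expect_error(mixture_pvalue(1, c(0, 0)), "zero")
  expect_equal(mixture_pvalue(-1, c(1, 2)), 1)
  # dispersed weights: Imhof inversion vs Monte Carlo oracle within 3 SE
  set.seed(2024)
  w <- c(3, 2.2, 1.7, 1.1, 0.9, 0.5, 0.4, 0.2)
  ndraw <- 2e5
  draws <- colSums(w * matrix(rchisq(ndraw * length(w), 1), nrow = length(w)))
  for (q in c(5, 10, 15, 25)) {
    p_mc <- mean(draws >= q)
    se <- sqrt(p_mc * (1 - p_mc) / ndraw)
    expect_lt(abs(mixture_pvalue(q, w) - p_mc), 3 * se + 1e-12)
  }
})

test_that("trace and eigenvalue routes give identical corrected statistics", {
  x <- generate_data(condition_spec("latent", 10, N = 300,
                                    specification = "misspecified",
                                    seed = 91), pop)$values
  res <- analyze_sample(x, spec_mis)
  tr <- res$tests$traces
  w <- res$tests$weights
  Tml <- res$fit$T_ml
  # statistics recomputed from the weight vector
  expect_equal(t_m(Tml, sum(w), 87)$statistic,
               res$tests$table$value[res$tests$table$statistic == "M"],
               tolerance = 1e-8)
  expect_equal(t_mv1(Tml, sum(w), sum(w^2))$statistic,
               res$tests$table$value[res$tests$table$statistic == "MV1"],
               tolerance = 1e-8)
  expect_equal(t_ms(Tml, sum(w), sum(w^2), sum(w^3))$statistic,
               res$tests$table$value[res$tests$table$statistic == "MS"],
               tolerance = 1e-6)
  expect_equal(tr$t1, sum(w), tolerance = 1e-8)
})
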