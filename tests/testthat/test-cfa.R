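test_that("the correct specification recovers the printed parameters from sigma0", {
  fit <- fit_cfa(spec_correct, pop$sigma0, N = 200)
  expect_true(fit$converged)
  expect_lt(fit$F_ml, 1e-8)
  expect_equal(fit$lambda, unname(default_loadings()), tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(fit$phi, unname(default_factor_corr()), tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(fit$sigma_hat, pop$sigma0, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("any representable covariance is fitted exactly", {
  # build S = Sigma(theta) for an arbitrary feasible parameter vector
  theta <- semlrt:::start_values(spec_mis)
  theta[1:15] <- seq(.4, .8, length.out = 15)
  S <- semlrt:::sigma_of_theta(spec_mis, theta)
  fit <- fit_cfa(spec_mis, S, N = 500)
  expect_lt(fit$F_ml, 1e-9)
})

test_that("the misspecified model attains F0 on the population matrix", {
  fit <- fit_cfa(spec_mis, pop$sigma0, N = 200)
  expect_equal(round(fit$F_ml, 3), 0.328)
  expect_equal(t_ml(fit), fit$F_ml * 199)
  expect_equal(fit$T_ml, t_ml(fit))
})

test_that("input validation catches degenerate covariance input", {
  S <- pop$sigma0
  S[1, 2] <- 0.9                          # asymmetric
  expect_error(fit_cfa(spec_mis, S, 100), "symmetric")
  S2 <- diag(15); S2[1, 1] <- -1
  expect_error(fit_cfa(spec_mis, S2, 100), "positive definite")
})

test_that("the optimizer is deterministic", {
  ds <- normal_sample(300, seed = 31)
  S <- cov(ds)
  f1 <- fit_cfa(spec_correct, S, 300)
  f2 <- fit_cfa(spec_correct, S, 300)
  expect_identical(f1$theta, f2$theta)
  expect_lt(f1$grad_norm, 1e-6)
})

test_that("refitting after variable reordering permutes estimates consistently", {
  ds <- normal_sample(300, seed = 32)
  S <- cov(ds)
  perm <- c(6:10, 1:5, 11:15)             # swap the first two indicator blocks
  mask_perm <- spec_mis$loading_mask[perm, c(2, 1, 3)]
  f1 <- fit_cfa(spec_mis, S, 300)
  f2 <- fit_cfa(model_spec(mask_perm), S[perm, perm], 300)
  expect_equal(f1$F_ml, f2$F_ml, tolerance = 1e-8)
  expect_equal(f2$psi, f1$psi[perm], tolerance = 1e-5)
})

test_that("analytic Jacobian matches central finite differences", {
  for (spec in list(spec_mis, spec_correct)) {
    fit <- fit_cfa(spec, pop$sigma0, N = 200)
    D <- delta_jacobian(spec, fit$theta)
    expect_equal(dim(D), c(120, spec$q))
    h <- 1e-6
    fd <- vapply(seq_along(fit$theta), function(k) {
      tp <- fit$theta; tm <- fit$theta
      tp[k] <- tp[k] + h; tm[k] <- tm[k] - h
      (semlrt:::vech(semlrt:::sigma_of_theta(spec, tp)) -
         semlrt:::vech(semlrt:::sigma_of_theta(spec, tm))) / (2 * h)
    }, numeric(120))
    expect_lt(max(abs(D - fd)), 1e-6)
  }
})

test_that("residual-variance Jacobian columns are vech diagonal indicators", {
  D <- delta_jacobian(spec_null, rep(.8, 15))
  expect_equal(ncol(D), 15)
  idx <- semlrt:::vech_index(15)
  for (i in c(1, 7, 15)) {
    expected <- as.numeric(idx[, 1] == i & idx[, 2] == i)
    expect_equal(D[, i], expected)
  }
})

test_that("T_ML follows its reference chi-square under normality at large N", {
  # fit-only replications of the correctly specified model
  reps <- 1000
  tvals <- numeric(reps)
  kept <- 0L
  attempt <- 0L
  while (kept < reps) {
    attempt <- attempt + 1L
    ds <- generate_data(condition_spec("normal", 3, N = 1000,
                                       specification = "correct",
                                       seed = 5000 + attempt), pop)
    fit <- fit_cfa(spec_correct, cov(ds$values), 1000)
    if (!fit$converged || fit$heywood) next
    kept <- kept + 1L
    tvals[kept] <- fit$T_ml
  }
  expect_gt(stats::ks.test(tvals, stats::pchisq, df = 81)$p.value, 0.01)
  # chi-square mean property
  expect_equal(mean(tvals), 81, tolerance = 0.02)
})
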