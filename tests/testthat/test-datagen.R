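test_that("condition specification validates and normalizes its inputs", {
  cnd <- condition_spec("marginal", 3, 200, "correct", reps = 10, seed = 1)
  expect_equal(cnd$source, "normal")
  expect_error(condition_spec("normal", 10), "kurtosis = 3")
  expect_error(condition_spec("latent", 2), "kurtosis")
})

test_that("generation is bit-identical for identical condition and seed", {
  cnd <- condition_spec("latent", 10, 150, "correct", seed = 9)
  d1 <- generate_data(cnd, pop)
  d2 <- generate_data(cnd, pop)
  expect_identical(d1$values, d2$values)
  d3 <- generate_data(cnd, pop, seed = 10)
  expect_false(identical(d1$values, d3$values))
})

test_that("the normal control matches sigma0 and normal moments", {
  ds <- generate_data(condition_spec("normal", 3, 2e5, "correct", seed = 12),
                      pop)
  mm <- ds$realized_moments
  expect_lt(max(abs(mm$skewness)), 0.05)
  expect_lt(max(abs(mm$kurtosis - 3)), 0.1)
  expect_lt(max(abs(cov(ds$values) - pop$sigma0)), 0.02)
  expect_equal(mardia_kurtosis(ds$values), 15 * 17, tolerance = 0.02)
})

test_that("Fleishman coefficients solve the moment equations", {
  expect_equal(fleishman_coefficients(0, 3), c(a = 0, b = 1, c = 0, d = 0),
               tolerance = 1e-8)
  for (tgt in list(c(0, 7), c(1.2, 10), c(1.75, 17), c(-1, 8))) {
    cf <- fleishman_coefficients(tgt[1], tgt[2])
    expect_equal(cf[["a"]], -cf[["c"]])
    # closed-form moments of a + bZ + cZ^2 + dZ^3
    b <- cf[["b"]]; cc <- cf[["c"]]; d <- cf[["d"]]
    v <- b^2 + 6 * b * d + 2 * cc^2 + 15 * d^2
    sk <- 2 * cc * (b^2 + 24 * b * d + 105 * d^2 + 2)
    ku <- 24 * (b * d + cc^2 * (1 + b^2 + 28 * b * d) +
                  d^2 * (12 + 48 * b * d + 141 * cc^2 + 225 * d^2))
    expect_equal(v, 1, tolerance = 1e-8)
    expect_equal(sk, tgt[1], tolerance = 1e-6)
    expect_equal(ku, tgt[2] - 3, tolerance = 1e-6)
  }
  expect_error(fleishman_coefficients(3, 4), "infeasible")
})

test_that("NORTA with normal marginals reproduces the target correlation", {
  tgt <- matrix(c(1, .6, .3, .6, 1, .5, .3, .5, 1), 3, 3)
  marg <- replicate(3, semlrt:::std_quantile(comp_normal()))
  R <- norta_intermediate_matrix(tgt, marg)
  expect_equal(R, tgt, tolerance = 5e-3)
  x <- norta_sample(diag(3), marg, 5e4, seed = 3)
  off <- cor(x)[upper.tri(diag(3))]
  expect_lt(max(abs(off)), 0.02)
})

test_that("log-normal marginals need an inflated intermediate correlation", {
  marg <- replicate(2, semlrt:::std_quantile(comp_lnorm()))
  rho <- norta_intermediate_corr(marg[[1]], marg[[2]], 0.5)
  expect_gt(rho, 0.5)
  x <- norta_sample(matrix(c(1, .5, .5, 1), 2), marg, 3e5, seed = 4)
  expect_equal(cor(x)[1, 2], 0.5, tolerance = 0.02)
  expect_equal(sample_kurtosis(x[, 1]), comp_lnorm()$kurt, tolerance = 35)
})

test_that("latent and error sources share marginal moments but differ multivariately", {
  N <- 1e5
  dl <- generate_data(condition_spec("latent", 10, N, "correct", seed = 21),
                      pop)
  de <- generate_data(condition_spec("error", 10, N, "correct", seed = 22),
                      pop)
  expect_equal(mean(dl$realized_moments$kurtosis),
               mean(de$realized_moments$kurtosis), tolerance = 0.2)
  expect_lt(max(abs(cov(dl$values) - pop$sigma0)), 0.05)
  expect_lt(max(abs(cov(de$values) - pop$sigma0)), 0.05)
  # the multivariate fourth-moment structure is the study's manipulation:
  # equal marginal kurtosis, clearly different multivariate kurtosis
  expect_gt(abs(mardia_kurtosis(dl$values) - mardia_kurtosis(de$values)), 30)
})

test_that("sample covariance converges to sigma0 at the root-N rate", {
  errs <- vapply(c(1e3, 1e5), function(N) {
    ds <- generate_data(condition_spec("error", 10, N, "correct", seed = 33),
                        pop)
    max(abs(cov(ds$values) - pop$sigma0))
  }, 0)
  expect_gt(errs[1] / errs[2], 3)   # expect ~10 from a 100-fold N increase
})

test_that("generated datasets round-trip through CSV with metadata", {
  cnd <- condition_spec("error", 3, 50, "correct", seed = 14)
  ds <- generate_data(cnd, pop)
  path <- tempfile(fileext = ".csv")
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_equal(back$values, ds$values, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$condition$source, "error")
  expect_equal(back$condition$seed, 14L)
  file.remove(path, paste0(path, ".meta.json"))
})

test_that("covariance matrices round-trip through CSV", {
  path <- tempfile(fileext = ".csv")
  write_covariance(pop$sigma0, path)
  expect_equal(read_covariance(path), pop$sigma0, tolerance = 1e-12,
               ignore_attr = TRUE)
  file.remove(path)
})
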