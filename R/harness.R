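# Monte Carlo harness: replication loop with redraw-on-nonconvergence,
# rejection rates, Bradley's criterion, median fit indices.

derive_seed <- function(master, index) {
  # counter-based derivation; keeps every value a valid 32-bit seed and any
  # single replication reconstructible in isolation
  as.integer((as.double(master) * 48271 + as.double(index) * 2654435761) %%
               2147483629) + 1L
}

#' Bradley's liberal robustness criterion
#'
#' A rejection rate (in percent) is acceptable when it lies inside the
#' closed interval \eqn{[\alpha \pm 0.5\alpha]} -- for \eqn{\alpha = .05},
#' `[2.5, 7.5]` percent.
#'
#' @param rate_percent empirical rejection rate in percent.
#' @param alpha nominal significance level.
#' @export
bradley_check <- function(rate_percent, alpha = .05) {
  stopifnot(rate_percent >= 0, rate_percent <= 100)
  rate_percent >= 100 * alpha * 0.5 & rate_percent <= 100 * alpha * 1.5
}

#' Analyze one sample
#'
#' Fits the analysis model and the independence null model to a data matrix,
#' computes all seven test statistics (sharing one \eqn{\hat\Gamma}) and the
#' per-statistic fit indices.
#'
#' @param data N x p data matrix (raw observations).
#' @param spec a [model_spec()] (the null model is constructed internally).
#' @param alpha significance level used for the rejection flags.
#' @return List: `fit`, `null_fit`, `tests`, `null_tests`, `indices`, and a
#'   tidy `table` combining statistic values, p-values, rejections, RMSEA
#'   and CFI.
#' @export
analyze_sample <- function(data, spec, alpha = .05) {
  data <- as.matrix(data)
  N <- nrow(data)
  S <- stats::cov(data)
  fit <- fit_cfa(spec, S, N)
  if (!fit$converged) return(list(fit = fit, converged = FALSE))
  null_spec <- model_spec("null", p = ncol(data))
  null_fit <- fit_cfa(null_spec, S, N)
  gam <- gamma_adf(data)
  tests <- test_statistics(fit, data, gamma_hat = gam)
  null_tests <- test_statistics(null_fit, data, gamma_hat = gam)
  idx <- fit_index_set(tests, null_tests)
  tab <- merge(tests$table, idx, by = "statistic", sort = FALSE)
  tab$reject <- tab$p_value <= alpha
  list(fit = fit, null_fit = null_fit, tests = tests,
       null_tests = null_tests, indices = idx, table = tab,
       converged = TRUE)
}

#' Run one simulation condition
#'
#' Draws `reps` valid replications (samples whose model fit converged
#' without an active Heywood bound; invalid draws are replaced by a fresh
#' sample with a new derived seed) and aggregates rejection rates, Bradley
#' flags and median fit indices per statistic.
#'
#' @param condition a [condition_spec()].
#' @param pop a [population_model()].
#' @param alpha significance level.
#' @param retry_factor retry budget as a multiple of `reps`.
#' @param keep_replications return the per-replication table as well.
#' @return Object of class `condition_result`: `condition`, `summary` (one
#'   row per statistic: rejection rate in percent, Bradley flag, median
#'   RMSEA/CFI, median scaling factor c), `counts`, and optionally
#'   `replications`.
#' @export
run_condition <- function(condition, pop = population_model(), alpha = .05,
                          retry_factor = 10, keep_replications = FALSE) {
  stopifnot(inherits(condition, "condition_spec"))
  if (condition$reps < 1) stop("reps must be positive")
  spec <- model_spec(condition$specification)
  rows <- vector("list", condition$reps)
  cvec <- numeric(condition$reps)
  done <- 0L; attempt <- 0L
  n_nonconv <- 0L; n_heywood <- 0L
  budget <- retry_factor * condition$reps
  while (done < condition$reps) {
    attempt <- attempt + 1L
    if (attempt > budget)
      stop(sprintf("condition failed: %d valid of %d attempted draws",
                   done, attempt - 1L))
    ds <- generate_data(condition, pop,
                        seed = derive_seed(condition$seed, attempt))
    res <- tryCatch(analyze_sample(ds$values, spec, alpha = alpha),
                    error = function(e) list(converged = FALSE))
    if (!isTRUE(res$converged)) { n_nonconv <- n_nonconv + 1L; next }
    if (res$fit$heywood) { n_heywood <- n_heywood + 1L; next }
    done <- done + 1L
    tab <- res$table
    tab$replication <- done
    rows[[done]] <- tab
    cvec[done] <- res$tests$c
  }
  reps_tab <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(reps_tab, reps_tab$statistic),
    function(d) data.frame(
      statistic = d$statistic[1],
      rejection_rate = 100 * mean(d$reject),
      bradley = bradley_check(100 * mean(d$reject), alpha),
      median_rmsea = condition_point_estimate(d$rmsea),
      median_cfi = if (all(is.na(d$cfi))) NA_real_
                   else condition_point_estimate(d$cfi))))
  ord <- c("ML", "M", "MB", "MV1", "MV2", "MS", "mix")
  agg <- agg[match(ord, agg$statistic), ]
  rownames(agg) <- NULL
  structure(list(
    condition = condition, summary = agg,
    median_c = stats::median(cvec),
    counts = c(attempted = attempt, nonconvergent = n_nonconv,
               heywood = n_heywood, valid = done),
    replications = if (keep_replications) reps_tab),
    class = "condition_result")
}

#' @export
print.condition_result <- function(x, ...) {
  cnd <- x$condition
  cat(sprintf(
    "condition: source=%s k=%g N=%d %s reps=%d (attempted %d)\n",
    cnd$source, cnd$kurtosis, cnd$N, cnd$specification, cnd$reps,
    x$counts["attempted"]))
  print(transform(x$summary, rejection_rate = round(rejection_rate, 1),
                  median_rmsea = round(median_rmsea, 3),
                  median_cfi = round(median_cfi, 3)))
  invisible(x)
}

#' Run a grid of conditions
#'
#' Enumerates the crossed design (sources x kurtosis x sample sizes x
#' specification statuses) and runs each cell, deriving per-condition seeds
#' from the master seed. Failed cells are recorded and the run continues.
#'
#' @param sources,kurtoses,Ns,specifications design factors. The default
#'   grid is the full study design (the normal control arises as
#'   marginal/k=3).
#' @param reps replications per cell.
#' @param seed master seed.
#' @param pop a [population_model()].
#' @param alpha significance level.
#' @param verbose print progress lines.
#' @return List: `conditions` (one summary row per condition x statistic as
#'   a data frame), `results` (the `condition_result` objects), `failures`.
#' @export
run_study <- function(sources = c("latent", "error", "marginal"),
                      kurtoses = c(3, 10, 17),
                      Ns = c(200, 400, 600, 1000),
                      specifications = c("correct", "misspecified"),
                      reps = 1000L, seed = 1L,
                      pop = population_model(), alpha = .05,
                      verbose = interactive()) {
  grid <- expand.grid(source = sources, kurtosis = kurtoses, N = Ns,
                      specification = specifications,
                      stringsAsFactors = FALSE)
  results <- vector("list", nrow(grid))
  failures <- list()
  out <- list()
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    cnd <- condition_spec(g$source, g$kurtosis, g$N, g$specification,
                          reps = reps, seed = derive_seed(seed, i))
    if (verbose)
      message(sprintf("[%d/%d] %s k=%g N=%d %s", i, nrow(grid), cnd$source,
                      cnd$kurtosis, cnd$N, cnd$specification))
    res <- tryCatch(run_condition(cnd, pop, alpha = alpha),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        list(condition = cnd, message = conditionMessage(res))
      next
    }
    results[[i]] <- res
    s <- res$summary
    s$source <- cnd$source; s$kurtosis <- cnd$kurtosis
    s$N <- cnd$N; s$specification <- cnd$specification
    out[[length(out) + 1L]] <- s
  }
  list(conditions = do.call(rbind, out), results = results,
       failures = failures)
}
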