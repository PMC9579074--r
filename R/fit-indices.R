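# Sample RMSEA and CFI for each (corrected) test statistic.
#
# The uncorrected formulas are
#   RMSEA = sqrt(max(0, (T_ML - df) / ((N-1) df)))
#   CFI   = 1 - (T_ML - df) / (T_nm - df_nm)
# and the corrected variants rescale the excess of the corrected statistic
# over its reference df back to the T_ML metric before plugging in: c for
# T_MB, b = tr(UG)/d for T_MV1, a = sqrt(tr[(UG)^2]/df) for T_MV2,
# g = tr(UG)/v for T_MS. The mixture variant replaces df by tr(UG). The
# corrected CFI variants floor the misfit ratio at zero; the uncorrected
# CFI is left unfloored (the `floor_ml` switch restores symmetry if wanted).

#' Sample RMSEA for a named statistic
#'
#' @param statistic_name one of `"ML"`, `"M"`, `"MB"`, `"MV1"`, `"MV2"`,
#'   `"MS"`, `"mix"`. The plain scaled statistic `"M"` uses the uncorrected
#'   formula with its own value.
#' @param value the statistic's value.
#' @param df model degrees of freedom.
#' @param N sample size.
#' @param traces list `t1`, `t2` of traces of \eqn{(\hat U\hat\Gamma)^k}
#'   (needed for all variants except `"ML"`).
#' @return Nonnegative scalar.
#' @export
rmsea_sample <- function(statistic_name, value, df, N, traces = NULL) {
  nm1 <- N - 1
  num_den <- switch(statistic_name,
    ML = ,
    M = c(value - df, df),
    MB = c(traces$t1 / df * (value - df), df),
    MV1 = {
      d <- traces$t1^2 / traces$t2
      c(traces$t1 / d * (value - d), d)
    },
    MV2 = c(sqrt(traces$t2 / df) * (value - df), df),
    MS = {
      v <- traces$t2^3 / traces$t3^2
      c(traces$t1 / v * (value - v), v)
    },
    mix = c(value - traces$t1, traces$t1),
    stop("unknown statistic name: ", statistic_name))
  sqrt(max(0, num_den[1] / (nm1 * num_den[2])))
}

#' Sample CFI for a named statistic
#'
#' @inheritParams rmsea_sample
#' @param value,null_value statistic values for the hypothesized and the
#'   null (independence) model, computed with the same correction.
#' @param df,null_df model and null-model degrees of freedom.
#' @param traces,null_traces trace lists for model and null model.
#' @param floor_ml floor the uncorrected variant's misfit ratio at zero as
#'   well (default `FALSE`, the verbatim formula).
#' @return Scalar not exceeding one.
#' @export
cfi_sample <- function(statistic_name, value, null_value, df, null_df,
                       traces = NULL, null_traces = NULL, floor_ml = FALSE) {
  excess <- function(nm, val, dfl, tr) {
    switch(nm,
      ML = ,
      M = val - dfl,
      MB = tr$t1 / dfl * (val - dfl),
      MV1 = {
        d <- tr$t1^2 / tr$t2
        tr$t1 / d * (val - d)
      },
      MV2 = sqrt(tr$t2 / dfl) * (val - dfl),
      MS = {
        v <- tr$t2^3 / tr$t3^2
        tr$t1 / v * (val - v)
      },
      mix = val - tr$t1,
      stop("unknown statistic name: ", nm))
  }
  num <- excess(statistic_name, value, df, traces)
  den <- excess(statistic_name, null_value, null_df, null_traces)
  if (!is.finite(den) || den <= 0) return(NA_real_)
  ratio <- num / den
  if (statistic_name %in% c("ML", "mix") && !floor_ml) 1 - ratio
  else 1 - max(0, ratio)
}

#' Condition-level point estimate
#'
#' The median across replications (the study's point estimate for fit
#' indices).
#'
#' @param values numeric vector of per-replication values.
#' @export
condition_point_estimate <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("no valid replications")
  stats::median(values)
}

#' Fit indices for all statistics of one replication
#'
#' Combines a model and a null-model [test_statistics()] result into the
#' per-statistic RMSEA and CFI set.
#'
#' @param tests model `sem_tests` object.
#' @param null_tests null-model `sem_tests` object (same data, same
#'   \eqn{\hat\Gamma}).
#' @param floor_ml see [cfi_sample()].
#' @return Data frame with columns `statistic`, `rmsea`, `cfi`.
#' @export
fit_index_set <- function(tests, null_tests, floor_ml = FALSE) {
  stopifnot(inherits(tests, "sem_tests"), inherits(null_tests, "sem_tests"))
  tab <- tests$table; ntab <- null_tests$table
  out <- lapply(seq_len(nrow(tab)), function(i) {
    nm <- tab$statistic[i]
    data.frame(statistic = nm,
      rmsea = rmsea_sample(nm, tab$value[i], tests$df, tests$N,
                           tests$traces),
      cfi = cfi_sample(nm, tab$value[i], ntab$value[ntab$statistic == nm],
                       tests$df, null_tests$df, tests$traces,
                       null_tests$traces, floor_ml = floor_ml))
  })
  do.call(rbind, out)
}
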