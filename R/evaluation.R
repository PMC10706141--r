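#' Pearson correlation between predictions and references
#'
#' Standard product-moment correlation; requires at least 3 pairs and
#' non-degenerate variance on both sides.
#'
#' @param a,b Numeric vectors of equal length.
#' @return `r` in \[-1, 1\].
#' @examples
#' pearson_cc(1:10, 2 * (1:10) + 1)
#' @export
pearson_cc <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  if (length(a) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  stats::cor(a, b)
}

#' Mean absolute error and mean squared error
#'
#' @param pred,ref Numeric vectors of equal length (units g for BMC,
#'   g/cm2 for BMD).
#' @return A scalar.
#' @examples
#' mae(c(1, -3) + 5, c(5, 5))  # 2
#' mse(c(1, -3) + 5, c(5, 5))  # 5
#' @export
mae <- function(pred, ref) {
  if (length(pred) != length(ref)) stop("length mismatch", call. = FALSE)
  mean(abs(pred - ref))
}

#' @rdname mae
#' @export
mse <- function(pred, ref) {
  if (length(pred) != length(ref)) stop("length mismatch", call. = FALSE)
  mean((pred - ref)^2)
}

#' Paired t-test for prediction bias
#'
#' One-sample two-sided t-test of the differences `pred - ref` against zero
#' (n - 1 degrees of freedom). A bias-fitted linear regressor has in-sample
#' residuals summing to zero, so this test returns p = 1 in-sample — the
#' unbiasedness signature. Degenerate cases: all differences identical and
#' zero gives `t = 0, p = 1`; identical and nonzero gives `p = 0` (with a
#' warning), since a deterministic offset is bias with certainty.
#'
#' @param pred,ref Numeric vectors of equal length, n >= 2.
#' @return List with `t_stat` and `p_value`.
#' @examples
#' paired_t_test(c(2, 3, 4), c(1, 1, 1))  # differences 1, 2, 3
#' @export
paired_t_test <- function(pred, ref) {
  if (length(pred) != length(ref)) stop("length mismatch", call. = FALSE)
  if (length(pred) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- pred - ref
  # degenerate spread: differences at (or numerically indistinguishable from)
  # a constant, e.g. the all-zero residuals of an interpolating fit
  eps <- 1e-10 * max(1, mean(abs(ref)))
  if (stats::sd(d) <= eps) {
    if (abs(mean(d)) <= eps) return(list(t_stat = 0, p_value = 1))
    warning("zero-variance nonzero differences: p set to 0", call. = FALSE)
    return(list(t_stat = sign(mean(d)) * Inf, p_value = 0))
  }
  tt <- stats::t.test(d, mu = 0, alternative = "two.sided")
  list(t_stat = unname(tt$statistic), p_value = tt$p.value)
}

#' Evaluate a fitted regressor on a feature table
#'
#' Predicts on `data`, compares against the model's target column, and
#' returns the evaluation battery as a one-row tibble: Pearson correlation,
#' MAE, MSE, the paired-t bias test, and the nonzero-weight count.
#'
#' @param model A `texture_lm` (or `texture_ann`).
#' @param data Feature table containing the model's feature columns and its
#'   target column.
#' @return One-row tibble: `target`, `n`, `lambda`, `nonzero`, `cc`, `mae`,
#'   `mse`, `t_stat`, `p_value`.
#' @examples
#' co <- generate_cohort(sim_config(n_subjects = 30, n_slices = 1, seed = 3))
#' ft <- extract_cohort_features(co)
#' fit <- fit_texture_lm(ft, "bmc_true")
#' evaluate_model(fit, ft)
#' @export
evaluate_model <- function(model, data) {
  target <- model$target_name
  if (!target %in% names(data)) {
    stop("data lacks the model's target column `", target, "`", call. = FALSE)
  }
  pred <- predict(model, data)
  ref <- data[[target]]
  tt <- paired_t_test(pred, ref)
  report <- tibble::tibble(
    target = target,
    n = length(ref),
    lambda = if (!is.null(model$lambda)) model$lambda else NA_real_,
    nonzero = if (!is.null(model$weights)) sum(model$weights != 0) else NA_integer_,
    cc = pearson_cc(pred, ref),
    mae = mae(pred, ref),
    mse = mse(pred, ref),
    t_stat = tt$t_stat,
    p_value = tt$p_value
  )
  stopifnot(report$mae <= sqrt(report$mse) + 1e-12)  # Jensen sanity check
  report
}
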