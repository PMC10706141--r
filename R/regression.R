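#' Z-score normalization of a design matrix and target
#'
#' Standardizes each feature column and the target to mean 0, sample (n-1)
#' SD 1, recording the statistics needed to map raw inputs into model space
#' and predictions back to original units. Zero-variance columns cannot be
#' standardized; they are dropped with a warning and recorded.
#'
#' @param X Numeric matrix (samples x features) with column names.
#' @param y Numeric target vector, length `nrow(X)`.
#' @return List with `X_norm`, `y_norm`, and `norm` — a `norm_stats` list
#'   holding `feature_means`, `feature_sds`, `target_mean`, `target_sd`,
#'   `kept` (column names retained) and `dropped`.
#' @examples
#' X <- cbind(a = c(1, 2, 3))
#' normalize_features(X, c(2, 4, 6))$X_norm
#' @export
normalize_features <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 samples to normalize", call. = FALSE)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  mu <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  keep <- sds > 0
  if (any(!keep)) {
    warning("dropping zero-variance feature(s): ",
            paste(colnames(X)[!keep], collapse = ", "), call. = FALSE)
  }
  Xk <- X[, keep, drop = FALSE]
  X_norm <- sweep(sweep(Xk, 2, mu[keep]), 2, sds[keep], "/")
  ty_mu <- mean(y)
  ty_sd <- stats::sd(y)
  if (ty_sd == 0) stop("target has zero variance", call. = FALSE)
  norm <- structure(list(
    feature_means = mu[keep], feature_sds = sds[keep],
    target_mean = ty_mu, target_sd = ty_sd,
    kept = colnames(X)[keep], dropped = colnames(X)[!keep]
  ), class = "norm_stats")
  list(X_norm = X_norm, y_norm = (y - ty_mu) / ty_sd, norm = norm)
}

# Moore-Penrose pseudoinverse solve via SVD: minimum-norm least-squares
# solution of A w = b.
pinv_solve <- function(A, b) {
  sv <- svd(A)
  tol <- max(dim(A)) * .Machine$double.eps * max(sv$d)
  pos <- sv$d > tol
  drop(sv$v[, pos, drop = FALSE] %*%
         ((crossprod(sv$u[, pos, drop = FALSE], b)) / sv$d[pos]))
}

#' Fit a linear regressor by normal equations (pseudoinverse)
#'
#' The headline estimator: in normalized space, minimize the in-sample MSE of
#' `y = b + X w` by the minimum-norm least-squares solution computed through
#' an SVD pseudoinverse of the bias-augmented design. Because the bias is
#' fit, in-sample residuals have mean zero to numerical precision — which is
#' why a paired t-test of in-sample predictions against references returns
#' p = 1. Rank-deficient designs fall back to the minimum-norm solution.
#'
#' With more samples than trainable parameters, no split or regularization is
#' applied at this stage; held-out evaluation is layered on top where needed.
#'
#' @param X_norm Standardized design matrix (see [normalize_features()]).
#' @param y_norm Standardized target.
#' @return List with `weights` (named), `bias`, `lambda = 0`.
#' @examples
#' fit_lr(cbind(x = c(-1, 0, 1)), c(-1, 0, 1))
#' @export
fit_lr <- function(X_norm, y_norm) {
  X_norm <- as.matrix(X_norm)
  n <- nrow(X_norm); p <- ncol(X_norm)
  if (n < p + 1) {
    stop(sprintf(
      "samples < features: %d sample(s) cannot identify %d weight(s) + bias",
      n, p
    ), call. = FALSE)
  }
  A <- cbind(`(bias)` = 1, X_norm)
  wb <- pinv_solve(A, y_norm)
  weights <- wb[-1]
  names(weights) <- colnames(X_norm)
  list(weights = weights, bias = wb[1], lambda = 0)
}

soft_threshold <- function(z, g) sign(z) * pmax(abs(z) - g, 0)

#' Fit a LASSO regressor by cyclic coordinate descent
#'
#' Minimizes `sum (y - b - X w)^2 + lambda * sum |w|` with an unpenalized
#' bias, by coordinate descent with the closed-form soft-threshold update
#' `w_j = S(2 x_j' r_j, lambda) / (2 x_j' x_j)`. Convergence is declared when
#' the largest weight change in a sweep drops below `tol`; `lambda = 0`
#' reproduces the normal-equation solution. For `lambda >=`
#' [lasso_lambda_max()] every weight is zero.
#'
#' @inheritParams fit_lr
#' @param lambda Penalty `lambda >= 0`, on the scale of the summed (not
#'   averaged) squared error.
#' @param w_init Optional warm-start weights.
#' @param tol Convergence tolerance on the max weight change (default 1e-8).
#' @param max_sweeps Sweep budget (default 1e5); exhaustion is an error
#'   carrying the last iterate in its `data`.
#' @return List with `weights`, `bias`, `lambda`, `sweeps`.
#' @examples
#' nf <- normalize_features(cbind(x = rnorm(20)), rnorm(20))
#' fit_lasso(nf$X_norm, nf$y_norm, lambda = 1)$weights
#' @export
fit_lasso <- function(X_norm, y_norm, lambda, w_init = NULL,
                      tol = 1e-8, max_sweeps = 1e5) {
  if (lambda < 0) stop("`lambda` must be >= 0", call. = FALSE)
  X <- as.matrix(X_norm)
  storage.mode(X) <- "double"
  p <- ncol(X)
  if (any(colSums(X^2) == 0)) {
    stop("zero-variance column in standardized design", call. = FALSE)
  }
  w <- if (is.null(w_init)) numeric(p) else as.numeric(w_init)
  stopifnot(length(w) == p)
  out <- .lasso_cd_core(X, as.numeric(y_norm), lambda, w, tol,
                        as.integer(max_sweeps))
  if (!out$converged) {
    cond <- structure(
      class = c("bonetex_lasso_no_convergence", "error", "condition"),
      list(message = sprintf("coordinate descent did not converge in %d sweeps",
                             as.integer(max_sweeps)),
           call = NULL,
           data = list(weights = out$weights, bias = out$bias, lambda = lambda))
    )
    stop(cond)
  }
  w <- out$weights
  names(w) <- colnames(X)
  list(weights = w, bias = out$bias, lambda = lambda, sweeps = out$sweeps)
}

#' Smallest penalty that zeroes every LASSO weight
#'
#' For the objective `sum (y - b - Xw)^2 + lambda sum |w|` with the bias at
#' its unpenalized optimum, all weights are zero iff
#' `lambda >= max_j |2 x_j' (y - mean(y))|`.
#'
#' @inheritParams fit_lr
#' @return The scalar `lambda_max`.
#' @export
lasso_lambda_max <- function(X_norm, y_norm) {
  X <- as.matrix(X_norm)
  max(abs(2 * crossprod(X, y_norm - mean(y_norm))))
}

#' Default penalty grid for the LASSO path
#'
#' Zero, then 20 log-spaced values from `1e-3 * lambda_max` up to
#' `lambda_max`, with the absolute value 0.04 inserted when it falls inside
#' the range so a mildly sparse operating point is always represented.
#'
#' @param lambda_max Upper end of the grid (see [lasso_lambda_max()]).
#' @return Increasing numeric vector starting at 0.
#' @export
default_lambda_grid <- function(lambda_max) {
  grid <- exp(seq(log(1e-3 * lambda_max), log(lambda_max), length.out = 20))
  # nudge the top of the grid so full shrinkage holds despite rounding in the
  # lambda_max inner products
  grid[length(grid)] <- grid[length(grid)] * (1 + 1e-8)
  if (0.04 > min(grid) && 0.04 < lambda_max) grid <- c(grid, 0.04)
  sort(unique(c(0, grid)))
}

# In-sample correlation, NA when predictions are degenerate (e.g. the
# all-zero model at full LASSO shrinkage predicts a constant).
safe_cc <- function(pred, ref) {
  if (stats::sd(pred) == 0 || stats::sd(ref) == 0) return(NA_real_)
  stats::cor(pred, ref)
}

new_texture_lm <- function(weights, bias, lambda, norm, target_name,
                           training = NULL) {
  structure(list(weights = weights, bias = bias, lambda = lambda,
                 norm = norm, target_name = target_name,
                 training = training),
            class = "texture_lm")
}

#' @export
print.texture_lm <- function(x, ...) {
  cat(sprintf("<texture_lm> target %s: %d feature(s) (%d nonzero), lambda = %g\n",
              x$target_name, length(x$weights), sum(x$weights != 0), x$lambda))
  if (!is.null(x$training)) {
    cat(sprintf("  in-sample (n = %d): cc %.3f, mae %.4g, mse %.4g\n",
                x$training$n, x$training$cc, x$training$mae, x$training$mse))
  }
  invisible(x)
}

resolve_feature_cols <- function(data, features) {
  if (!is.null(features)) return(features)
  cols <- grep("^[jx][0-9]+$", names(data), value = TRUE)
  if (!length(cols)) {
    stop("no feature columns found (expected j1..j45 or x1..x90); ",
         "pass `features` explicitly", call. = FALSE)
  }
  cols
}

#' Fit a bone-mineral texture regressor from a feature table
#'
#' Data-frame-first interface around [normalize_features()] plus [fit_lr()]
#' (`lambda = 0`, normal equations) or [fit_lasso()] (`lambda > 0`). Features
#' and the target are z-scored internally; the fitted object stores the
#' normalization statistics so [predict()][predict.texture_lm] works on raw
#' feature tables and returns original units (g or g/cm2).
#'
#' @param data Feature table, e.g. from [extract_cohort_features()] (targets
#'   `bmc_true`/`bmd_true`) or [build_change_table()] (`d_bmc`/`d_bmd`).
#' @param target Name of the target column.
#' @param features Character vector of feature column names; defaults to all
#'   columns matching `j<digits>` or `x<digits>`.
#' @param lambda L1 penalty; 0 (default) fits by normal equations.
#' @return A `texture_lm` object with [generics::tidy()],
#'   [generics::glance()], [generics::augment()], `predict()` and
#'   [autoplot.texture_lm()] methods.
#' @examples
#' co <- generate_cohort(sim_config(n_subjects = 30, n_slices = 1, seed = 2))
#' ft <- extract_cohort_features(co)
#' fit <- fit_texture_lm(ft, "bmc_true")
#' glance(fit)
#' @export
fit_texture_lm <- function(data, target, features = NULL, lambda = 0) {
  stopifnot(is.data.frame(data), target %in% names(data))
  features <- resolve_feature_cols(data, features)
  X <- as.matrix(data[features])
  y <- data[[target]]
  nf <- normalize_features(X, y)
  fit <- if (lambda == 0) {
    fit_lr(nf$X_norm, nf$y_norm)
  } else {
    fit_lasso(nf$X_norm, nf$y_norm, lambda)
  }
  model <- new_texture_lm(fit$weights, fit$bias, lambda, nf$norm, target)
  preds <- predict(model, data)
  model$training <- list(
    n = nrow(data),
    cc = safe_cc(preds, y),
    mae = mae(preds, y),
    mse = mse(preds, y)
  )
  model
}

#' Predict bone-mineral values from raw features
#'
#' Applies the stored z-score statistics to the feature columns, evaluates
#' `b + X w` in normalized space, and maps back to original units through the
#' stored target mean/SD.
#'
#' @param object A `texture_lm`.
#' @param newdata Data frame (or matrix) containing the model's feature
#'   columns.
#' @param ... Unused.
#' @return Numeric predictions in original units.
#' @export
predict.texture_lm <- function(object, newdata, ...) {
  ns <- object$norm
  if (is.matrix(newdata)) newdata <- as.data.frame(newdata)
  missing <- setdiff(ns$kept, names(newdata))
  if (length(missing)) {
    stop("newdata lacks feature column(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  X <- as.matrix(newdata[ns$kept])
  X_norm <- sweep(sweep(X, 2, ns$feature_means), 2, ns$feature_sds, "/")
  y_norm <- drop(X_norm %*% object$weights) + object$bias
  ns$target_mean + ns$target_sd * y_norm
}

#' Trace the LASSO path over a penalty grid
#'
#' Fits one model per penalty (warm-started from the previous, smaller one)
#' and records the sparsity and in-sample metrics at each stop. As the
#' penalty grows, weights are driven to zero, the in-sample correlation
#' falls and the errors rise — the classic sparsity/accuracy trade-off.
#'
#' @inheritParams fit_texture_lm
#' @param lambda_grid Increasing penalty grid including 0; defaults to
#'   [default_lambda_grid()] at the data's [lasso_lambda_max()].
#' @return A `lasso_path` object; `tidy()` gives the per-penalty summary
#'   tibble and `autoplot()` plots it. `$models` holds the fitted
#'   `texture_lm` objects.
#' @examples
#' co <- generate_cohort(sim_config(n_subjects = 30, n_slices = 1, seed = 2))
#' ft <- extract_cohort_features(co)
#' path <- lasso_path(ft, "bmc_true", lambda_grid = c(0, 1, 10, 1e6))
#' tidy(path)
#' @export
lasso_path <- function(data, target, features = NULL, lambda_grid = NULL) {
  stopifnot(is.data.frame(data), target %in% names(data))
  features <- resolve_feature_cols(data, features)
  X <- as.matrix(data[features])
  y <- data[[target]]
  nf <- normalize_features(X, y)
  if (is.null(lambda_grid)) {
    lambda_grid <- default_lambda_grid(lasso_lambda_max(nf$X_norm, nf$y_norm))
  }
  if (is.unsorted(lambda_grid) || lambda_grid[1] != 0) {
    stop("`lambda_grid` must be sorted ascending and include 0", call. = FALSE)
  }
  # Fit from the largest penalty down (glmnet-style): the sparse solution at
  # lambda_max is exact, and each warm start keeps coordinate descent fast.
  models <- vector("list", length(lambda_grid))
  w_warm <- NULL
  for (i in rev(seq_along(lambda_grid))) {
    lam <- lambda_grid[i]
    fit <- if (lam == 0) {
      fit_lr(nf$X_norm, nf$y_norm)
    } else {
      fit_lasso(nf$X_norm, nf$y_norm, lam, w_init = w_warm)
    }
    if (lam > 0) w_warm <- fit$weights
    model <- new_texture_lm(fit$weights, fit$bias, lam, nf$norm, target)
    preds <- predict(model, data)
    model$training <- list(n = nrow(data), cc = safe_cc(preds, y),
                           mae = mae(preds, y), mse = mse(preds, y))
    models[[i]] <- model
  }
  structure(list(lambdas = lambda_grid, models = models,
                 target_name = target),
            class = "lasso_path")
}

#' @export
print.lasso_path <- function(x, ...) {
  cat(sprintf("<lasso_path> target %s, %d penalties in [%g, %g]\n",
              x$target_name, length(x$lambdas),
              min(x$lambdas), max(x$lambdas)))
  print(generics::tidy(x))
  invisible(x)
}

#' Serialize a fitted texture regressor to JSON
#'
#' Human-readable, diff-able model file: weights, bias, penalty, the z-score
#' statistics needed to predict on raw inputs, and the target name.
#' `read_model_json()` restores a working `texture_lm`.
#'
#' @param model A `texture_lm`.
#' @param path Output file path.
#' @return `write_model_json()` the path, invisibly; `read_model_json()` a
#'   `texture_lm`.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "texture_lm"))
  payload <- list(
    target_name = model$target_name,
    lambda = model$lambda,
    bias = model$bias,
    weights = as.list(model$weights),
    norm = list(
      feature_means = as.list(model$norm$feature_means),
      feature_sds = as.list(model$norm$feature_sds),
      target_mean = model$norm$target_mean,
      target_sd = model$norm$target_sd,
      kept = model$norm$kept,
      dropped = model$norm$dropped
    ),
    training = model$training
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  norm <- structure(list(
    feature_means = unlist(p$norm$feature_means),
    feature_sds = unlist(p$norm$feature_sds),
    target_mean = p$norm$target_mean,
    target_sd = p$norm$target_sd,
    kept = p$norm$kept,
    dropped = p$norm$dropped %||% character(0)
  ), class = "norm_stats")
  new_texture_lm(unlist(p$weights), p$bias, p$lambda, norm, p$target_name,
                 training = p$training)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a small fully connected network on the texture features
#'
#' Optional non-linear baseline: a multilayer perceptron with hidden layers
#' of 8, 8 and 2 rectified-linear units and a single linear output, trained
#' by seeded full-batch gradient descent on the MSE in normalized space.
#' Provided for completeness next to the linear regressor; the linear model
#' remains the headline estimator.
#'
#' @inheritParams fit_texture_lm
#' @param hidden Hidden layer sizes (default `c(8, 8, 2)`).
#' @param epochs Full-batch gradient steps.
#' @param learning_rate Step size.
#' @param seed Seed for the weight initialization; training is deterministic
#'   given it.
#' @return A `texture_ann` with fields `layers` (weight matrices/bias
#'   vectors), `norm`, `target_name`, `mse_trace`; has a `predict()` method.
#' @section Errors: Divergence (MSE exceeding 10x its initial value) aborts.
#' @export
fit_texture_ann <- function(data, target, features = NULL,
                            hidden = c(8, 8, 2), epochs = 1000,
                            learning_rate = 0.02, seed = 1) {
  stopifnot(is.data.frame(data), target %in% names(data))
  features <- resolve_feature_cols(data, features)
  nf <- normalize_features(as.matrix(data[features]), data[[target]])
  X <- nf$X_norm; y <- nf$y_norm
  sizes <- c(ncol(X), hidden, 1)
  withr::local_seed(seed)
  layers <- lapply(seq_len(length(sizes) - 1), function(i) {
    list(W = matrix(stats::rnorm(sizes[i] * sizes[i + 1],
                                 sd = sqrt(2 / sizes[i])),
                    sizes[i], sizes[i + 1]),
         b = rep(0.01, sizes[i + 1]))  # small positive: avoids dead ReLUs at init
  })
  n <- nrow(X)
  forward <- function(layers) {
    acts <- list(X)
    for (i in seq_along(layers)) {
      z <- sweep(acts[[i]] %*% layers[[i]]$W, 2, -layers[[i]]$b)
      acts[[i + 1]] <- if (i < length(layers)) pmax(z, 0) else z
    }
    acts
  }
  mse0 <- NULL
  trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    acts <- forward(layers)
    err <- drop(acts[[length(acts)]]) - y
    cur <- mean(err^2)
    trace[ep] <- cur
    if (is.null(mse0)) mse0 <- cur
    if (!is.finite(cur) || cur > 10 * mse0) {
      stop("ANN training diverged (MSE exceeded 10x its initial value)",
           call. = FALSE)
    }
    grad_out <- matrix(2 * err / n, n, 1)
    for (i in rev(seq_along(layers))) {
      if (i < length(layers)) {
        grad_out <- grad_out * (acts[[i + 1]] > 0)
      }
      gW <- crossprod(acts[[i]], grad_out)
      gb <- colSums(grad_out)
      grad_out <- grad_out %*% t(layers[[i]]$W)
      layers[[i]]$W <- layers[[i]]$W - learning_rate * gW
      layers[[i]]$b <- layers[[i]]$b - learning_rate * gb
    }
  }
  structure(list(layers = layers, norm = nf$norm, target_name = target,
                 hidden = hidden, mse_trace = trace),
            class = "texture_ann")
}

#' @export
predict.texture_ann <- function(object, newdata, ...) {
  ns <- object$norm
  if (is.matrix(newdata)) newdata <- as.data.frame(newdata)
  X <- as.matrix(newdata[ns$kept])
  a <- sweep(sweep(X, 2, ns$feature_means), 2, ns$feature_sds, "/")
  L <- object$layers
  for (i in seq_along(L)) {
    z <- sweep(a %*% L[[i]]$W, 2, -L[[i]]$b)
    a <- if (i < length(L)) pmax(z, 0) else z
  }
  ns$target_mean + ns$target_sd * drop(a)
}
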