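test_that("z-score normalization standardizes, drops constants, and inverts", {
  X <- cbind(a = c(1, 2, 3), b = c(10, 30, 20))
  y <- c(2, 4, 6)
  nf <- normalize_features(X, y)
  expect_equal(unname(nf$X_norm[, "a"]), c(-1, 0, 1))  # hand z-score, ddof = 1
  expect_equal(colMeans(nf$X_norm), c(a = 0, b = 0), tolerance = 1e-10)
  expect_equal(apply(nf$X_norm, 2, sd), c(a = 1, b = 1), tolerance = 1e-10)
  expect_equal(mean(nf$y_norm), 0, tolerance = 1e-10)
  expect_equal(sd(nf$y_norm), 1, tolerance = 1e-10)

  # idempotence: normalizing already-normalized data changes nothing
  nf2 <- normalize_features(nf$X_norm, nf$y_norm)
  expect_equal(nf2$X_norm, nf$X_norm, tolerance = 1e-10)

  # inverse transform restores the originals
  back <- sweep(sweep(nf$X_norm, 2, nf$norm$feature_sds, "*"), 2,
                -nf$norm$feature_means)
  expect_equal(back, X, tolerance = 1e-10)

  Xc <- cbind(a = c(1, 2, 3), const = c(7, 7, 7))
  expect_warning(nfc <- normalize_features(Xc, y), "zero-variance")
  expect_identical(nfc$norm$dropped, "const")
  expect_identical(colnames(nfc$X_norm), "a")

  expect_error(normalize_features(X[1, , drop = FALSE], y[1]), "2 samples")
})

test_that("the normal-equation fit reproduces an exact linear relationship", {
  fit <- fit_lr(cbind(x = c(-1, 0, 1)), c(-1, 0, 1))
  expect_equal(unname(fit$weights), 1, tolerance = 1e-12)
  expect_equal(fit$bias, 0, tolerance = 1e-12)

  # raw-space check through the data-frame interface: y = 2x exactly
  dat <- tibble::tibble(x1 = c(1, 2, 3), y = c(2, 4, 6))
  model <- fit_texture_lm(dat, "y", features = "x1")
  expect_equal(predict(model, dat), dat$y, tolerance = 1e-10)
})

test_that("planted weights are recovered from a noiseless design", {
  withr::local_seed(3)
  n <- 200; p <- 45
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("j", 1:p)
  w_true <- rnorm(p)
  y <- drop(X %*% w_true) + 1.5
  nf <- normalize_features(X, y)
  fit <- fit_lr(nf$X_norm, nf$y_norm)
  # map the normalized-space weights back to raw scale and compare
  w_raw <- fit$weights / nf$norm$feature_sds * nf$norm$target_sd
  expect_equal(unname(w_raw), w_true, tolerance = 1e-6)
  # residuals vanish and their mean is zero (bias absorbs it)
  model <- fit_texture_lm(as.data.frame(cbind(X, y = y)), "y")
  expect_equal(mean(predict(model, as.data.frame(X)) - y), 0, tolerance = 1e-8)
})

test_that("pure-noise targets yield near-zero weights and correlation", {
  withr::local_seed(4)
  n <- 1000
  X <- matrix(rnorm(n * 10), n, 10, dimnames = list(NULL, paste0("j", 1:10)))
  y <- rnorm(n)
  nf <- normalize_features(X, y)
  fit <- fit_lr(nf$X_norm, nf$y_norm)
  expect_lt(max(abs(fit$weights)), 0.15)
  preds <- drop(nf$X_norm %*% fit$weights) + fit$bias
  expect_lt(abs(pearson_cc(preds, nf$y_norm)), 0.25)
})

test_that("the sample-size precondition is enforced", {
  X <- matrix(rnorm(20), 4, 5, dimnames = list(NULL, paste0("j", 1:5)))
  expect_error(fit_lr(X, rnorm(4)), "samples < features")
})

test_that("first-order optimality: perturbing any weight cannot lower the MSE", {
  withr::local_seed(6)
  X <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("j", 1:5)))
  y <- drop(X %*% rnorm(5)) + rnorm(60)
  nf <- normalize_features(X, y)
  fit <- fit_lr(nf$X_norm, nf$y_norm)
  mse_at <- function(w, b) mean((nf$y_norm - drop(nf$X_norm %*% w) - b)^2)
  base <- mse_at(fit$weights, fit$bias)
  for (j in seq_along(fit$weights)) {
    for (eps in c(-1e-3, 1e-3)) {
      w <- fit$weights; w[j] <- w[j] + eps
      expect_gte(mse_at(w, fit$bias), base)
    }
  }
})

test_that("coordinate-descent LASSO agrees with its closed forms", {
  withr::local_seed(7)
  n <- 80
  X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("j", 1:8)))
  y <- drop(X %*% c(2, -1, 0, 0, 1, 0, 0, 0.5)) + rnorm(n, sd = 0.5)
  nf <- normalize_features(X, y)

  # lambda = 0 reproduces the normal-equation solution
  lr <- fit_lr(nf$X_norm, nf$y_norm)
  l0 <- fit_lasso(nf$X_norm, nf$y_norm, lambda = 0)
  expect_equal(l0$weights, lr$weights, tolerance = 1e-6)
  expect_equal(l0$bias, lr$bias, tolerance = 1e-6)

  # single standardized feature: w = soft-threshold of the OLS coordinate
  x1 <- nf$X_norm[, 1, drop = FALSE]
  for (lam in c(0.5, 5, 50)) {
    f1 <- fit_lasso(x1, nf$y_norm, lambda = lam)
    rho <- sum(x1 * (nf$y_norm - mean(nf$y_norm)))
    expected <- sign(2 * rho) * max(abs(2 * rho) - lam, 0) / (2 * sum(x1^2))
    expect_equal(unname(f1$weights), expected, tolerance = 1e-7)
  }

  # full shrinkage at and above lambda_max
  lmax <- lasso_lambda_max(nf$X_norm, nf$y_norm)
  fmax <- fit_lasso(nf$X_norm, nf$y_norm, lambda = lmax * 1.0001)
  expect_true(all(fmax$weights == 0))
})

test_that("the LASSO solution satisfies the KKT conditions", {
  withr::local_seed(8)
  n <- 100
  X <- matrix(rnorm(n * 12), n, 12, dimnames = list(NULL, paste0("j", 1:12)))
  y <- drop(X %*% c(3, -2, 1, rep(0, 9))) + rnorm(n)
  nf <- normalize_features(X, y)
  lam <- 0.3 * lasso_lambda_max(nf$X_norm, nf$y_norm)
  fit <- fit_lasso(nf$X_norm, nf$y_norm, lam)
  r <- nf$y_norm - drop(nf$X_norm %*% fit$weights) - fit$bias
  grad <- -2 * drop(crossprod(nf$X_norm, r))  # gradient of the smooth part
  active <- fit$weights != 0
  expect_true(all(abs(grad[!active]) <= lam + 1e-6))
  expect_equal(grad[active], -lam * sign(fit$weights[active]), tolerance = 1e-5)
})

test_that("the coordinate-descent solution matches glmnet", {
  skip_if_not_installed("glmnet")
  withr::local_seed(9)
  n <- 120
  X <- matrix(rnorm(n * 15), n, 15, dimnames = list(NULL, paste0("j", 1:15)))
  y <- drop(X %*% c(2, -1.5, 1, rep(0, 12))) + rnorm(n)
  nf <- normalize_features(X, y)
  lam_ours <- 0.2 * lasso_lambda_max(nf$X_norm, nf$y_norm)
  ours <- fit_lasso(nf$X_norm, nf$y_norm, lam_ours, tol = 1e-12)
  # glmnet minimizes RSS/(2n) + lambda*|w|; ours minimizes RSS + lambda*|w|
  g <- glmnet::glmnet(nf$X_norm, nf$y_norm, alpha = 1,
                      lambda = lam_ours / (2 * n),
                      standardize = FALSE, intercept = TRUE,
                      thresh = 1e-14)
  expect_equal(unname(ours$weights), as.numeric(g$beta), tolerance = 1e-4)
  expect_equal(ours$bias, as.numeric(g$a0), tolerance = 1e-4)
})

test_that("the LASSO path trades accuracy for sparsity monotonically", {
  co <- generate_cohort(sim_config(n_subjects = 40, n_slices = 1, seed = 13))
  ft <- extract_cohort_features(co)
  X <- as.matrix(ft[paste0("j", 1:45)])
  nf <- normalize_features(X, ft$bmc_true)
  lmax <- lasso_lambda_max(nf$X_norm, nf$y_norm)
  path <- lasso_path(ft, "bmc_true",
                     lambda_grid = c(0, 10^seq(-2, 0, length.out = 8) * lmax))
  td <- tidy(path)
  expect_identical(td$nonzero[nrow(td)], 0L)           # full shrinkage
  expect_true(all(diff(td$mse) >= -1e-8))              # MSE non-decreasing
  lr <- fit_texture_lm(ft, "bmc_true")
  expect_equal(td$cc[1], glance(lr)$cc, tolerance = 1e-6)  # endpoint identity
  expect_error(lasso_path(ft, "bmc_true", lambda_grid = c(1, 2)), "include 0")
})

test_that("prediction round-trips the normalization exactly", {
  withr::local_seed(10)
  dat <- tibble::as_tibble(as.data.frame(
    matrix(rnorm(50 * 6), 50, 6, dimnames = list(NULL, paste0("j", 1:6)))
  ))
  dat$y <- drop(as.matrix(dat) %*% rnorm(6)) + 5
  model <- fit_texture_lm(dat, "y")
  # exact-fit problem: predictions reproduce training targets
  expect_equal(predict(model, dat), dat$y, tolerance = 1e-8)
  # all-mean input predicts the de-normalized bias
  at_mean <- tibble::as_tibble(as.list(model$norm$feature_means))
  expect_equal(predict(model, at_mean),
               model$norm$target_mean + model$norm$target_sd * model$bias,
               tolerance = 1e-10)
  expect_error(predict(model, dat[, 1:3]), "lacks feature")
})

test_that("model JSON serialization round-trips predictions", {
  co <- generate_cohort(sim_config(n_subjects = 25, n_slices = 1, seed = 14))
  ft <- extract_cohort_features(co)
  model <- fit_texture_lm(ft, "bmc_true")
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(model, path)
  back <- read_model_json(path)
  expect_equal(predict(back, ft), predict(model, ft), tolerance = 1e-12)
  expect_identical(back$target_name, "bmc_true")
})

test_that("tidiers expose terms and fit summaries", {
  dat <- tibble::as_tibble(as.data.frame(
    matrix(rnorm(40 * 4), 40, 4, dimnames = list(NULL, paste0("j", 1:4)))
  ))
  dat$y <- rnorm(40)
  model <- fit_texture_lm(dat, "y")
  td <- tidy(model)
  expect_identical(td$term[1], "(bias)")
  expect_identical(nrow(td), 5L)
  gl <- glance(model)
  expect_identical(gl$n, 40L)
  aug <- augment(model, dat)
  expect_true(all(c(".pred", ".resid") %in% names(aug)))
  expect_equal(aug$.resid, dat$y - aug$.pred)
})

test_that("the small neural network trains deterministically and learns a line", {
  withr::local_seed(11)
  dat <- tibble::as_tibble(as.data.frame(
    matrix(rnorm(150 * 5), 150, 5, dimnames = list(NULL, paste0("j", 1:5)))
  ))
  dat$y <- drop(as.matrix(dat[paste0("j", 1:5)]) %*% c(1, -2, 0.5, 0, 1))

  a <- fit_texture_ann(dat, "y", epochs = 1500, learning_rate = 0.02, seed = 7)
  b <- fit_texture_ann(dat, "y", epochs = 1500, learning_rate = 0.02, seed = 7)
  expect_identical(a$layers, b$layers)  # same seed, same weights

  # training MSE is non-increasing overall (full-batch, small step)
  expect_lt(tail(a$mse_trace, 1), a$mse_trace[1])

  lr_cc <- glance(fit_texture_lm(dat, "y"))$cc
  ann_cc <- pearson_cc(predict(a, dat), dat$y)
  expect_gte(ann_cc, lr_cc - 0.05)

  # zero-epoch budget returns the initialized network
  init <- fit_texture_ann(dat, "y", epochs = 0, seed = 7)
  expect_length(init$mse_trace, 0)
  expect_equal(length(predict(init, dat)), nrow(dat))
})
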