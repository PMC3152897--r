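test_that("standardization uses training statistics (population variance)", {
  tr <- cbind(a = c(1, 3), b = c(0, 10))
  z <- standardize(tr)
  expect_equal(unname(z[, "a"]), c(-1, 1))
  expect_equal(colMeans(z), c(a = 0, b = 0))
  expect_equal(colMeans(z^2), c(a = 1, b = 1))   # population convention
  # new data transformed by the training statistics, not its own
  nv <- standardize(tr, cbind(a = 5, b = 5))
  expect_equal(unname(nv[1, "a"]), (5 - 2) / 1)
  expect_warning(zc <- standardize(cbind(k = c(2, 2, 2))), "constant")
  expect_equal(unname(zc[, 1]), c(0, 0, 0))
  expect_error(standardize(tr, cbind(a = 1)), "mismatch")
})

test_that("ridge-logistic IRLS matches an independent optimizer", {
  set.seed(11)
  X <- matrix(rnorm(16), 8, 2)
  y <- c(0, 1, 0, 1, 1, 0, 1, 0)
  lam <- 1
  fit <- fit_ridge_logistic(X, y, lambda = lam)
  nll <- function(b) {
    eta <- b[1] + X %*% b[-1]
    -sum(y * eta - log1p(exp(eta))) + lam * sum(b[-1]^2)
  }
  for (s in 1:3) {
    set.seed(s)
    o <- optim(rnorm(3), nll, method = "BFGS",
               control = list(reltol = 1e-15, maxit = 500))
    expect_equal(unname(coef(fit)), o$par, tolerance = 1e-5)
  }
})

test_that("ridge-logistic limits behave: symmetry zero, heavy shrinkage", {
  f <- fit_ridge_logistic(matrix(c(-1, 1, -1, 1), 4, 1), c(0, 0, 1, 1),
                          lambda = 1e-8)
  expect_equal(unname(coef(f)), c(0, 0), tolerance = 1e-6)
  set.seed(12)
  X <- matrix(rnorm(40), 20, 2)
  y <- rep(c(0, 1), c(5, 15))
  fh <- fit_ridge_logistic(X, y, lambda = 1e6)
  expect_lt(max(abs(fh$coefficients)), 1e-4)
  expect_equal(fh$intercept, log(15 / 5), tolerance = 1e-2)
  expect_error(fit_ridge_logistic(X, rep(1, 20)), "both classes")
})

test_that("ridge-logistic agrees with glmnet under matched penalties", {
  skip_if_not_installed("glmnet")
  set.seed(13)
  n <- 60
  X <- matrix(rnorm(n * 3), n, 3)
  y <- rbinom(n, 1, plogis(X %*% c(1, -0.5, 0.2)))
  lam <- 2
  fit <- fit_ridge_logistic(X, y, lambda = lam)
  # glmnet minimizes -loglik/n + lambda_g/2 * ||beta||^2
  g <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                      lambda = 2 * lam / n, standardize = FALSE,
                      thresh = 1e-14)
  expect_equal(unname(fit$coefficients), as.numeric(g$beta), tolerance = 1e-3)
  expect_equal(fit$intercept, unname(g$a0), tolerance = 1e-3)
})

test_that("parameters are recovered on synthetic logistic data", {
  # near-unpenalized fit equals the maximum-likelihood solution
  set.seed(14)
  n <- 500
  beta <- c(1.2, -0.8)
  X <- matrix(rnorm(n * 2), n, 2)
  y <- rbinom(n, 1, plogis(0.3 + X %*% beta))
  fit <- fit_ridge_logistic(X, y, lambda = 1e-8)
  ml <- stats::glm(y ~ X, family = stats::binomial(),
                   control = list(epsilon = 1e-12))
  expect_equal(unname(coef(fit)), unname(stats::coef(ml)), tolerance = 1e-5)
  # and at a sample size where the MLE standard error sits well inside a
  # 10% band, the known coefficients are recovered to that accuracy
  set.seed(14)
  n <- 4000
  X <- matrix(rnorm(n * 2), n, 2)
  y <- rbinom(n, 1, plogis(0.3 + X %*% beta))
  fit <- fit_ridge_logistic(X, y, lambda = 1e-8)
  expect_lt(max(abs(fit$coefficients - beta) / abs(beta)), 0.1)
  expect_equal(fit$intercept, 0.3, tolerance = 0.15)
})

test_that("AUC follows the Mann-Whitney pair formulation", {
  expect_equal(auc(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auc(c(0.2, 0.4, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  expect_equal(auc(rep(0.3, 4), c(1, 1, 0, 0)), 0.5)
  set.seed(15)
  s <- rnorm(30); y <- rbinom(30, 1, 0.5); y[1:2] <- 0:1
  # invariance under strictly increasing transforms; label-flip complement
  expect_equal(auc(s, y), auc(exp(s), y))
  expect_equal(auc(s, y) + auc(s, 1 - y), 1)
  if (requireNamespace("pROC", quietly = TRUE)) {
    expect_equal(auc(s, y),
                 as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                                direction = "<"))))
  }
  expect_error(auc(s, rep(1, 30)), "both classes")
})

test_that("LOOCV separates planted panels and degrades on noise", {
  ds <- synth_expression(200, de_genes = setNames(rep(1.5, 3),
                                                  c("G0001", "G0002", "G0003")),
                         seed = 1)
  ev <- loocv_evaluate(ds, feature_panel("planted",
                                         genes = c("G0001", "G0002", "G0003")))
  expect_gte(ev$auc, 0.8)
  expect_equal(length(ev$oof_scores), 32L)
  expect_true(all(ev$oof_scores >= 0 & ev$oof_scores <= 1))

  # feature identical to the label
  m <- matrix(rep(c(0, 1), each = 16), nrow = 1,
              dimnames = list("F", sprintf("S%02d", 1:32)))
  dsl <- expression_dataset(m, labels = rep(c("good", "poor"), each = 16))
  expect_equal(loocv_evaluate(dsl, feature_panel("lab", genes = "F"))$auc, 1)

  # pure noise: LOOCV with prevalence-shifted folds anti-learns on average
  aucs <- vapply(1:100, function(s) {
    d <- synth_expression(1, seed = s)
    loocv_evaluate(d, feature_panel("noise", genes = "G0001"))$auc
  }, numeric(1))
  expect_lt(mean(aucs), 0.5)
})

test_that("fold-scoped scaling never reads the held-out sample while training", {
  ds <- synth_expression(5, n_good = 6, n_poor = 6, seed = 16)
  i <- 3L
  others <- setdiff(seq_along(ds$samples), i)
  panel <- feature_panel("taint", genes = ds$genes[1:3])
  # manual fit on the n-1 retained samples
  X <- t(ds$matrix[1:3, ])
  ytr <- as.numeric(ds$labels[others] == "poor")
  Xtr <- standardize(X[others, ])
  fit <- fit_ridge_logistic(Xtr, ytr)
  for (shift in c(0, 50)) {
    ds2 <- ds
    ds2$matrix[1:3, i] <- ds$matrix[1:3, i] + shift
    ev <- loocv_evaluate(ds2, panel)
    Xte <- standardize(X[others, ], matrix(ds2$matrix[1:3, i], 1))
    # fold-i score is exactly the untainted model applied to the held-out row:
    # perturbing that row never alters the trained coefficients
    expect_equal(unname(ev$oof_scores[i]), unname(predict(fit, Xte)),
                 tolerance = 1e-9)
  }
})

test_that("train-on-A score-on-B evaluation works across datasets", {
  tr <- synth_expression(10, de_genes = c(G0001 = 2, G0002 = 2), seed = 17)
  te <- synth_expression(10, n_good = 5, n_poor = 6,
                         de_genes = c(G0001 = 2, G0002 = 2), seed = 18)
  res <- train_test_evaluate(tr, te, feature_panel("x", genes = c("G0001", "G0002")))
  expect_equal(length(res$scores), 11L)
  expect_gt(res$auc, 0.7)
})
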