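#' Feature panels
#'
#' An ordered set of classifier inputs: individual genes and/or module
#' mean-expression profiles.
#'
#' @param name panel identifier.
#' @param genes character vector of gene features.
#' @param modules character vector of module ids whose mean profiles are
#'   features (resolved against `partition` at evaluation time).
#' @return An object of class `feature_panel`.
#' @export
feature_panel <- function(name, genes = character(0), modules = character(0)) {
  genes <- as.character(genes); modules <- as.character(modules)
  if (!length(genes) && !length(modules)) stop("panel must be non-empty")
  if (anyDuplicated(genes) || anyDuplicated(modules))
    stop("duplicate features in panel")
  structure(list(name = as.character(name), genes = genes, modules = modules),
            class = "feature_panel")
}

#' @export
print.feature_panel <- function(x, ...) {
  cat("feature_panel '", x$name, "': ", length(x$genes), " gene(s), ",
      length(x$modules), " module mean(s)\n", sep = "")
  invisible(x)
}

# samples x features numeric matrix for a panel
panel_feature_matrix <- function(ds, panel, partition = NULL) {
  stopifnot(inherits(ds, "expression_dataset"), inherits(panel, "feature_panel"))
  cols <- list()
  if (length(panel$genes)) {
    unknown <- setdiff(panel$genes, ds$genes)
    if (length(unknown))
      stop("panel genes without expression data: ",
           paste(unknown, collapse = ", "))
    for (g in panel$genes) cols[[g]] <- ds$matrix[g, ]
  }
  if (length(panel$modules)) {
    if (is.null(partition))
      stop("module-mean features require a module partition")
    assignment <- if (inherits(partition, "module_partition"))
      partition$assignment else partition
    for (mid in panel$modules) {
      mg <- names(assignment)[as.character(assignment) == mid]
      if (!length(mg)) stop("module '", mid, "' not found in partition")
      cols[[paste0("module_mean_", mid)]] <-
        suppressMessages(module_mean_profile(ds, mg))
    }
  }
  do.call(cbind, cols)
}

#' Column standardization from training statistics
#'
#' Centers and scales the columns of `apply_to` by the column means and
#' standard deviations of `train` (population convention, dividing by n,
#' so the training columns get exactly unit variance). Zero-variance
#' training columns pass through as zeros with a warning.
#'
#' @param train numeric matrix (>= 2 rows) supplying the statistics.
#' @param apply_to matrix to transform (defaults to `train`).
#' @return The transformed `apply_to`.
#' @export
standardize <- function(train, apply_to = train) {
  train <- as.matrix(train); apply_to <- as.matrix(apply_to)
  if (nrow(train) < 2L) stop("`train` needs >= 2 rows")
  if (ncol(train) != ncol(apply_to)) stop("column dimension mismatch")
  mu <- colMeans(train)
  sdv <- sqrt(colMeans(sweep(train, 2L, mu)^2))
  zero <- sdv == 0
  if (any(zero)) {
    warning("constant training column(s) passed through as zeros: ",
            paste(colnames(train)[zero], collapse = ", "))
    sdv[zero] <- 1
  }
  out <- sweep(sweep(apply_to, 2L, mu), 2L, sdv, "/")
  out[, zero] <- 0
  out
}

#' Ridge-penalized logistic regression
#'
#' Maximizes `sum(log-likelihood) - lambda * sum(beta^2)` (intercept
#' unpenalized) by iteratively reweighted least squares with step halving.
#' Convergence when the largest absolute parameter change falls below
#' `tol` or the penalized deviance stabilizes (relative change below
#' `tol`); non-convergence raises an error carrying the last iterate. With
#' `lambda > 0` the objective is strictly concave, so the optimum is
#' unique.
#'
#' @param X numeric matrix, samples x features.
#' @param y binary response: 0/1, logical, or a good/poor factor (`poor`
#'   is the positive class).
#' @param lambda ridge penalty (default 1e-8, a near-unpenalized fit whose
#'   tiny penalty keeps the optimum finite on separable data).
#' @param max_iter,tol IRLS controls.
#' @return An object of class `ridge_logistic`: list with `intercept`,
#'   `coefficients` (named by feature), `lambda`, `converged`,
#'   `iterations`, `deviance`.
#' @export
fit_ridge_logistic <- function(X, y, lambda = 1e-8, max_iter = 200L,
                               tol = 1e-8) {
  X <- as.matrix(X)
  y <- encode_response(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (lambda < 0) stop("`lambda` must be >= 0")
  p <- ncol(X)
  Xa <- cbind(`(intercept)` = 1, X)
  pen <- c(0, rep(2 * lambda, p))     # d/dbeta of lambda * beta^2 pieces
  beta <- numeric(p + 1L)
  obj <- function(b) {
    eta <- drop(Xa %*% b)
    # numerically safe -2*(penalized loglik)
    2 * (sum(log1p(exp(-abs(eta))) + pmax(eta, 0) - y * eta) +
           lambda * sum(b[-1L]^2))
  }
  dev <- obj(beta)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    eta <- drop(Xa %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    grad <- drop(crossprod(Xa, y - mu)) - pen * beta / 2 * 2
    H <- crossprod(Xa * w, Xa)
    diag(H) <- diag(H) + pen
    step <- tryCatch(solve(H, grad), error = function(e)
      solve(H + diag(1e-10, p + 1L), grad))
    # step halving on the penalized deviance
    fac <- 1
    repeat {
      cand <- beta + fac * step
      dev_new <- obj(cand)
      if (dev_new <= dev + 1e-12 || fac < 1e-8) break
      fac <- fac / 2
    }
    delta <- max(abs(cand - beta))
    rel <- abs(dev - dev_new) / (abs(dev_new) + 0.1)
    beta <- cand
    dev <- dev_new
    if (delta < tol || rel < tol) { converged <- TRUE; break }
  }
  fit <- structure(
    list(intercept = unname(beta[1L]),
         coefficients = setNames(beta[-1L],
                                 colnames(X) %||% paste0("x", seq_len(p))),
         lambda = lambda, converged = converged, iterations = it,
         deviance = dev),
    class = "ridge_logistic"
  )
  if (!converged)
    stop(errorCondition(
      paste0("IRLS did not converge in ", max_iter, " iterations"),
      fit = fit, class = "netmarker_nonconvergence"))
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

encode_response <- function(y) {
  if (is.factor(y)) {
    if (all(levels(y) %in% c("good", "poor"))) return(as.numeric(y == "poor"))
    if (nlevels(y) == 2L) return(as.numeric(y == levels(y)[2L]))
    stop("factor response must have two levels")
  }
  if (is.logical(y)) return(as.numeric(y))
  if (is.character(y)) {
    if (!all(y %in% c("good", "poor"))) stop("character response must be good/poor")
    return(as.numeric(y == "poor"))
  }
  if (!all(y %in% c(0, 1))) stop("numeric response must be 0/1")
  as.numeric(y)
}

#' @export
print.ridge_logistic <- function(x, ...) {
  cat("ridge_logistic (lambda =", format(x$lambda), "),",
      x$iterations, "IRLS iterations\n")
  print(c(`(intercept)` = x$intercept, x$coefficients))
  invisible(x)
}

#' @export
coef.ridge_logistic <- function(object, ...) {
  c(`(intercept)` = object$intercept, object$coefficients)
}

#' @export
predict.ridge_logistic <- function(object, newdata,
                                   type = c("response", "link"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  eta <- object$intercept + drop(newdata %*% object$coefficients)
  if (type == "link") eta else 1 / (1 + exp(-eta))
}

#' Area under the ROC curve (rank formulation)
#'
#' The fraction of (positive, negative) pairs in which the positive scores
#' higher, ties counting 0.5 — the Mann-Whitney formulation of the AUC.
#'
#' @param scores numeric scores (higher = more "poor").
#' @param labels binary labels: 0/1, logical, or a good/poor vector
#'   (`poor` positive).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  y <- encode_response(labels)
  if (length(scores) != length(y)) stop("scores and labels differ in length")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classifier configuration
#'
#' @param ridge_lambda ridge penalty (default 1e-8).
#' @param standardize re-scale inputs to mean 0, variance 1 (default TRUE).
#' @param scaler_scope `"fold"` (statistics from each training fold only;
#'   leakage-free, the default) or `"global"` (whole-dataset statistics).
#' @param max_iter,tol IRLS controls.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(ridge_lambda = 1e-8, standardize = TRUE,
                              scaler_scope = c("fold", "global"),
                              max_iter = 200L, tol = 1e-8) {
  scaler_scope <- match.arg(scaler_scope)
  if (ridge_lambda < 0) stop("`ridge_lambda` must be >= 0")
  if (tol <= 0) stop("`tol` must be > 0")
  structure(list(ridge_lambda = ridge_lambda, standardize = standardize,
                 scaler_scope = scaler_scope, max_iter = as.integer(max_iter),
                 tol = tol),
            class = "classifier_config")
}

#' Leave-one-out cross-validated panel evaluation
#'
#' Each sample is scored (predicted probability of poor outcome) by a
#' ridge-logistic model trained on the remaining n - 1 samples, with
#' feature standardization per `cfg$scaler_scope`; the pooled out-of-fold
#' scores are summarized by [auc()].
#'
#' @param ds an [expression_dataset].
#' @param panel a [feature_panel].
#' @param cfg a [classifier_config].
#' @param partition module partition, required when the panel contains
#'   module-mean features.
#' @return An object of class `panel_evaluation`: list with `panel`,
#'   `oof_scores` (named by sample), `auc`, `labels`, `config`.
#' @export
loocv_evaluate <- function(ds, panel, cfg = classifier_config(),
                           partition = NULL) {
  stopifnot(inherits(ds, "expression_dataset"),
            inherits(panel, "feature_panel"),
            inherits(cfg, "classifier_config"))
  X <- panel_feature_matrix(ds, panel, partition)
  y <- encode_response(ds$labels)
  n <- nrow(X)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    tr_idx <- setdiff(seq_len(n), i)
    if (length(unique(y[tr_idx])) < 2L)
      stop("training fold ", i, " lost one outcome class")
    Xtr <- X[tr_idx, , drop = FALSE]
    Xte <- X[i, , drop = FALSE]
    if (cfg$standardize) {
      ref <- if (cfg$scaler_scope == "global") X else Xtr
      Xte <- suppressWarnings(standardize(ref, Xte))
      Xtr <- suppressWarnings(standardize(ref, Xtr))
    }
    fit <- fit_ridge_logistic(Xtr, y[tr_idx], lambda = cfg$ridge_lambda,
                              max_iter = cfg$max_iter, tol = cfg$tol)
    scores[i] <- predict(fit, Xte)
  }
  names(scores) <- ds$samples
  structure(
    list(panel = panel, oof_scores = scores,
         auc = auc(scores, ds$labels), labels = ds$labels, config = cfg),
    class = "panel_evaluation"
  )
}

#' @export
print.panel_evaluation <- function(x, ...) {
  cat("panel_evaluation '", x$panel$name, "': LOOCV AUC = ",
      format(x$auc, digits = 3), " (n = ", length(x$oof_scores), ")\n",
      sep = "")
  invisible(x)
}

#' Train on one dataset, score another
#'
#' Fits the panel's ridge-logistic model on dataset `train` and returns
#' predicted poor-outcome probabilities and AUC on dataset `test` — the
#' cross-platform verification pattern (e.g. a microarray-derived model
#' scored on qPCR measurements of the same genes).
#'
#' @param train,test [expression_dataset]s sharing the panel's features.
#' @param panel a [feature_panel].
#' @param cfg a [classifier_config].
#' @param partition optional module partition for module-mean features.
#' @return List with `scores` (on `test`), `auc`, and the fitted model.
#' @export
train_test_evaluate <- function(train, test, panel, cfg = classifier_config(),
                                partition = NULL) {
  Xtr <- panel_feature_matrix(train, panel, partition)
  Xte <- panel_feature_matrix(test, panel, partition)
  if (cfg$standardize) {
    Xte <- suppressWarnings(standardize(Xtr, Xte))
    Xtr <- suppressWarnings(standardize(Xtr, Xtr))
  }
  fit <- fit_ridge_logistic(Xtr, encode_response(train$labels),
                            lambda = cfg$ridge_lambda,
                            max_iter = cfg$max_iter, tol = cfg$tol)
  sc <- predict(fit, Xte)
  names(sc) <- test$samples
  list(scores = sc, auc = auc(sc, test$labels), fit = fit)
}
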