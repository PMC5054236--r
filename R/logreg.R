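## Regularized logistic regression, AUC, and nested cross-validation.
##
## The fitted objective is
##   f(w, w0) = 1/2 ||w||^2 + lambda * sum_i log(1 + exp(-y_i (w'X_i + w0)))
## with y_i in {-1, +1} and the intercept unpenalized. lambda multiplies the
## loss term, so SMALLER lambda means STRONGER regularization (the
## C-parameter convention of liblinear-style solvers).

## labels -> {-1, +1}; accepts "positive"/"negative", logical, 0/1, -1/+1
label_signs <- function(y) {
  if (is.character(y) || is.factor(y)) {
    y <- as.character(y)
    bad <- !y %in% c("positive", "negative")
    if (any(bad)) stop("character labels must be 'positive'/'negative'")
    return(ifelse(y == "positive", 1, -1))
  }
  y <- as.numeric(y)
  if (all(y %in% c(0, 1))) return(2 * y - 1)
  if (all(y %in% c(-1, 1))) return(y)
  stop("labels must be binary")
}

#' Fit the regularized logistic model
#'
#' Minimizes `1/2 ||w||^2 + lambda * sum_i log(1 + exp(-y_i (w'X_i + w0)))`
#' over the weights `w` and the unpenalized intercept `w0`, with labels
#' coded -1/+1. Smaller `lambda` means stronger regularization. The strictly
#' convex objective is minimized by L-BFGS with an analytic gradient; the
#' returned fit records the achieved objective and gradient norm.
#'
#' @param X Numeric matrix or sparse `Matrix` of feature counts (documents
#'   in rows).
#' @param y Binary labels: `"positive"`/`"negative"`, 0/1, or -1/+1. Both
#'   classes must be present.
#' @param lambda Positive scalar loss weight.
#' @param w_init,w0_init Optional warm-start values.
#' @param maxit Newton iteration cap.
#' @param tol Convergence: stop when the gradient norm is at most
#'   `tol * (1 + ||w||)`.
#' @param max_cg Conjugate-gradient iteration cap per Newton step.
#' @return A `logreg_model`: list with `w` (named if `X` has column names),
#'   `w0`, `lambda`, `objective`, `grad_norm`, `converged`.
#' @export
fit_logreg <- function(X, y, lambda, w_init = NULL, w0_init = 0,
                       maxit = 100L, tol = 1e-6, max_cg = 200L) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0) {
    stop("lambda must be a positive scalar")
  }
  yt <- label_signs(y)
  if (length(unique(yt)) < 2L) stop("both classes must be present in y")
  if (nrow(X) != length(yt)) stop("nrow(X) must equal length(y)")
  Xs <- as(as(Matrix::Matrix(X, sparse = TRUE), "generalMatrix"),
           "CsparseMatrix")
  if (any(!is.finite(Xs@x))) stop("X contains non-finite entries")
  p <- ncol(Xs)
  w0 <- if (is.null(w_init)) numeric(p) else as.numeric(w_init)
  fit <- logreg_newton_cpp(Xs@i, Xs@p, Xs@x, nrow(Xs), p, yt, lambda,
                           w0, w0_init, as.integer(maxit), tol,
                           as.integer(max_cg))
  w <- fit$w
  if (!is.null(colnames(X))) names(w) <- colnames(X)
  structure(list(
    w = w, w0 = fit$w0, lambda = lambda,
    objective = fit$objective,
    grad_norm = fit$grad_norm,
    iterations = fit$iterations,
    converged = fit$converged
  ), class = "logreg_model")
}

#' @export
print.logreg_model <- function(x, ...) {
  cat(sprintf("<logreg_model> %d features, lambda = %g, objective = %.6g\n",
              length(x$w), x$lambda, x$objective))
  invisible(x)
}

#' Linear scores from a fitted logistic model
#'
#' Returns `w'X_i + w0` per row: a monotone transform of the class
#' probability, sufficient for AUC ranking.
#'
#' @param model A `logreg_model`.
#' @param X Matrix with the same number of columns the model was fit on.
#' @return Numeric vector of scores.
#' @export
predict_scores <- function(model, X) {
  if (ncol(X) != length(model$w)) {
    stop("X has ", ncol(X), " columns but the model has ", length(model$w),
         " weights")
  }
  as.numeric(X %*% model$w) + model$w0
}

#' Area under the ROC curve
#'
#' The Mann-Whitney form: the probability that a random positive is scored
#' above a random negative, with tied pairs receiving half credit. Computed
#' via midranks, which agrees exactly with the brute-force count over all
#' positive-negative pairs.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (see [fit_logreg()] coding).
#' @return AUC in `[0, 1]`; 0.5 is chance level.
#' @export
auc <- function(scores, labels) {
  yt <- label_signs(labels)
  if (length(scores) != length(yt)) stop("scores and labels differ in length")
  n_pos <- sum(yt > 0)
  n_neg <- sum(yt < 0)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[yt > 0]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Stratified fold assignment
#'
#' Shuffles each class separately (seeded) and deals indices round-robin, so
#' each fold's count of each class differs from any other fold's by at most
#' one.
#'
#' @param y Binary labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`.
#' @export
make_folds <- function(y, k, seed) {
  yt <- label_signs(y)
  if (min(sum(yt > 0), sum(yt < 0)) < k) {
    stop("each class needs at least k members for k folds")
  }
  folds <- integer(length(yt))
  with_seed(seed, {
    for (cls in c(-1, 1)) {
      idx <- which(yt == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Nested cross-validated AUC
#'
#' Splits the data into `k` stratified outer folds. For each outer fold, the
#' loss weight `lambda` is chosen by (k-1)-fold inner cross-validation on
#' the training folds only — the value maximizing mean inner AUC, ties going
#' to the smallest (most regularized) `lambda` — then the model is refit on
#' all training folds at the chosen value and scored on the held-out fold.
#' The default grid is the logarithmic line search 1e-5, 1e-4, ..., 1e2.
#'
#' @param X Feature matrix.
#' @param y Binary labels (each class needs >= `k` members).
#' @param k Number of outer folds (default 5).
#' @param lambda_grid Positive candidate values.
#' @param seed Integer seed for the fold assignments.
#' @return A `cv_result`: `fold_auc`, `mean_auc`, `sd_auc`, `lambda_selected`
#'   (per fold), `folds` (outer assignment), `inner_folds` (per outer fold,
#'   the inner assignment over its training rows), `inner_auc` (per outer
#'   fold, mean inner AUC per grid value), `seed`.
#' @export
cross_validate <- function(X, y, k = 5L, lambda_grid = 10^seq(-5, 2),
                           seed = 1L) {
  if (length(lambda_grid) == 0L) stop("lambda_grid must be non-empty")
  lambda_grid <- sort(as.numeric(lambda_grid))
  if (any(lambda_grid <= 0)) stop("lambda values must be positive")
  yt <- label_signs(y)
  folds <- make_folds(yt, k, seed)
  fold_auc <- numeric(k)
  lambda_sel <- numeric(k)
  inner_folds_all <- vector("list", k)
  inner_auc_all <- vector("list", k)
  for (i in seq_len(k)) {
    tr <- which(folds != i)
    te <- which(folds == i)
    Xtr <- X[tr, , drop = FALSE]
    ytr <- yt[tr]
    inner <- make_folds(ytr, k - 1L, child_seed(seed, i))
    inner_folds_all[[i]] <- inner
    ## mean inner AUC per lambda, warm-starting along the grid
    inner_mean <- numeric(length(lambda_grid))
    auc_mat <- matrix(NA_real_, k - 1L, length(lambda_grid))
    for (j in seq_len(k - 1L)) {
      itr <- which(inner != j)
      ite <- which(inner == j)
      w_prev <- NULL; w0_prev <- 0
      for (l in seq_along(lambda_grid)) {
        m <- fit_logreg(Xtr[itr, , drop = FALSE], ytr[itr], lambda_grid[l],
                        w_init = w_prev, w0_init = w0_prev)
        w_prev <- m$w; w0_prev <- m$w0
        auc_mat[j, l] <- auc(predict_scores(m, Xtr[ite, , drop = FALSE]),
                             ytr[ite])
      }
    }
    inner_mean <- colMeans(auc_mat)
    inner_auc_all[[i]] <- stats::setNames(inner_mean,
                                          format(lambda_grid, trim = TRUE))
    best <- which(inner_mean >= max(inner_mean) - 1e-12)[1L] # tie -> smallest
    lambda_sel[i] <- lambda_grid[best]
    fit <- fit_logreg(Xtr, ytr, lambda_sel[i])
    fold_auc[i] <- auc(predict_scores(fit, X[te, , drop = FALSE]), yt[te])
  }
  structure(list(
    fold_auc = fold_auc, mean_auc = mean(fold_auc), sd_auc = sd(fold_auc),
    lambda_selected = lambda_sel, folds = folds,
    inner_folds = inner_folds_all, inner_auc = inner_auc_all,
    k = as.integer(k), seed = as.integer(seed)
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold mean AUC %.3f (SD %.3f; range %.3f-%.3f)\n",
              x$k, x$mean_auc, x$sd_auc, min(x$fold_auc), max(x$fold_auc)))
  cat("  selected lambda per fold:",
      paste(format(x$lambda_selected, trim = TRUE), collapse = ", "), "\n")
  invisible(x)
}

#' Select lambda by plain k-fold cross-validation
#'
#' The "full-data cross-validated choice" used as the default bootstrap
#' lambda policy: a single (non-nested) k-fold CV over the grid, returning
#' the value with the highest mean AUC (ties to the smallest value).
#'
#' @inheritParams cross_validate
#' @return The selected lambda (scalar).
#' @export
select_lambda <- function(X, y, k = 5L, lambda_grid = 10^seq(-5, 2),
                          seed = 1L) {
  lambda_grid <- sort(as.numeric(lambda_grid))
  yt <- label_signs(y)
  folds <- make_folds(yt, k, seed)
  auc_mat <- matrix(NA_real_, k, length(lambda_grid))
  for (j in seq_len(k)) {
    itr <- which(folds != j)
    ite <- which(folds == j)
    w_prev <- NULL; w0_prev <- 0
    for (l in seq_along(lambda_grid)) {
      m <- fit_logreg(X[itr, , drop = FALSE], yt[itr], lambda_grid[l],
                      w_init = w_prev, w0_init = w0_prev)
      w_prev <- m$w; w0_prev <- m$w0
      auc_mat[j, l] <- auc(predict_scores(m, X[ite, , drop = FALSE]), yt[ite])
    }
  }
  mean_auc <- colMeans(auc_mat)
  lambda_grid[which(mean_auc >= max(mean_auc) - 1e-12)[1L]]
}
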