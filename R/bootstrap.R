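#' Bootstrap coefficient estimates
#'
#' Draws `B` bootstrap resamples of the documents (with replacement), refits
#' the regularized logistic model on each, and summarizes every feature's
#' coefficient by its replicate mean, SD, and normal-approximation 95%
#' confidence interval (mean +/- 1.96 SD). Replicates that draw only one
#' class are redrawn (and counted); a redraw rate above 10% aborts.
#'
#' @param X Feature matrix (documents x features).
#' @param y Binary labels.
#' @param lambda_policy `"fixed"` (default): every replicate uses `lambda`.
#'   `"cv"`: lambda is re-selected per replicate by [select_lambda()]
#'   (computationally heavy).
#' @param lambda The fixed loss weight; typically the full-data
#'   cross-validated choice from [select_lambda()].
#' @param B Number of replicates (study default 1000).
#' @param seed Integer seed.
#' @param retain Character vector of feature names whose per-replicate
#'   coefficient samples to keep (needed by [coefficient_density()]), or
#'   `TRUE` for all features.
#' @param stratified If `TRUE`, resample within each class (off by
#'   default: plain document resampling).
#' @param cv_k,cv_grid Inner CV settings when `lambda_policy = "cv"`.
#' @return A `bootstrap_summary`: tibble `summary` (feature, mean, sd,
#'   ci_lower, ci_upper) plus `B`, `lambda_policy`, `lambda`, `seed`,
#'   `n_redraws`, and `samples` (B x retained matrix or `NULL`).
#' @export
bootstrap_coefficients <- function(X, y, lambda, lambda_policy = c("fixed", "cv"),
                                   B = 1000L, seed = 1L, retain = NULL,
                                   stratified = FALSE, cv_k = 5L,
                                   cv_grid = 10^seq(-5, 2)) {
  lambda_policy <- match.arg(lambda_policy)
  B <- as.integer(B)
  if (B < 2L) stop("B must be >= 2")
  yt <- label_signs(y)
  if (length(unique(yt)) < 2L) stop("both classes must be present")
  n <- nrow(X)
  p <- ncol(X)
  feats <- colnames(X) %||% paste0("f", seq_len(p))

  retain_idx <- NULL
  if (isTRUE(retain)) {
    retain_idx <- seq_len(p)
  } else if (!is.null(retain)) {
    retain_idx <- match(retain, feats)
    if (anyNA(retain_idx)) {
      stop("unknown feature(s) in retain: ",
           paste(retain[is.na(retain_idx)], collapse = ", "))
    }
  }
  samples <- if (!is.null(retain_idx)) {
    matrix(NA_real_, B, length(retain_idx),
           dimnames = list(NULL, feats[retain_idx]))
  } else NULL

  ## full-data fit used as warm start for every replicate
  base_fit <- fit_logreg(X, yt, lambda)

  sum_w <- numeric(p)
  sum_w2 <- numeric(p)
  n_redraws <- 0L
  with_seed(seed, {
    for (b in seq_len(B)) {
      repeat {
        idx <- if (stratified) {
          c(sample(which(yt > 0), sum(yt > 0), replace = TRUE),
            sample(which(yt < 0), sum(yt < 0), replace = TRUE))
        } else {
          sample.int(n, n, replace = TRUE)
        }
        if (length(unique(yt[idx])) == 2L) break
        n_redraws <- n_redraws + 1L
        if (n_redraws > 0.1 * B) {
          stop("more than 10% of bootstrap replicates drew a single class")
        }
      }
      lam_b <- if (lambda_policy == "fixed") lambda else {
        select_lambda(X[idx, , drop = FALSE], yt[idx], k = cv_k,
                      lambda_grid = cv_grid, seed = child_seed(seed, b))
      }
      fit <- fit_logreg(X[idx, , drop = FALSE], yt[idx], lam_b,
                        w_init = base_fit$w, w0_init = base_fit$w0)
      sum_w <- sum_w + fit$w
      sum_w2 <- sum_w2 + fit$w^2
      if (!is.null(samples)) samples[b, ] <- fit$w[retain_idx]
    }
  })
  mean_w <- sum_w / B
  var_w <- pmax(0, (sum_w2 - B * mean_w^2) / (B - 1))
  sd_w <- sqrt(var_w)
  z <- 1.96
  structure(list(
    summary = tibble::tibble(
      feature = feats, mean = unname(mean_w), sd = unname(sd_w),
      ci_lower = unname(mean_w - z * sd_w),
      ci_upper = unname(mean_w + z * sd_w)
    ),
    B = B, lambda_policy = lambda_policy, lambda = lambda,
    seed = as.integer(seed), n_redraws = n_redraws, samples = samples
  ), class = "bootstrap_summary")
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("<bootstrap_summary> %d features, B = %d (lambda %s = %g, %d redraws)\n",
              nrow(x$summary), x$B, x$lambda_policy, x$lambda, x$n_redraws))
  invisible(x)
}

#' Rank features by confidence-interval bound
#'
#' Positively predictive features are ranked in descending order of the
#' lower bound of their bootstrap confidence interval; negative features in
#' ascending order of the upper bound. Ties are broken by replicate mean,
#' then lexicographically by feature name.
#'
#' @param summary A [bootstrap_coefficients()] result.
#' @param direction `"positive"` or `"negative"`.
#' @param top_n How many features to return (study default 25). If larger
#'   than the feature count, all features are returned with a message.
#' @return A tibble (rank, feature, mean, sd, ci_lower, ci_upper).
#' @export
rank_features <- function(summary, direction = c("positive", "negative"),
                          top_n = 25L) {
  direction <- match.arg(direction)
  stopifnot(inherits(summary, "bootstrap_summary"))
  s <- summary$summary
  if (top_n > nrow(s)) {
    message("top_n exceeds the number of features; returning all ", nrow(s))
    top_n <- nrow(s)
  }
  ord <- if (direction == "positive") {
    order(-s$ci_lower, -s$mean, s$feature, method = "radix")
  } else {
    order(s$ci_upper, s$mean, s$feature, method = "radix")
  }
  out <- s[ord[seq_len(top_n)], ]
  out <- tibble::add_column(out, rank = seq_len(nrow(out)), .before = 1L)
  out
}

#' Kernel density of a feature's bootstrap coefficients
#'
#' Gaussian KDE with Silverman's rule-of-thumb bandwidth over the retained
#' replicate samples of one feature, normalized so the curve integrates to 1
#' (trapezoid rule, within 1e-3).
#'
#' @param summary A [bootstrap_coefficients()] result fitted with `retain`
#'   covering `feature`.
#' @param feature Feature name.
#' @return A tibble with `x` (coefficient value) and `y` (density).
#' @export
coefficient_density <- function(summary, feature) {
  stopifnot(inherits(summary, "bootstrap_summary"))
  if (is.null(summary$samples) || !feature %in% colnames(summary$samples)) {
    stop("replicate samples for '", feature, "' were not retained; rerun ",
         "bootstrap_coefficients() with retain = c(\"", feature, "\", ...)")
  }
  x <- summary$samples[, feature]
  if (sd(x) == 0) {
    ## all replicates identical: return a narrow spike centred on the value
    d <- density(x, bw = max(1e-8, abs(x[1]) * 1e-6 + 1e-8))
  } else {
    d <- density(x, bw = "nrd0")
  }
  area <- sum(diff(d$x) * (head(d$y, -1) + d$y[-1]) / 2)
  tibble::tibble(x = d$x, y = d$y / area)
}
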