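# Independent oracles used across the suite. These deliberately use naive,
# transparent algorithms (dense Newton with explicit Hessian solves,
# brute-force pair counting, exhaustive permutation matching) so they share
# no code path with the package implementations they check.

## High-precision dense Newton solver for the regularized logistic objective
## 1/2||w||^2 + lambda * sum log(1+exp(-y (Xw + w0))), intercept unpenalized.
oracle_logreg <- function(X, y, lambda, max_iter = 200, tol = 1e-12) {
  X <- as.matrix(X)
  yt <- ifelse(y %in% c("positive", 1), 1, -1)
  Xt <- cbind(1, X) # column 1 = intercept
  p <- ncol(Xt)
  par <- numeric(p)
  pen <- diag(p)
  pen[1, 1] <- 0 # intercept unpenalized
  for (it in seq_len(max_iter)) {
    m <- yt * as.numeric(Xt %*% par)
    s <- 1 / (1 + exp(m)) # sigma(-m)
    grad <- pen %*% par - lambda * as.numeric(t(Xt) %*% (yt * s))
    d <- s * (1 - s)
    H <- pen + lambda * t(Xt) %*% (Xt * d)
    step <- solve(H, grad)
    ## damped Newton: halve until the objective does not increase
    obj <- function(par) {
      m <- yt * as.numeric(Xt %*% par)
      sum(par[-1]^2) / 2 + lambda * sum(ifelse(m > 30, exp(-m),
                                               log1p(exp(-m))))
    }
    f0 <- obj(par)
    alpha <- 1
    repeat {
      cand <- par - alpha * step
      if (obj(cand) <= f0 + 1e-12 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    par <- par - alpha * as.numeric(step)
    if (sqrt(sum(grad^2)) < tol * (1 + sqrt(sum(par^2)))) break
  }
  list(w0 = par[1], w = par[-1])
}

## Brute-force AUC: loop over all positive-negative pairs, half credit ties.
oracle_auc <- function(scores, labels) {
  yt <- ifelse(labels %in% c("positive", 1), 1, -1)
  pos <- scores[yt > 0]
  neg <- scores[yt < 0]
  total <- 0
  for (sp in pos) {
    for (sn in neg) {
      total <- total + (sp > sn) + 0.5 * (sp == sn)
    }
  }
  total / (length(pos) * length(neg))
}

## Total-variation distance between two discrete distributions.
tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, matrix(seq_len(n)[-i][sub], nrow(sub)))
  }))
}

## Best assignment of fitted topics to true topics by minimal mean TV
## distance (exhaustive over permutations; fine for the K used in tests).
match_topics <- function(beta_fit, beta_true) {
  K <- nrow(beta_true)
  perms <- all_permutations(K)
  best <- Inf
  best_perm <- NULL
  for (r in seq_len(nrow(perms))) {
    d <- mean(vapply(seq_len(K), function(k) {
      tv_dist(beta_fit[perms[r, k], ], beta_true[k, ])
    }, numeric(1)))
    if (d < best) {
      best <- d
      best_perm <- perms[r, ]
    }
  }
  list(perm = best_perm, mean_tv = best)
}

## Small handcrafted corpus reused by io/featurize tests.
tiny_corpus <- function() {
  news_corpus(rbind(
    citation_record("a1", title = "Magnetic resonance imaging study",
                    abstract = "A cohort study of alcohol use in women.",
                    mesh_terms = c("Great Britain", "Humans"),
                    journal = "J Test", year = 2012L, issue = "3",
                    label = "positive", source_tag = "toy"),
    citation_record("a2", title = "Protein binding in mice",
                    abstract = "Signaling proteins and receptor binding were analyzed.",
                    mesh_terms = c("Mice", "Humans"),
                    journal = "J Test", year = 2012L, issue = "3",
                    label = "negative", source_tag = "toy"),
    citation_record("a3", title = "Magnetic resonance of protein structure",
                    abstract = "Cohort data on magnetic resonance and alcohol.",
                    mesh_terms = c("Great Britain", "Mice"),
                    journal = "J Other", year = 2013L, issue = "1",
                    label = "negative", source_tag = "toy")
  ))
}

## Deterministic random labeled scores for AUC comparisons.
random_score_set <- function(n, seed) {
  set.seed(seed)
  list(
    scores = round(rnorm(n), 2), # rounding forces ties regularly
    labels = c(rep(1, ceiling(n / 3)), rep(0, n - ceiling(n / 3)))[sample.int(n)]
  )
}
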