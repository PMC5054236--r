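#' Construct a supervised topic model
#'
#' The model has `K` topics `beta` (each a distribution over the `V`-word
#' vocabulary), a symmetric Dirichlet prior `alpha` on per-document topic
#' proportions, and per-class response coefficient vectors `eta` (C x K).
#' A document's class label is drawn from a softmax over `eta_c' zbar`,
#' where `zbar` is the document's empirical topic frequency vector (the
#' average of its per-word topic assignments). The first class is the
#' reference: its coefficient row is fixed at zero for identifiability (for
#' the binary tasks, class 1 = negative, class 2 = positive).
#'
#' @param beta K x V matrix; rows must be strictly positive and sum to 1.
#' @param eta C x K matrix of response coefficients; row 1 must be zero.
#' @param alpha Symmetric Dirichlet concentration (study default 1).
#' @param vocab Optional character vector of length V naming the words.
#' @return An `slda_model`.
#' @export
slda_model <- function(beta, eta, alpha = 1, vocab = NULL) {
  beta <- as.matrix(beta)
  eta <- as.matrix(eta)
  K <- nrow(beta)
  if (ncol(eta) != K) stop("eta must have K columns")
  if (nrow(eta) < 2L) stop("at least two classes are required")
  if (any(beta <= 0)) stop("beta entries must be strictly positive")
  if (any(abs(rowSums(beta) - 1) > 1e-8)) stop("beta rows must sum to 1")
  if (any(eta[1L, ] != 0)) stop("the reference class row of eta must be zero")
  if (alpha <= 0) stop("alpha must be positive")
  if (!is.null(vocab) && length(vocab) != ncol(beta)) {
    stop("vocab length must equal ncol(beta)")
  }
  structure(list(K = K, C = nrow(eta), V = ncol(beta), alpha = alpha,
                 beta = beta, eta = eta, vocab = vocab),
            class = "slda_model")
}

#' @export
print.slda_model <- function(x, ...) {
  cat(sprintf("<slda_model> K = %d topics, C = %d classes, V = %d words, alpha = %g\n",
              x$K, x$C, x$V, x$alpha))
  invisible(x)
}

## token-id documents -> per-document unique (0-based ids, counts)
compress_docs <- function(docs, V) {
  ids <- vector("list", length(docs))
  cts <- vector("list", length(docs))
  for (d in seq_along(docs)) {
    w <- as.integer(docs[[d]])
    if (length(w) == 0L) stop("document ", d, " is empty")
    if (any(w < 1L | w > V)) stop("document ", d, " has token ids outside 1..V")
    tab <- tabulate_sparse(w)
    ids[[d]] <- tab$j - 1L
    cts[[d]] <- as.numeric(tab$x)
  }
  list(ids = ids, cts = cts)
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Sample documents and labels from the generative story
#'
#' For each document: topic proportions `theta ~ Dirichlet(alpha)`; each
#' word position draws a topic `z_n ~ Multinomial(theta)` and then a word
#' `w_n ~ beta[z_n]`; the class label is drawn from
#' `softmax(eta_c' zbar)` where `zbar` holds the document's empirical topic
#' frequencies.
#'
#' @param model An [slda_model()].
#' @param n_docs Number of documents.
#' @param doc_length Integer word count per document (scalar or vector of
#'   length `n_docs`); all lengths must be >= 1.
#' @param seed Integer seed.
#' @return List with `docs` (token-id vectors, 1-based), `labels` (class
#'   ids, 1 = reference), `theta` (n x K), `z` (per-doc topic assignment
#'   vectors), `zbar` (n x K empirical topic frequencies).
#' @export
sample_slda_corpus <- function(model, n_docs, doc_length, seed = 1L) {
  stopifnot(inherits(model, "slda_model"))
  len <- rep_len(as.integer(doc_length), n_docs)
  if (any(len < 1L)) stop("doc lengths must be >= 1")
  K <- model$K
  with_seed(seed, {
    docs <- vector("list", n_docs)
    zs <- vector("list", n_docs)
    labels <- integer(n_docs)
    theta <- matrix(NA_real_, n_docs, K)
    zbar <- matrix(NA_real_, n_docs, K)
    for (d in seq_len(n_docs)) {
      g <- rgamma(K, shape = model$alpha)
      th <- g / sum(g)
      z <- sample.int(K, len[d], replace = TRUE, prob = th)
      w <- vapply(z, function(k) {
        sample.int(model$V, 1L, prob = model$beta[k, ])
      }, integer(1))
      zb <- tabulate(z, nbins = K) / len[d]
      pr <- softmax(as.numeric(model$eta %*% zb))
      labels[d] <- sample.int(model$C, 1L, prob = pr)
      docs[[d]] <- w
      zs[[d]] <- z
      theta[d, ] <- th
      zbar[d, ] <- zb
    }
    list(docs = docs, labels = labels, theta = theta, z = zs, zbar = zbar)
  })
}

## seeded initialization of beta from randomly selected documents (the
## classic "seeded" LDA init: each topic smooths the word counts of a few
## random documents)
init_beta <- function(ids, cts, K, V, seed) {
  with_seed(seed, {
    beta <- matrix(0, K, V)
    n_seed_docs <- min(5L, length(ids))
    for (k in seq_len(K)) {
      pick <- sample.int(length(ids), n_seed_docs)
      for (d in pick) beta[k, ids[[d]] + 1L] <- beta[k, ids[[d]] + 1L] + cts[[d]]
      beta[k, ] <- beta[k, ] + runif(V, 0.5, 1.5) # break symmetry
    }
    beta / rowSums(beta)
  })
}

#' Fit the supervised topic model by variational EM
#'
#' E-step: per-document coordinate ascent on the variational Dirichlet and
#' the per-word topic posteriors `phi`, where each `phi` update multiplies
#' the usual topic-word likelihood term by the label term induced by the
#' softmax response bound. M-step: topic-word distributions proportional to
#' expected counts (smoothed by `beta_smooth`), and response coefficients
#' `eta` updated by BFGS maximization of the bounded ELBO's response term
#' (kept only if it improves it). The per-iteration ELBO (the bound, after
#' each E-step) is recorded and must be non-decreasing up to floating-point
#' and bound slack.
#'
#' @param docs List of token-id vectors (1-based, dense in `1..V`); every
#'   document must be non-empty.
#' @param labels Integer class ids in `1..C` (1 = reference/negative), or
#'   `NULL` to fit unsupervised (plain variational LDA).
#' @param K Number of topics (study default 20).
#' @param alpha Symmetric Dirichlet concentration (study default 1).
#' @param V Vocabulary size; defaults to the largest token id seen.
#' @param vocab Optional word names of length `V`.
#' @param max_iter,tol EM iteration cap and relative-ELBO tolerance.
#' @param e_max_iter,e_tol Per-document E-step caps.
#' @param seed Integer seed (initialization).
#' @param n_restarts Number of seeded restarts; the fit with the best final
#'   ELBO is kept.
#' @param beta_smooth Additive mass renormalized into `beta` at each M-step
#'   so no word has zero probability at prediction time.
#' @return An `slda_fit`: `model` ([slda_model()]), `doc_states` (list with
#'   `gamma`, `zbar` matrices and per-doc `phi`), and `trace` (`elbo` per EM
#'   iteration, `iterations`, `converged`, `monotone`, `seed`).
#' @export
fit_slda <- function(docs, labels = NULL, K = 20L, alpha = 1,
                     V = NULL, vocab = NULL, max_iter = 200L, tol = 1e-5,
                     e_max_iter = 100L, e_tol = 1e-6, seed = 1L,
                     n_restarts = 1L, beta_smooth = 1e-8) {
  if (is.null(V)) V <- max(vapply(docs, max, numeric(1)))
  V <- as.integer(V)
  comp <- compress_docs(docs, V)
  D <- length(docs)
  supervised <- !is.null(labels)
  if (supervised) {
    labels <- as.integer(labels)
    if (length(labels) != D) stop("labels must match the number of documents")
    C <- max(labels)
    if (length(unique(labels)) < 2L) stop("labels must cover >= 2 classes")
    labels0 <- labels - 1L
  } else {
    C <- 2L
    labels0 <- rep.int(-1L, D)
  }
  doc_len <- vapply(comp$cts, sum, numeric(1))

  run_once <- function(run_seed) {
    beta <- init_beta(comp$ids, comp$cts, K, V, run_seed)
    eta <- matrix(0, C, K)
    elbo_trace <- numeric(0)
    converged <- FALSE
    est <- NULL
    for (it in seq_len(max_iter)) {
      est <- slda_estep_cpp(comp$ids, comp$cts, log(beta), eta, labels0,
                            alpha, as.integer(e_max_iter), e_tol, TRUE)
      if (!isTRUE(est$ok) || !is.finite(est$elbo)) {
        stop("non-finite ELBO at EM iteration ", it)
      }
      elbo_trace <- c(elbo_trace, est$elbo)
      if (it > 1L) {
        prev <- elbo_trace[it - 1L]
        if (abs(est$elbo - prev) < tol * (abs(prev) + 1e-10)) {
          converged <- TRUE
          break
        }
      }
      ## M-step: beta from expected topic-word counts, smoothed
      beta_new <- est$ss + beta_smooth
      beta <- beta_new / rowSums(beta_new)
      if (supervised) {
        eta <- update_eta(est$phi, comp$cts, labels0, eta, doc_len)
      }
    }
    list(beta = beta, eta = eta, est = est, elbo = elbo_trace,
         converged = converged, seed = run_seed)
  }

  runs <- lapply(seq_len(n_restarts), function(r) run_once(child_seed(seed, r)))
  best <- runs[[which.max(vapply(runs, function(r) max(r$elbo), numeric(1)))]]

  model <- slda_model(best$beta, best$eta, alpha = alpha, vocab = vocab)
  elbo <- best$elbo
  monotone <- length(elbo) < 2L ||
    all(diff(elbo) >= -1e-6 * abs(elbo[-length(elbo)]))
  structure(list(
    model = model,
    doc_states = list(gamma = best$est$gamma, zbar = best$est$zbar,
                      phi = best$est$phi),
    trace = list(elbo = elbo, iterations = length(elbo),
                 converged = best$converged, monotone = monotone,
                 seed = best$seed),
    labels = labels
  ), class = "slda_fit")
}

#' @export
print.slda_fit <- function(x, ...) {
  cat(sprintf("<slda_fit> K = %d, %d documents, %d EM iterations (%s), final ELBO %.2f\n",
              x$model$K, nrow(x$doc_states$zbar), x$trace$iterations,
              if (x$trace$converged) "converged" else "iteration cap",
              x$trace$elbo[length(x$trace$elbo)]))
  invisible(x)
}

## BFGS step on the free rows of eta (reference row pinned at 0); the update
## is kept only when it does not decrease the response objective
update_eta <- function(phis, cts, labels0, eta, doc_len, maxit = 12L) {
  C <- nrow(eta)
  K <- ncol(eta)
  pack <- function(e) as.numeric(e[-1L, , drop = FALSE])
  unpack <- function(par) {
    e <- matrix(0, C, K)
    e[-1L, ] <- matrix(par, C - 1L, K)
    e
  }
  ## optim evaluates fn and gr at the same point in lockstep; one C++ call
  ## serves both
  cache <- new.env(parent = emptyenv())
  eval_at <- function(par) {
    if (!identical(par, cache$par)) {
      o <- slda_eta_obj_cpp(phis, cts, labels0, unpack(par), doc_len)
      cache$par <- par
      cache$val <- -o$value
      cache$grad <- -as.numeric(o$grad[-1L, , drop = FALSE])
    }
    invisible(NULL)
  }
  fn <- function(par) { eval_at(par); cache$val }
  gr <- function(par) { eval_at(par); cache$grad }
  v0 <- fn(pack(eta))
  opt <- optim(pack(eta), fn, gr, method = "BFGS",
               control = list(maxit = maxit))
  if (opt$value <= v0) unpack(opt$par) else eta
}

#' Posterior topic state of a single document
#'
#' Runs the variational E-step to convergence without any label term (the
#' unsupervised posterior used for prediction on unlabeled documents).
#'
#' @param model An [slda_model()].
#' @param doc Non-empty vector of token ids in `1..V`.
#' @param e_max_iter,e_tol E-step caps.
#' @return List with `gamma` (variational Dirichlet), `phi` (per-word-type
#'   topic posteriors), `zbar` (empirical topic frequencies under `phi`).
#' @export
infer_document <- function(model, doc, e_max_iter = 100L, e_tol = 1e-6) {
  stopifnot(inherits(model, "slda_model"))
  comp <- compress_docs(list(doc), model$V)
  est <- slda_estep_cpp(comp$ids, comp$cts, log(model$beta), model$eta,
                        -1L, model$alpha, as.integer(e_max_iter), e_tol, TRUE)
  list(gamma = est$gamma[1L, ], phi = est$phi[[1L]], zbar = est$zbar[1L, ])
}

#' Predict class probabilities for a document
#'
#' Softmax over `eta_c' zbar` with `zbar` from [infer_document()].
#'
#' @inheritParams infer_document
#' @return Numeric vector of per-class probabilities (sums to 1).
#' @export
predict_label <- function(model, doc, e_max_iter = 100L, e_tol = 1e-6) {
  state <- infer_document(model, doc, e_max_iter, e_tol)
  softmax(as.numeric(model$eta %*% state$zbar))
}

#' Serialize / restore a supervised topic model
#'
#' Writes `<path>.json` (K, C, V, alpha, eta, vocabulary) and
#' `<path>.beta.tsv` (dense K x V topic-word matrix, tab-separated).
#' `read_slda_model()` restores an [slda_model()] equal to the original up
#' to text-serialization precision (17 significant digits).
#'
#' @param model An [slda_model()].
#' @param path Output path stem (without extension).
#' @return The JSON path (write) or an `slda_model` (read), invisibly for
#'   the writer.
#' @export
write_slda_model <- function(model, path) {
  stopifnot(inherits(model, "slda_model"))
  jsonlite::write_json(
    list(K = model$K, C = model$C, V = model$V, alpha = model$alpha,
         eta = model$eta, vocab = model$vocab),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.table(format(model$beta, digits = 17, trim = TRUE),
                     paste0(path, ".beta.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(paste0(path, ".json"))
}

#' @rdname write_slda_model
#' @export
read_slda_model <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  beta <- as.matrix(utils::read.table(paste0(path, ".beta.tsv"), sep = "\t"))
  dimnames(beta) <- NULL
  eta <- matrix(unlist(hdr$eta), nrow = hdr$C)
  beta <- beta / rowSums(beta) # renormalize serialization rounding
  slda_model(beta, eta, alpha = hdr$alpha,
             vocab = if (is.null(hdr$vocab)) NULL else unlist(hdr$vocab))
}

#' Per-topic report: coefficient, top words, prevalence
#'
#' Topics are sorted by their response coefficient for the positive class
#' (descending; the reference class is pinned at zero, so this is the
#' log-odds push of the topic). The report carries each topic's `top_m`
#' most probable words (ties broken lexicographically) and its prevalence,
#' the mean of `zbar` over documents.
#'
#' @param fit An `slda_fit` (or pass `model` and `doc_states` explicitly).
#' @param top_m Number of words to report per topic (study default 10).
#' @param positive_class Class index whose coefficient row is reported
#'   (default: the last class; class 1 is the reference).
#' @return A tibble (topic, coefficient, prevalence, words).
#' @export
topic_report <- function(fit, top_m = 10L, positive_class = NULL) {
  model <- fit$model
  zbar <- fit$doc_states$zbar
  if (is.null(positive_class)) positive_class <- model$C
  coefs <- model$eta[positive_class, ]
  prevalence <- colMeans(zbar)
  words <- model$vocab %||% paste0("w", seq_len(model$V))
  top_words <- vapply(seq_len(model$K), function(k) {
    ord <- order(-model$beta[k, ], words, method = "radix")
    paste(words[ord[seq_len(min(top_m, model$V))]], collapse = " ")
  }, character(1))
  out <- tibble::tibble(topic = seq_len(model$K), coefficient = coefs,
                        prevalence = prevalence, words = top_words)
  out[order(-out$coefficient, out$topic), ]
}
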