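# Every fit in this file also asserts ELBO monotonicity via its trace; the
# acceptance suite repeats the check on the recovery fixture.

expect_monotone_elbo <- function(fit) {
  el <- fit$trace$elbo
  if (length(el) >= 2) {
    expect_true(all(diff(el) >= -1e-6 * abs(el[-length(el)])),
                label = "ELBO non-decreasing per EM iteration")
  }
  expect_true(fit$trace$monotone)
}

small_model <- function() {
  beta <- rbind(c(0.7, 0.1, 0.1, 0.1),
                c(0.1, 0.1, 0.1, 0.7))
  eta <- rbind(c(0, 0), c(2, -2))
  slda_model(beta, eta, alpha = 1)
}

test_that("model constructor enforces simplex and identifiability invariants", {
  expect_error(slda_model(rbind(c(0.5, 0.4)), rbind(0, 1)), "sum to 1")
  expect_error(slda_model(rbind(c(0.5, 0.5, 0), c(0.2, 0.3, 0.5)),
                          rbind(c(0, 0), c(1, 1))), "strictly positive")
  expect_error(slda_model(rbind(c(0.5, 0.5)), rbind(1, 0)), "reference")
  m <- small_model()
  expect_equal(rowSums(m$beta), c(1, 1))
})

test_that("K = 1 sampling forces a single topic and the word marginal is beta", {
  m <- slda_model(matrix(c(0.5, 0.3, 0.2), 1, 3), rbind(0, 0.7), alpha = 1)
  sim <- sample_slda_corpus(m, 300, 40, seed = 3)
  expect_true(all(unlist(sim$z) == 1))
  expect_true(all(sim$theta == 1))
  freq <- tabulate(unlist(sim$docs), nbins = 3) / (300 * 40)
  se <- sqrt(0.5 * 0.5 / (300 * 40))
  expect_true(all(abs(freq - m$beta[1, ]) < 4 * se + 0.01))
})

test_that("zero response coefficients give uniform labels; K = 2 word marginal matches the mixture", {
  m <- slda_model(rbind(c(0.8, 0.1, 0.05, 0.05), c(0.05, 0.05, 0.1, 0.8)),
                  rbind(c(0, 0), c(0, 0)), alpha = 1)
  sim <- sample_slda_corpus(m, 2000, 30, seed = 4)
  p_pos <- mean(sim$labels == 2)
  expect_lt(abs(p_pos - 0.5), 3 * sqrt(0.25 / 2000))
  ## with alpha symmetric, E[theta] = 1/2 each: marginal = mixture of rows
  freq <- tabulate(unlist(sim$docs), nbins = 4) / (2000 * 30)
  mix <- colMeans(m$beta)
  expect_true(all(abs(freq - mix) < 3 * sqrt(mix * (1 - mix) / (2000 * 30)) + 0.005))
})

test_that("labels respond to eta through the empirical topic frequencies", {
  m <- small_model() # eta_pos = (2, -2)
  sim <- sample_slda_corpus(m, 1500, 40, seed = 5)
  hi <- sim$zbar[, 1] > 0.7 # documents dominated by topic 1
  lo <- sim$zbar[, 1] < 0.3
  expect_gt(mean(sim$labels[hi] == 2), mean(sim$labels[lo] == 2))
})

test_that("sampling is seed-reproducible", {
  m <- small_model()
  s1 <- sample_slda_corpus(m, 20, 15, seed = 6)
  s2 <- sample_slda_corpus(m, 20, 15, seed = 6)
  expect_identical(s1$docs, s2$docs)
  expect_identical(s1$labels, s2$labels)
})

test_that("K = 1 fits recover the smoothed empirical word frequencies", {
  set.seed(7)
  docs <- lapply(1:40, function(i) sample.int(6, 25, replace = TRUE,
                                              prob = c(4, 3, 2, 1, 1, 1)))
  labels <- rep(c(1L, 2L), 20)
  fit <- fit_slda(docs, labels, K = 1, alpha = 1, V = 6, seed = 2,
                  max_iter = 30)
  emp <- tabulate(unlist(docs), nbins = 6) / length(unlist(docs))
  expect_equal(as.numeric(fit$model$beta), emp, tolerance = 1e-6)
  expect_monotone_elbo(fit)
  ## the unsupervised path agrees exactly in the K = 1 degenerate case
  fit_u <- fit_slda(docs, labels = NULL, K = 1, alpha = 1, V = 6, seed = 2,
                    max_iter = 30)
  expect_equal(fit$model$beta, fit_u$model$beta, tolerance = 1e-10)
})

test_that("fitting is deterministic given data and seed", {
  sim <- make_slda_corpus(slda_sim_spec(K = 3, V = 30, n_docs = 60,
                                        doc_length = 20,
                                        words_per_topic = 10,
                                        eta_pos = c(2, 0, 0), seed = 8))
  f1 <- fit_slda(sim$docs, sim$labels, K = 3, V = 30, seed = 5, max_iter = 15)
  f2 <- fit_slda(sim$docs, sim$labels, K = 3, V = 30, seed = 5, max_iter = 15)
  expect_identical(f1$trace$elbo, f2$trace$elbo)
  expect_identical(f1$model$beta, f2$model$beta)
  expect_identical(f1$model$eta, f2$model$eta)
  expect_monotone_elbo(f1)
})

test_that("simplex invariants hold for fitted state and errors are raised early", {
  sim <- make_slda_corpus(slda_sim_spec(K = 3, V = 30, n_docs = 40,
                                        doc_length = 15,
                                        words_per_topic = 10,
                                        eta_pos = c(1, 0, 0), seed = 9))
  fit <- fit_slda(sim$docs, sim$labels, K = 3, V = 30, seed = 1, max_iter = 10)
  expect_equal(rowSums(fit$model$beta), rep(1, 3), tolerance = 1e-8)
  expect_equal(rowSums(fit$doc_states$zbar), rep(1, 40), tolerance = 1e-8)
  expect_equal(fit$model$eta[1, ], c(0, 0, 0))
  for (d in c(1, 20)) {
    expect_equal(rowSums(fit$doc_states$phi[[d]]),
                 rep(1, nrow(fit$doc_states$phi[[d]])), tolerance = 1e-8)
  }
  expect_error(fit_slda(list(integer(0), c(1L, 2L)), c(1L, 2L), K = 2, V = 5),
               "empty")
  expect_error(fit_slda(list(c(1L, 9L)), c(1L), K = 2, V = 5), "outside")
})

test_that("document inference concentrates on the only generating topic", {
  m <- slda_model(rbind(c(0.48, 0.48, 0.02, 0.02) / 1,
                        c(0.02, 0.02, 0.48, 0.48)),
                  rbind(c(0, 0), c(1, -1)), alpha = 1)
  state <- infer_document(m, rep(c(3L, 4L), 15))
  expect_gt(state$zbar[2], 0.9)
  expect_equal(sum(state$zbar), 1, tolerance = 1e-8)
  s2 <- infer_document(m, rep(c(3L, 4L), 15))
  expect_identical(state, s2) # deterministic
  expect_error(infer_document(m, c(1L, 7L)), "outside")
})

test_that("one-word documents track the exact prior-times-likelihood posterior", {
  ## For a one-word document with a symmetric prior, the exact posterior
  ## over its topic is proportional to beta[, w]. Mean-field inference
  ## slightly sharpens this (the digamma tilt of the variational Dirichlet),
  ## so the check allows that known bias while pinning order and magnitude.
  m <- slda_model(rbind(c(0.7, 0.2, 0.1), c(0.2, 0.1, 0.7)),
                  rbind(c(0, 0), c(0.5, -0.5)), alpha = 1)
  state <- infer_document(m, 1L, e_max_iter = 500, e_tol = 1e-12)
  exact <- m$beta[, 1] / sum(m$beta[, 1])
  expect_equal(order(state$zbar), order(exact))
  expect_lt(max(abs(state$zbar - exact)), 0.15)
  expect_gte(state$zbar[1], exact[1]) # sharpening goes toward the mode
})

test_that("label prediction is the softmax of eta times zbar", {
  m0 <- slda_model(rbind(c(0.5, 0.5), c(0.5, 0.5)),
                   rbind(c(0, 0), c(0, 0)), alpha = 1)
  p <- predict_label(m0, c(1L, 2L, 1L))
  expect_identical(p, c(0.5, 0.5)) # all-zero eta: exactly 1/C
  m <- small_model()
  p2 <- predict_label(m, rep(1L, 20)) # words loading on topic 1, eta_2,1 = 2
  expect_gt(p2[2], 0.5)
  expect_equal(sum(p2), 1, tolerance = 1e-12)
  ## hand-computed softmax from a known zbar
  state <- infer_document(m, rep(1L, 20))
  hand <- exp(m$eta %*% state$zbar)
  hand <- as.numeric(hand / sum(hand))
  expect_equal(p2, hand, tolerance = 1e-12)
})

test_that("topic report sorts by coefficient with hand-set models", {
  beta <- rbind(c(0.6, 0.2, 0.1, 0.1),
                c(0.1, 0.1, 0.2, 0.6),
                c(0.25, 0.25, 0.25, 0.25))
  eta <- rbind(c(0, 0, 0), c(-1, 3, 0))
  fit <- structure(list(
    model = slda_model(beta, eta, alpha = 1,
                       vocab = c("apple", "pear", "plum", "fig")),
    doc_states = list(zbar = matrix(1 / 3, 5, 3))
  ), class = "slda_fit")
  rep1 <- topic_report(fit, top_m = 2)
  expect_equal(rep1$topic, c(2L, 3L, 1L)) # coefficients 3, 0, -1
  expect_equal(rep1$words[rep1$topic == 1], "apple pear")
  expect_equal(rep1$words[rep1$topic == 3], "apple fig") # tie -> lexicographic
  expect_equal(rep1$prevalence, rep(1 / 3, 3), tolerance = 1e-12)
  ## all-zero coefficients fall back to topic order
  fit$model$eta <- rbind(c(0, 0, 0), c(0, 0, 0))
  rep0 <- topic_report(fit)
  expect_equal(rep0$topic, 1:3)
})

test_that("restarts keep the best ELBO", {
  sim <- make_slda_corpus(slda_sim_spec(K = 2, V = 20, n_docs = 30,
                                        doc_length = 12, words_per_topic = 8,
                                        eta_pos = c(1, 0), seed = 10))
  f1 <- fit_slda(sim$docs, sim$labels, K = 2, V = 20, seed = 3,
                 max_iter = 10, n_restarts = 3)
  f2 <- fit_slda(sim$docs, sim$labels, K = 2, V = 20, seed = 3,
                 max_iter = 10, n_restarts = 1)
  expect_gte(max(f1$trace$elbo) + 1e-9, max(f2$trace$elbo))
})

test_that("model serialization round-trips within text precision", {
  m <- slda_model(rbind(c(0.6, 0.3, 0.1), c(0.2, 0.2, 0.6)),
                  rbind(c(0, 0), c(1.5, -0.25)), alpha = 0.7,
                  vocab = c("alpha", "beta", "gamma"))
  stem <- tempfile("slda")
  write_slda_model(m, stem)
  back <- read_slda_model(stem)
  expect_equal(back$beta, m$beta, tolerance = 1e-12)
  expect_equal(back$eta, m$eta)
  expect_equal(back$alpha, m$alpha)
  expect_identical(back$vocab, m$vocab)
})
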