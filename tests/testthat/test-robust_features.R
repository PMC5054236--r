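test_that("degenerate resampling (identical rows per class) gives zero-width CIs", {
  ## balanced data whose bootstrap resamples always contain both identical
  ## row types, so every replicate fit is the same
  X <- rbind(matrix(rep(c(1, 0), each = 12), 12, 2),
             matrix(rep(c(0, 1), each = 12), 12, 2))
  y <- rep(c(1, 0), each = 12)
  bs <- bootstrap_coefficients(X, y, lambda = 1, B = 30, seed = 5,
                               stratified = TRUE)
  expect_lt(max(bs$summary$sd), 1e-6)
  expect_lt(max(bs$summary$ci_upper - bs$summary$ci_lower), 1e-5)
})

test_that("CI symmetry and the 1.96 normal width hold for every feature", {
  sim <- simulate_logistic_data(n = 120, beta = c(1, 0, -0.5), seed = 31)
  bs <- bootstrap_coefficients(sim$X, sim$y, lambda = 5, B = 60, seed = 8)
  s <- bs$summary
  expect_equal(s$ci_upper - s$mean, s$mean - s$ci_lower, tolerance = 1e-12)
  expect_equal(s$ci_upper, s$mean + 1.96 * s$sd, tolerance = 1e-12)
  expect_true(all(s$ci_lower <= s$mean & s$mean <= s$ci_upper))
})

test_that("bootstrap summaries are seed-reproducible and count redraws", {
  sim <- simulate_logistic_data(n = 60, beta = c(1, -1), seed = 32)
  b1 <- bootstrap_coefficients(sim$X, sim$y, lambda = 1, B = 25, seed = 4)
  b2 <- bootstrap_coefficients(sim$X, sim$y, lambda = 1, B = 25, seed = 4)
  expect_identical(b1$summary, b2$summary)
  expect_gte(b1$n_redraws, 0L)
  expect_error(bootstrap_coefficients(sim$X, sim$y, 1, B = 1), "B must be")
})

test_that("replicate SD stabilizes as B grows (no systematic widening)", {
  sim <- simulate_logistic_data(n = 150, beta = c(1.5, 0, 0), seed = 33)
  sds <- vapply(c(50, 200), function(B) {
    bs <- bootstrap_coefficients(sim$X, sim$y, lambda = 10, B = B, seed = 7)
    bs$summary$sd[1]
  }, numeric(1))
  ## the B=200 estimate must be within 50% of the B=50 estimate: SDs
  ## converge, CI width is not an increasing function of B
  expect_lt(abs(sds[2] - sds[1]) / sds[1], 0.5)
})

test_that("ranking sorts by CI bound with mean/lexicographic tie-breaks", {
  s <- tibble::tibble(
    feature = c("bbb", "aaa", "ccc", "ddd", "eee"),
    mean = c(1, 1, 2, -2, -1),
    sd = c(0.1, 0.1, 0.5, 0.2, 0.1)
  )
  s$ci_lower <- s$mean - 1.96 * s$sd
  s$ci_upper <- s$mean + 1.96 * s$sd
  fake <- structure(list(summary = s, B = 10L, lambda_policy = "fixed",
                         lambda = 1, seed = 1L, n_redraws = 0L,
                         samples = NULL),
                    class = "bootstrap_summary")
  pos <- rank_features(fake, "positive", 5)
  ## hand sort: ccc (lower 1.02), then the aaa/bbb tie (identical mean and
  ## CI -> lexicographic), then eee, ddd
  expect_equal(pos$feature, c("ccc", "aaa", "bbb", "eee", "ddd"))
  neg <- rank_features(fake, "negative", 2)
  ## ascending upper bound: ddd (-1.608), eee (-0.804)
  expect_equal(neg$feature, c("ddd", "eee"))
  expect_message(rank_features(fake, "positive", 10), "returning all")
})

test_that("a planted strong positive feature tops the CI-lower-bound ranking", {
  sim <- simulate_logistic_data(n = 300, beta = c(2.5, 0, 0, 0, 0, 0),
                                seed = 34)
  bs <- bootstrap_coefficients(sim$X, sim$y, lambda = 10, B = 80, seed = 9)
  pos <- rank_features(bs, "positive", 6)
  expect_equal(pos$feature[1], "f1")
  expect_gt(bs$summary$ci_lower[1], max(bs$summary$ci_lower[-1]))
})

test_that("coefficient densities integrate to one and track the samples", {
  sim <- simulate_logistic_data(n = 100, beta = c(1, 0), seed = 35)
  bs <- bootstrap_coefficients(sim$X, sim$y, lambda = 5, B = 100, seed = 10,
                               retain = c("f1", "f2"))
  d <- coefficient_density(bs, "f1")
  area <- sum(diff(d$x) * (head(d$y, -1) + d$y[-1]) / 2)
  expect_equal(area, 1, tolerance = 1e-3)
  expect_lt(abs(d$x[which.max(d$y)] - mean(bs$samples[, "f1"])), 0.2)
  expect_error(coefficient_density(bs, "nope"), "not retained")
})

test_that("KDE recovers the mode of normal samples and both modes of a bimodal set", {
  fake_summary <- function(samples) {
    structure(list(
      summary = tibble::tibble(feature = "f", mean = mean(samples),
                               sd = sd(samples),
                               ci_lower = mean(samples) - 1.96 * sd(samples),
                               ci_upper = mean(samples) + 1.96 * sd(samples)),
      B = length(samples), lambda_policy = "fixed", lambda = 1, seed = 1L,
      n_redraws = 0L,
      samples = matrix(samples, ncol = 1, dimnames = list(NULL, "f"))
    ), class = "bootstrap_summary")
  }
  set.seed(36)
  ## the KDE mode of 1000 standard-normal draws sits near 0; the 0.15 bound
  ## is a sampling-error allowance, checked on the median of repeated draws
  modes <- replicate(5, {
    d <- coefficient_density(fake_summary(rnorm(1000)), "f")
    d$x[which.max(d$y)]
  })
  expect_lt(median(abs(modes)), 0.15)
  bimodal <- c(rnorm(500, -3, 0.3), rnorm(500, 3, 0.3))
  d2 <- coefficient_density(fake_summary(bimodal), "f")
  ## local maxima of the curve
  y <- d2$y
  peaks <- which(diff(sign(diff(y))) == -2) + 1
  modes <- d2$x[peaks[y[peaks] > max(y) / 4]]
  expect_true(any(modes < -2) && any(modes > 2))
})
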