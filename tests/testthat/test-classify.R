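test_that("intercept-only deviance on balanced labels is 2n log 2", {
  d <- data.frame(y = rep(0:1, each = 12))
  f <- fit_logistic(d, "y")
  expect_equal(f$deviance, 48 * log(2), tolerance = 1e-8)
  expect_equal(f$aic, 48 * log(2) + 2, tolerance = 1e-8)
  expect_false(f$separation)
})

test_that("complete separation is flagged with a near-zero deviance", {
  d <- data.frame(y = rep(0:1, each = 12),
                  x = c(seq(-1, -0.1, length.out = 12),
                        seq(0.1, 1, length.out = 12)))
  f <- fit_logistic(d, "y", "x")
  expect_true(f$separation)
  expect_lt(f$deviance, 1e-4)
  expect_gte(f$aic, 4)
  expect_lte(f$aic, 4.01)
})

test_that("coefficients match an independent Newton solver", {
  set.seed(16)
  d <- data.frame(x = c(rnorm(15, -0.5), rnorm(15, 0.8)))
  d$y <- rep(0:1, each = 15)
  f <- fit_logistic(d, "y", "x")
  # oracle: straight Newton-Raphson on the log-likelihood
  X <- cbind(1, d$x)
  beta <- c(0, 0)
  for (i in 1:50) {
    p <- 1 / (1 + exp(-X %*% beta))
    W <- as.vector(p * (1 - p))
    step <- solve(t(X) %*% (X * W), t(X) %*% (d$y - p))
    beta <- beta + step
    if (max(abs(step)) < 1e-12) break
  }
  expect_equal(unname(f$coefficients), as.vector(beta), tolerance = 1e-6)
})

test_that("input validation rejects degenerate problems", {
  d <- data.frame(y = rep(1, 10), x = rnorm(10))
  expect_error(fit_logistic(d, "y", "x"), class = "twv_bad_response")
  d2 <- data.frame(y = rep(0:1, 5), x = rnorm(10))
  d2$x2 <- 2 * d2$x
  expect_error(fit_logistic(d2, "y", c("x", "x2")), class = "twv_rank_deficient")
})

test_that("best subset picks the single separating predictor (AIC -> 4)", {
  set.seed(17)
  d <- data.frame(y = rep(0:1, each = 12),
                  x1 = rnorm(24), x2 = rnorm(24),
                  sep = c(runif(12, -1, -0.1), runif(12, 0.1, 1)),
                  x4 = rnorm(24), x5 = rnorm(24))
  bs <- best_subset(d, "y", c("x1", "x2", "sep", "x4", "x5"))
  expect_identical(bs$best$subset, "sep")
  expect_equal(round(bs$best$aic), 4)
  expect_true(bs$best$separation)
})

test_that("two jointly separating predictors give the AIC -> 6 limit", {
  set.seed(18)
  x1 <- runif(24, -1, 1)
  x2 <- runif(24, -1, 1)
  margin <- x1 + x2
  keep <- abs(margin) > 0.2
  while (sum(keep) < 24) {
    x1 <- c(x1, runif(24, -1, 1)); x2 <- c(x2, runif(24, -1, 1))
    margin <- x1 + x2; keep <- abs(margin) > 0.2
  }
  x1 <- x1[keep][1:24]; x2 <- x2[keep][1:24]
  d <- data.frame(y = as.integer((x1 + x2) > 0), x1 = x1, x2 = x2)
  # neither coordinate separates alone in this draw
  expect_gt(min(max(x1[d$y == 0]) - min(x1[d$y == 1]),
                max(x2[d$y == 0]) - min(x2[d$y == 1])), 0)
  bs <- best_subset(d, "y", c("x1", "x2"))
  expect_identical(bs$best$subset, c("x1", "x2"))
  expect_equal(round(bs$best$aic), 6)
})

test_that("pure-noise predictors do not beat the intercept by more than chance", {
  set.seed(19)
  d <- data.frame(y = rep(0:1, each = 12),
                  a = rnorm(24), b = rnorm(24), c = rnorm(24))
  bs <- best_subset(d, "y", c("a", "b", "c"))
  null_aic <- bs$models$aic[bs$models$subset == "(intercept)"]
  expect_lte(bs$models$aic[1], null_aic)
  expect_lte(null_aic - bs$models$aic[1], 2.5)
})

test_that("adding a pure-noise predictor raises AIC in expectation", {
  set.seed(20)
  deltas <- replicate(200, {
    d <- data.frame(y = rep(0:1, each = 12), z = rnorm(24))
    fit_logistic(d, "y", "z")$aic - fit_logistic(d, "y")$aic
  })
  expect_gt(mean(deltas), 0)
})

test_that("subset failures are recorded without aborting the sweep", {
  d <- data.frame(y = rep(0:1, each = 6), x = rnorm(12))
  d$x2 <- 2 * d$x                      # collinear with x
  bs <- best_subset(d, "y", c("x", "x2"))
  expect_true(any(!is.na(bs$models$error)))
  expect_true(any(is.na(bs$models$error)))
})
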