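test_that("identical groups give t = 0, p = 1 and evidence for the null", {
  a <- c(1, 2, 3, 4, 5)
  out <- compare_landmark(a, a)
  expect_equal(out$t, 0)
  expect_equal(out$p_welch, 1)
  expect_gt(out$log_bf01, 0)
})

test_that("the JZS Bayes factor matches a direct numerical-integration oracle", {
  set.seed(8)
  a <- rnorm(12)
  b <- rnorm(12, 1.2)
  out <- compare_landmark(a, b)
  # oracle: integrate the JZS marginal likelihood ratio written from scratch
  n1 <- 12; n2 <- 12
  tt <- stats::t.test(a, b, var.equal = FALSE)$statistic
  N <- n1 * n2 / (n1 + n2); nu <- n1 + n2 - 2; r <- sqrt(2) / 2
  num <- stats::integrate(function(g) {
    (1 + N * g)^(-1 / 2) * (1 + tt^2 / ((1 + N * g) * nu))^(-(nu + 1) / 2) *
      (r^2 / 2)^(1 / 2) / sqrt(pi) * g^(-3 / 2) * exp(-r^2 / (2 * g))
  }, 0, Inf, rel.tol = 1e-10)$value
  den <- (1 + tt^2 / nu)^(-(nu + 1) / 2)
  expect_equal(out$log_bf01, as.numeric(-log(num / den)), tolerance = 1e-5)
})

test_that("extreme separation is decisive in every flavour", {
  a <- c(1, 2, 3)
  b <- a + 100 * sd(a)
  out <- compare_landmark(a, b)
  expect_lt(out$p_welch, 0.001)
  expect_lt(out$log_bf01, 0)   # decisive evidence for a difference
  expect_error(compare_landmark(c(1, 1), c(1, 1)),
               class = "twv_degenerate_groups")
})

test_that("Welch statistic matches the closed formula and is affine invariant", {
  a <- c(3.1, 2.7, 4.4, 3.9, 2.2)
  b <- c(5.0, 4.8, 6.1, 5.5)
  out <- compare_landmark(a, b)
  se <- sqrt(var(a) / 5 + var(b) / 4)
  t_hand <- (mean(a) - mean(b)) / se
  df_hand <- se^4 / ((var(a) / 5)^2 / 4 + (var(b) / 4)^2 / 3)
  p_hand <- 2 * stats::pt(-abs(t_hand), df_hand)
  expect_equal(out$t, t_hand, tolerance = 1e-10)
  expect_equal(out$df, df_hand, tolerance = 1e-10)
  expect_equal(out$p_welch, p_hand, tolerance = 1e-10)
  out2 <- compare_landmark(10 * a - 3, 10 * b - 3)
  expect_equal(out2$p_welch, out$p_welch, tolerance = 1e-12)
})

test_that("confidence ellipses are near-circular for isotropic clouds", {
  set.seed(9)
  P <- matrix(rnorm(600, 0, 0.5), 300, 2)
  e <- confidence_ellipse(P)
  expect_lt(e$a / e$b, 1.25)
  expect_error(confidence_ellipse(cbind(1:10, 2 * (1:10))),
               class = "twv_singular_cov")
  expect_error(confidence_ellipse(P[1:2, ]), class = "twv_bad_argument")
})

test_that("the 95% ellipse covers the true mean at the nominal rate", {
  set.seed(10)
  Sigma <- matrix(c(1, 0.6, 0.6, 2), 2, 2)
  L <- chol(Sigma)
  hits <- 0
  R <- 500
  for (r in seq_len(R)) {
    P <- matrix(rnorm(400), 200, 2) %*% L
    e <- confidence_ellipse(P)
    # is the origin inside? rotate into the ellipse frame
    d <- c(-e$center_x, -e$center_y)
    u <- c(cos(e$angle) * d[1] + sin(e$angle) * d[2],
           -sin(e$angle) * d[1] + cos(e$angle) * d[2])
    hits <- hits + ((u[1] / e$a)^2 + (u[2] / e$b)^2 <= 1)
  }
  expect_gte(hits / R, 0.92)
  expect_lte(hits / R, 0.975)
})

test_that("demographic summary reproduces the characteristics table", {
  d <- cohort_demographics(lqts3_table1())
  expect_equal(d$n, 12)
  expect_equal(d$age_mean, 17.2, tolerance = 0.003)
  expect_equal(d$age_sd, 13.3, tolerance = 0.003)
  expect_equal(d$n_male, 7)
  expect_equal(d$n_late_onset, 9)
  expect_equal(d$n_asymmetric, 3)
  expect_equal(d$n_mexiletine_on, 6)
  expect_error(cohort_demographics(data.frame()), class = "twv_bad_argument")
  expect_error(cohort_demographics(data.frame(age = 1)), class = "twv_bad_argument")
})

test_that("per-landmark comparison table covers both axes of each landmark", {
  cfg <- two_group_configs(n_per = 8, sigma = 0.02, seed = 15)
  tab <- compare_landmarks(cfg)
  expect_true(all(table(tab$landmark) == 2))
  expect_true(all(tab$p_welch >= 0 & tab$p_welch <= 1))
})
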