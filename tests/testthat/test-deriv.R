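test_that("smoothing spline reproduces a cubic polynomial in the interior", {
  x <- seq(0, 100, 1)
  y <- 1e-6 * (x - 50)^3 + 0.01 * x
  f <- smooth_spline_fit(y, x, spar = 0)
  interior <- 21:81
  expect_lt(max(abs(f$fitted[interior] - y[interior])), 1e-8)
})

test_that("heavy smoothing approaches the least-squares line", {
  x <- seq(0, 100, 1)
  y <- 1e-6 * (x - 50)^3 + 0.01 * x
  f <- smooth_spline_fit(y, x, spar = 1)
  line <- stats::lm(y ~ x)$fitted.values
  expect_lt(max(abs(f$fitted - line)), 0.02 * diff(range(y)))
})

test_that("GCV-selected smoothing beats the raw signal on a noisy sine", {
  set.seed(10)
  xs <- seq(0, 10, length.out = 500)
  true <- sin(xs)
  noisy <- true + rnorm(500, 0, sd(true) / sqrt(10))   # SNR 10
  f <- smooth_spline_fit(noisy, xs, spar = NULL)
  expect_lt(sqrt(mean((f$fitted - true)^2)), sqrt(mean((noisy - true)^2)))
})

test_that("spline fit validates its arguments", {
  expect_error(smooth_spline_fit(1:5, 1:5), class = "twv_too_few_points")
  expect_error(smooth_spline_fit(rnorm(20), 1:20, spar = 1.5),
               class = "twv_bad_argument")
})

test_that("derivatives of a straight line are constant and curvature-free", {
  tr <- tibble::tibble(time_ms = 0:199, mv = 0.002 * (0:199))
  d <- beat_derivatives(tr)
  interior <- 30:170
  expect_lt(max(abs(d$d1[interior] - 0.002)), 1e-6)
  expect_lt(max(abs(d$d2[interior])), 1e-6)
  expect_lt(max(abs(d$kappa[interior])), 1e-6)
})

test_that("derivative landmarks of a noiseless Gaussian match closed forms", {
  x <- 0:899
  mu <- 420; s <- 50
  tr <- tibble::tibble(time_ms = x, mv = 0.5 * exp(-(x - mu)^2 / (2 * s^2)))
  d <- beat_derivatives(tr)
  # d1 zero crossing at the apex
  win <- which(d$time_ms > mu - s & d$time_ms < mu + s)
  i <- win[which(d$d1[win] >= 0 & d$d1[win + 1] < 0)]
  crossing <- d$time_ms[i] + d$d1[i] / (d$d1[i] - d$d1[i + 1])
  expect_lt(abs(crossing - mu), 1)
  # first local max of d2 at mu - sqrt(3) sigma
  win2 <- which(d$time_ms > 200 & d$time_ms < mu)
  expect_lt(abs(d$time_ms[win2][which.max(d$d2[win2])] - (mu - sqrt(3) * s)), 3)
})

test_that("curvature at a circular apex equals one over the radius", {
  xs <- seq(-80, 80, 1)
  tr <- tibble::tibble(time_ms = xs, mv = sqrt(100^2 - xs^2))
  d <- beat_derivatives(tr)
  k_apex <- d$kappa[d$time_ms == 0]
  expect_lt(abs(k_apex - (-0.01)) / 0.01, 0.05)
})

test_that("curvature identity holds pointwise for any derivative set", {
  b <- simulate_beat(beat_spec(noise_sd = 0.01, seed = 3))
  d <- beat_derivatives(correct_baseline(b$trace))
  expect_lt(max(abs(d$kappa * (1 + d$d1^2)^(3 / 2) - d$d2)), 1e-12)
})

test_that("second derivative and curvature agree on T-window argmax positions", {
  # small-slope beats: landmark positions from d2 and kappa coincide
  for (s in c(40, 60)) {
    b <- simulate_beat(beat_spec(t_sigma_left_ms = s, t_sigma_right_ms = s))
    d <- beat_derivatives(b$trace)
    win <- which(d$time_ms > 210 & d$time_ms < 420 + b$spec$st_shift_ms)
    expect_lte(abs(d$time_ms[win][which.max(d$d2[win])] -
                   d$time_ms[win][which.max(d$kappa[win])]), 2)
  }
})

test_that("spar diagnostics: RMSE shrinks with less smoothing", {
  b <- simulate_beat(beat_spec())
  tab <- spar_diagnostics(b, spar_list = seq(0.2, 0.7, 0.1))
  expect_equal(tab$spar, seq(0.2, 0.7, 0.1))
  expect_true(all(diff(tab$rmse) >= 0))      # sorted by spar: RMSE increases
  wn <- tibble::tibble(time_ms = 0:499, mv = rnorm(500, 0, 0.02))
  tw <- spar_diagnostics(wn, spar_list = c(0.2, 0.7))
  expect_lt(tw$rmse[tw$spar == 0.2], tw$rmse[tw$spar == 0.7])
  expect_equal(nrow(spar_diagnostics(b, spar_list = 0.5)), 1)
  expect_error(spar_diagnostics(b, spar_list = numeric()),
               class = "twv_bad_argument")
})
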