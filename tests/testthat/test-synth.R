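test_that("noiseless beat ground truth matches closed-form Gaussian landmarks", {
  spec <- beat_spec(t_center_ms = 300, t_sigma_left_ms = 50,
                    t_sigma_right_ms = 50, t_amp = 0.5)
  b <- simulate_beat(spec)
  tr <- setNames(b$truth$x_ms, b$truth$landmark)
  expect_equal(tr[["Tp"]], 300)
  expect_equal(b$truth$y_mv[b$truth$landmark == "Tp"], 0.5)
  expect_equal(tr[["FdFmax"]], 300 - 50)
  expect_equal(tr[["FdFmin"]], 300 + 50)
  expect_equal(tr[["SdFmax"]], 300 - sqrt(3) * 50)
  expect_equal(tr[["SdSmax"]], 300 + sqrt(3) * 50)
  expect_equal(tr[["Te"]], 300 + 2 * 50)  # tangent at inflection crosses 0 at mu + 2 sigma
  expect_equal(tr[["TeEye"]], 300 + 50 * sqrt(2 * log(50)))
})

test_that("ST shift translates the analytic T landmarks", {
  b0 <- simulate_beat(beat_spec(st_shift_ms = 0))
  b1 <- simulate_beat(beat_spec(st_shift_ms = 60))
  tlm <- c("SdFmax", "FdFmax", "Tp", "FdFmin", "SdSmax", "Te", "TeEye")
  d <- b1$truth$x_ms[match(tlm, b1$truth$landmark)] -
    b0$truth$x_ms[match(tlm, b0$truth$landmark)]
  expect_equal(d, rep(60, length(tlm)))
})

test_that("clean beat trace is exactly zero at both window endpoints", {
  b <- simulate_beat(beat_spec())
  expect_identical(b$clean$mv[1], 0)
  expect_identical(b$clean$mv[nrow(b$clean)], 0)
})

test_that("beat simulation is a pure function of its seed", {
  s <- beat_spec(noise_sd = 0.01, seed = 7)
  expect_identical(simulate_beat(s)$trace, simulate_beat(s)$trace)
  s2 <- beat_spec(noise_sd = 0.01, seed = 8)
  expect_false(identical(simulate_beat(s)$trace$mv, simulate_beat(s2)$trace$mv))
})

test_that("invalid beat specifications are rejected", {
  expect_error(beat_spec(rr_ms = -5), class = "twv_bad_argument")
  expect_error(beat_spec(rr_ms = 400, t_center_ms = 300, t_sigma_right_ms = 50),
               class = "twv_bad_beat_spec")
  expect_error(beat_spec(t_amp = -0.2), class = "twv_bad_argument")
})

test_that("cohort with zero between-case SD repeats the mean parameters", {
  ch <- simulate_cohort(cohort_spec("g", n_cases = 3, beats_per_case = 2,
                                    means = list(t_amp = 0.45)))
  expect_equal(unique(ch$cases$t_amp), 0.45)
  expect_equal(nrow(ch$beats), 6)
  # identical parameters, different noise seeds only
  expect_equal(ch$cases$st_shift_ms, rep(0, 3))
})

test_that("injected ST shift appears in the cohorts' ground-truth SdFmax gap", {
  st <- small_study(n_cases = 8, beats = 1, seed = 5)
  mean_sdfmax <- function(ch) {
    mean(purrr::map_dbl(ch$beats$beat, function(b) {
      b$truth$x_ms[b$truth$landmark == "SdFmax"]
    }))
  }
  gap <- mean_sdfmax(st$late) - mean_sdfmax(st$normal)
  expect_lt(abs(gap - 60), 10)
})

test_that("cohort regeneration with the same seed is identical", {
  sp <- cohort_spec("g", n_cases = 2, beats_per_case = 2,
                    means = list(noise_sd = 0.01), seed = 33)
  c1 <- simulate_cohort(sp)
  c2 <- simulate_cohort(sp)
  expect_identical(c1$cases, c2$cases)
  expect_identical(c1$beats$beat[[4]]$trace, c2$beats$beat[[4]]$trace)
  expect_error(cohort_spec("g", n_cases = 1), class = "twv_bad_cohort_spec")
})

test_that("configuration sampler is isotropic with the requested SD", {
  ms <- template_shape()
  cs <- simulate_configurations(ms, sigma = 0.01, n = 1000, seed = 4)
  resid_x <- cs$x - rep(ms[, 1], times = 1000)
  resid_y <- cs$y - rep(ms[, 2], times = 1000)
  expect_lt(abs(sd(resid_x) - 0.01) / 0.01, 0.05)
  expect_lt(abs(sd(resid_y) - 0.01) / 0.01, 0.05)
  expect_lt(abs(cor(resid_x, resid_y)), 0.05)
})

test_that("configuration sampler handles edge cases", {
  ms <- template_shape()
  cs0 <- simulate_configurations(ms, sigma = 0, n = 5, seed = 1)
  expect_equal(unique(cs0$x), ms[, 1])
  expect_identical(simulate_configurations(ms, 0.02, 4, seed = 9),
                   simulate_configurations(ms, 0.02, 4, seed = 9))
  expect_error(simulate_configurations(matrix(1, 9, 2), 0.1, 3),
               class = "twv_bad_configs")
})
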