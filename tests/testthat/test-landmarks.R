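test_that("Q and J are found at the QRS baseline intersections", {
  b <- simulate_beat(beat_spec())
  qj <- detect_q_j(b$trace)
  expect_lte(abs(qj$q_ms - b$q_ms), 1)
  expect_lte(abs(qj$j_ms - b$j_ms), 1)
  expect_error(detect_q_j(tibble::tibble(time_ms = 0:99, mv = 0)),
               class = "twv_no_crossing")
  # manual overrides are returned verbatim
  ov <- detect_q_j(b$trace, overrides = list(q_ms = 123, j_ms = 181))
  expect_identical(ov, list(q_ms = 123, j_ms = 181))
})

test_that("detected landmarks match analytic truth on noiseless beats", {
  for (spec in list(beat_spec(),
                    beat_spec(t_sigma_left_ms = 40, t_sigma_right_ms = 60),
                    beat_spec(st_shift_ms = 60, t_amp = 0.4))) {
    b <- simulate_beat(spec)
    lm <- extract_landmarks(b)
    d <- lm$x_ms - b$truth$x_ms[match(lm$landmark, b$truth$landmark)]
    expect_lt(max(abs(d)), 3)
    expect_identical(lm$x_ms[lm$landmark == "Q"], 0)
    expect_identical(lm$y_mv[lm$landmark == "Q"], 0)
    expect_identical(lm$y_mv[lm$landmark == "TeEye"], 0)
  }
})

test_that("an ST shift translates all detected T landmarks equally", {
  lm0 <- extract_landmarks(simulate_beat(beat_spec()))
  lm1 <- extract_landmarks(simulate_beat(beat_spec(st_shift_ms = 60)))
  tlm <- c("SdFmax", "FdFmax", "Tp", "FdFmin", "SdSmax")
  d <- lm1$x_ms[match(tlm, lm1$landmark)] - lm0$x_ms[match(tlm, lm0$landmark)]
  expect_true(all(abs(d - 60) <= 2))
})

test_that("amplitude scaling scales landmark y and leaves x unchanged", {
  b <- simulate_beat(beat_spec())
  lm1 <- extract_landmarks(b)
  scaled <- b$trace
  scaled$mv <- 2 * scaled$mv
  lm2 <- extract_landmarks(scaled, rr_ms = b$rr_ms)
  expect_equal(lm2$y_mv, 2 * lm1$y_mv, tolerance = 1e-6)
  expect_equal(lm2$x_ms, lm1$x_ms, tolerance = 1)
})

test_that("landmark ordering violations are rejected, not reordered", {
  lm <- extract_landmarks(simulate_beat(beat_spec()))
  bad <- lm
  bad$x_ms[bad$landmark == "FdFmax"] <- bad$x_ms[bad$landmark == "Tp"] + 50
  expect_error(twaveshape:::.check_landmark_order(bad),
               class = "twv_landmark_order")
})

test_that("the extraction chain satisfies the ordering invariant across beats", {
  set.seed(14)
  for (i in 1:6) {
    spec <- beat_spec(t_center_ms = runif(1, 260, 340),
                      t_sigma_left_ms = runif(1, 35, 60),
                      t_sigma_right_ms = runif(1, 35, 60),
                      st_shift_ms = sample(c(0, 60), 1),
                      t_amp = runif(1, 0.3, 0.6),
                      noise_sd = 0.005, seed = i)
    lm <- extract_landmarks(correct_baseline(simulate_beat(spec)$trace),
                            rr_ms = spec$rr_ms)
    x <- setNames(lm$x_ms, lm$landmark)
    expect_true(x[["J"]] > 0 && x[["SdFmax"]] >= x[["J"]] + 30)
    expect_true(x[["SdFmax"]] < x[["FdFmax"]] &&
                x[["FdFmax"]] <= x[["Tp"]] &&
                x[["Tp"]] <= x[["FdFmin"]] &&
                x[["FdFmin"]] < x[["SdSmax"]])
  }
})

test_that("tangent-method T-end hits an exactly linear descending limb", {
  # a descending straight limb is its own tangent: Tend at its zero crossing
  x <- 0:899
  y <- numeric(900)
  y[121:200] <- twaveshape:::.qrs_wave(120:199, 120, 1.2)
  ramp_up <- 300:400
  y[ramp_up + 1] <- 0.5 * (ramp_up - 300) / 100
  ramp_dn <- 401:500
  y[ramp_dn + 1] <- 0.5 * (1 - (ramp_dn - 400) / 100)   # hits 0 at x = 500
  tr <- tibble::tibble(time_ms = x, mv = y)
  d <- beat_derivatives(tr)
  i <- which(d$time_ms == 450)
  tend <- d$time_ms[i] - tr$mv[i] / d$d1[i]
  expect_lt(abs(tend - 500), 2)
})

test_that("Bazett correction rescales x only, once", {
  lm <- extract_landmarks(simulate_beat(beat_spec()))
  same <- bazett_correct(lm, rr_ms = 1000)
  expect_equal(same$x_ms, lm$x_ms)
  expect_equal(same$y_mv, lm$y_mv)
  fast <- bazett_correct(lm, rr_ms = 640)
  expect_equal(fast$x_ms, lm$x_ms / 0.8)
  expect_equal(fast$y_mv, lm$y_mv)
  expect_error(bazett_correct(fast), class = "twv_already_bazett")
  expect_error(bazett_correct(lm, rr_ms = -1), class = "twv_bad_argument")
})

test_that("case aggregation averages coordinates and counts exclusions", {
  lm <- extract_landmarks(simulate_beat(beat_spec()))
  agg <- aggregate_case(list(lm, lm, NULL))
  expect_equal(agg$mean$x_ms, lm$x_ms)
  expect_equal(agg$n_beats, 2)
  expect_equal(agg$n_excluded, 1)
  lm2 <- lm
  lm2$x_ms[lm2$landmark == "Tp"] <- lm$x_ms[lm$landmark == "Tp"] + 10
  agg2 <- aggregate_case(list(lm, lm2))
  expect_equal(agg2$mean$x_ms[agg2$mean$landmark == "Tp"],
               lm$x_ms[lm$landmark == "Tp"] + 5)
  expect_error(aggregate_case(list(NULL)), class = "twv_no_valid_beats")
})

test_that("beat averaging concentrates around the analytic truth", {
  spec0 <- beat_spec(noise_sd = 0.01)
  lms <- lapply(1:10, function(i) {
    s <- spec0; s$seed <- 100 + i
    extract_landmarks(correct_baseline(simulate_beat(s)$trace), rr_ms = 900)
  })
  agg <- aggregate_case(lms)
  truth_tp <- simulate_beat(spec0)$truth
  expect_lt(abs(agg$mean$x_ms[agg$mean$landmark == "Tp"] -
                truth_tp$x_ms[truth_tp$landmark == "Tp"]), 3)
})

test_that("group-mean J-to-SdFmax interval recovers an injected ST stretch", {
  st <- small_study(n_cases = 6, beats = 3, seed = 8)
  interval <- function(ch) {
    lm <- cohort_landmarks(ch, bazett = FALSE)
    w <- tidyr::pivot_wider(lm$cases[, c("case_id", "landmark", "x")],
                            names_from = "landmark", values_from = "x")
    mean(w$SdFmax - w$J)
  }
  gap <- interval(st$late) - interval(st$normal)
  expect_lt(abs(gap - 60), 10)
})
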