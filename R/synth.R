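#' Specify a synthetic V5-like ECG beat
#'
#' Builds the parameter set for one simulated beat on a 1 ms grid running
#' from a P-wave onset to the next P-wave onset. The beat is composed of a
#' small raised-cosine P wave, a fixed-width triangular biphasic QRS complex
#' whose first and last baseline intersections define the ground-truth Q and
#' J points, and an asymmetric-Gaussian T-wave with independent left and
#' right half-widths. Delaying the T-wave centre via `st_shift_ms` stretches
#' the ST segment, emulating the late-onset T-wave morphology of sodium
#' channel (LQTS3-like) repolarisation delay; lowering `t_amp` flattens the
#' apex the same way.
#'
#' All times are in milliseconds, amplitudes in millivolts (1.0 = 1 mV,
#' 1.0 = 1 ms). `t_center_ms` is measured from the Q point.
#'
#' @param rr_ms RR interval, i.e. window length (ms).
#' @param qrs_amp R-wave amplitude (mV).
#' @param t_amp T-wave apex amplitude (mV); must be positive (upright
#'   V5-like T-waves only).
#' @param t_center_ms T apex position relative to Q before any ST shift (ms).
#' @param t_sigma_left_ms,t_sigma_right_ms Gaussian half-widths of the
#'   ascending and descending T limbs (ms).
#' @param st_shift_ms Extra delay of the whole T-wave (ms, >= 0).
#' @param noise_sd White-noise standard deviation (mV).
#' @param drift_amp,drift_freq_hz Sinusoidal baseline drift amplitude (mV)
#'   and frequency (Hz).
#' @param powerline_amp Amplitude of a 50 Hz mains component (mV).
#' @param seed Integer seed for the beat's noise realisation.
#' @return An object of class `twv_beat_spec` (a named list).
#' @seealso [simulate_beat()], [cohort_spec()]
#' @export
#' @examples
#' beat_spec(st_shift_ms = 60, t_amp = 0.4)
beat_spec <- function(rr_ms = 900, qrs_amp = 1.2, t_amp = 0.5,
                      t_center_ms = 300, t_sigma_left_ms = 50,
                      t_sigma_right_ms = 50, st_shift_ms = 0,
                      noise_sd = 0, drift_amp = 0, drift_freq_hz = 0.3,
                      powerline_amp = 0, seed = 1L) {
  assert_number(rr_ms, "rr_ms", 0, strict = TRUE)
  assert_number(t_amp, "t_amp", 0, strict = TRUE)
  assert_number(t_sigma_left_ms, "t_sigma_left_ms", 0, strict = TRUE)
  assert_number(t_sigma_right_ms, "t_sigma_right_ms", 0, strict = TRUE)
  assert_number(st_shift_ms, "st_shift_ms", 0)
  assert_number(noise_sd, "noise_sd", 0)
  spec <- structure(
    list(rr_ms = rr_ms, qrs_amp = qrs_amp, t_amp = t_amp,
         t_center_ms = t_center_ms, t_sigma_left_ms = t_sigma_left_ms,
         t_sigma_right_ms = t_sigma_right_ms, st_shift_ms = st_shift_ms,
         noise_sd = noise_sd, drift_amp = drift_amp,
         drift_freq_hz = drift_freq_hz, powerline_amp = powerline_amp,
         seed = as.integer(seed)),
    class = "twv_beat_spec"
  )
  if (rr_ms <= t_center_ms + 4 * t_sigma_right_ms) {
    twv_abort("T-wave overruns the beat window: need rr_ms > t_center_ms + 4 * t_sigma_right_ms",
              "twv_bad_beat_spec")
  }
  # layout constants below: also require the shifted T to fit
  if (.q_offset + t_center_ms + st_shift_ms + 4 * t_sigma_right_ms >= rr_ms) {
    twv_abort("shifted T-wave overruns the beat window", "twv_bad_beat_spec")
  }
  spec
}

# fixed intra-beat layout (ms from P onset)
.q_offset <- 120   # P-onset to Q (PR-like interval)
.qrs_width <- 60   # Q to J
.p_lo <- 20        # raised-cosine P support
.p_hi <- 100
.p_amp <- 0.1

# asymmetric Gaussian T-wave, vectorised over t (absolute ms)
.t_wave <- function(t, mu, sL, sR, amp) {
  s <- ifelse(t < mu, sL, sR)
  amp * exp(-(t - mu)^2 / (2 * s^2))
}

.qrs_wave <- function(t, q0, amp) {
  # piecewise-linear biphasic deflection, exactly 0 at q0 and q0 + 60
  x <- t - q0
  r_up <- x >= 0 & x < 20
  r_dn <- x >= 20 & x < 45
  s_up <- x >= 45 & x <= .qrs_width
  y <- numeric(length(t))
  y[r_up] <- amp * x[r_up] / 20
  y[r_dn] <- amp - (amp + 0.25 * amp) * (x[r_dn] - 20) / 25
  y[s_up] <- -0.25 * amp + 0.25 * amp * (x[s_up] - 45) / 15
  y
}

.p_wave <- function(t) {
  y <- numeric(length(t))
  in_p <- t >= .p_lo & t <= .p_hi
  y[in_p] <- (.p_amp / 2) * (1 - cos(2 * pi * (t[in_p] - .p_lo) / (.p_hi - .p_lo)))
  y
}

# analytic landmark positions of the noiseless beat, x relative to Q
.ground_truth <- function(spec, teeye_frac = 0.02) {
  mu <- spec$t_center_ms + spec$st_shift_ms     # from Q
  sL <- spec$t_sigma_left_ms
  sR <- spec$t_sigma_right_ms
  A <- spec$t_amp
  tibble(
    landmark = twv_landmark_names(),
    x_ms = c(0, .qrs_width,
             mu - sqrt(3) * sL,            # SdFmax: inflection of curvature rise
             mu - sL,                      # FdFmax: steepest ascent
             mu,                           # Tp
             mu + sR,                      # FdFmin: steepest descent
             mu + sqrt(3) * sR,            # SdSmax
             mu + 2 * sR,                  # Te: tangent at FdFmin hits 0 at mu + 2 sigma
             mu + sR * sqrt(2 * log(1 / teeye_frac))),
    y_mv = c(0, 0,
             A * exp(-3 / 2),
             A * exp(-1 / 2),
             A,
             A * exp(-1 / 2),
             A * exp(-3 / 2),
             A * exp(-2),
             0)
  )
}

#' Simulate one ECG beat with analytic landmark ground truth
#'
#' Renders the beat described by a [beat_spec()] on a 1 ms grid of length
#' `rr_ms` (samples at 0, 1, ..., rr_ms - 1 from the P onset). The clean
#' (noise-free) component is anchored so that both window endpoints are
#' exactly zero; white noise, baseline drift and the optional 50 Hz mains
#' component are added afterwards. The returned ground truth gives the
#' analytic positions of all nine landmarks of the noiseless beat, with x
#' measured from Q.
#'
#' @param spec A [beat_spec()].
#' @return An object of class `twv_beat`: a list with elements `trace`
#'   (tibble `time_ms`, `mv`), `clean` (noise-free trace), `truth` (tibble
#'   `landmark`, `x_ms`, `y_mv`), `q_ms` (absolute Q time), `rr_ms`, and
#'   `spec`.
#' @export
#' @examples
#' b <- simulate_beat(beat_spec())
#' b$truth
simulate_beat <- function(spec) {
  if (!inherits(spec, "twv_beat_spec")) spec <- do.call(beat_spec, as.list(spec))
  t <- seq.int(0, spec$rr_ms - 1)
  mu_abs <- .q_offset + spec$t_center_ms + spec$st_shift_ms
  clean <- .p_wave(t) +
    .qrs_wave(t, .q_offset, spec$qrs_amp) +
    .t_wave(t, mu_abs, spec$t_sigma_left_ms, spec$t_sigma_right_ms, spec$t_amp)
  # anchor the clean trace exactly to zero at both endpoints
  n <- length(t)
  clean <- clean - (clean[1] + (clean[n] - clean[1]) * (t - t[1]) / (t[n] - t[1]))
  clean[c(1, n)] <- 0
  y <- clean
  if (spec$noise_sd > 0 || spec$drift_amp > 0 || spec$powerline_amp > 0) {
    old <- .Random.seed_get()
    on.exit(.Random.seed_set(old), add = TRUE)
    set.seed(spec$seed)
    phi <- runif(2, 0, 2 * pi)
    y <- y +
      rnorm(n, 0, spec$noise_sd) +
      spec$drift_amp * sin(2 * pi * spec$drift_freq_hz * t / 1000 + phi[1]) +
      spec$powerline_amp * sin(2 * pi * 50 * t / 1000 + phi[2])
  }
  structure(
    list(
      trace = tibble(time_ms = t, mv = y),
      clean = tibble(time_ms = t, mv = clean),
      truth = .ground_truth(spec),
      q_ms = .q_offset,
      j_ms = .q_offset + .qrs_width,
      r_peak_ms = .q_offset + 20,
      p_onset_ms = 0,
      next_p_onset_ms = spec$rr_ms,
      rr_ms = spec$rr_ms,
      spec = spec
    ),
    class = "twv_beat"
  )
}

# save/restore the RNG state so simulators are pure functions of their seed
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Specify a synthetic cohort of cases
#'
#' Describes a group of cases, each contributing several consecutive beats
#' (ten by default, mirroring the measurement of ten consecutive V5 beats
#' per subject). Beat parameters vary between cases: each case draws its own
#' [beat_spec()] parameters from independent Gaussians with the given means
#' and between-case standard deviations, and all beats of a case share those
#' parameters, differing only in their noise realisation.
#'
#' @param label Group label (e.g. `"normal"`, `"late_onset"`).
#' @param n_cases Number of cases (>= 2).
#' @param beats_per_case Beats per case (default 10).
#' @param means Named list of [beat_spec()] parameter means; unnamed
#'   parameters keep the `beat_spec()` defaults.
#' @param sds Named list of between-case SDs; parameters not named get SD 0.
#' @param seed Integer seed.
#' @return An object of class `twv_cohort_spec`.
#' @export
#' @examples
#' cohort_spec("late_onset", n_cases = 12,
#'             means = list(st_shift_ms = 60, t_amp = 0.4),
#'             sds = list(st_shift_ms = 10))
cohort_spec <- function(label, n_cases = 12, beats_per_case = 10,
                        means = list(), sds = list(), seed = 1L) {
  if (n_cases < 2) twv_abort("n_cases must be >= 2", "twv_bad_cohort_spec")
  if (beats_per_case < 1) twv_abort("beats_per_case must be >= 1", "twv_bad_cohort_spec")
  base <- formals(beat_spec)
  bad <- setdiff(c(names(means), names(sds)), names(base))
  if (length(bad)) {
    twv_abort(paste("unknown beat parameters:", paste(bad, collapse = ", ")),
              "twv_bad_cohort_spec")
  }
  structure(
    list(label = label, n_cases = as.integer(n_cases),
         beats_per_case = as.integer(beats_per_case),
         means = means, sds = sds, seed = as.integer(seed)),
    class = "twv_cohort_spec"
  )
}

#' Simulate a cohort of cases with known ground truth
#'
#' Draws per-case beat parameters from the cohort's between-case
#' distributions (truncating the strictly positive parameters at small
#' positive floors), then simulates every beat. Full provenance --- the
#' drawn parameters of every case --- is retained, so downstream recovery of
#' injected effects (e.g. an ST-segment stretch) can be checked against
#' truth. Regeneration with the same spec and seed is byte-identical.
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `twv_cohort`: list with `cases` (one row per
#'   case: `case_id`, `group`, and all drawn beat parameters), `beats`
#'   (tibble `case_id`, `group`, `beat_index`, `beat` list-column of
#'   `twv_beat`), and `spec`.
#' @export
#' @examples
#' ch <- simulate_cohort(cohort_spec("normal", n_cases = 2, beats_per_case = 2))
#' ch$cases
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "twv_cohort_spec"))
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(spec$seed)
  defaults <- lapply(formals(beat_spec), eval)
  par_names <- setdiff(names(defaults), "seed")
  floors <- c(rr_ms = 200, qrs_amp = 0.05, t_amp = 0.05,
              t_center_ms = 50, t_sigma_left_ms = 5, t_sigma_right_ms = 5,
              st_shift_ms = 0, noise_sd = 0, drift_amp = 0,
              drift_freq_hz = 0.01, powerline_amp = 0)
  cases <- purrr::map(seq_len(spec$n_cases), function(i) {
    drawn <- lapply(par_names, function(p) {
      m <- spec$means[[p]] %||% defaults[[p]]
      s <- spec$sds[[p]] %||% 0
      v <- if (s > 0) rnorm(1, m, s) else m
      max(v, floors[[p]])
    })
    names(drawn) <- par_names
    c(list(case_id = sprintf("%s_%02d", spec$label, i), group = spec$label), drawn)
  })
  cases_tbl <- purrr::map(cases, as_tibble) %>% list_rbind()
  beat_seeds <- matrix(
    sample.int(.Machine$integer.max - 1L, spec$n_cases * spec$beats_per_case),
    nrow = spec$n_cases
  )
  beats <- purrr::map(seq_len(spec$n_cases), function(i) {
    pars <- cases[[i]][par_names]
    purrr::map(seq_len(spec$beats_per_case), function(b) {
      bs <- do.call(beat_spec, c(pars, list(seed = beat_seeds[i, b])))
      tibble(case_id = cases[[i]]$case_id, group = spec$label, beat_index = b,
             beat = list(simulate_beat(bs)))
    }) %>% list_rbind()
  }) %>% list_rbind()
  structure(list(cases = cases_tbl, beats = beats, spec = spec),
            class = "twv_cohort")
}

#' Simulate landmark configurations under isotropic Gaussian perturbation
#'
#' Null-model generator for shape tests: each configuration is the mean
#' shape plus i.i.d. Gaussian noise of standard deviation `sigma` on every
#' coordinate. With `sigma = 0` all copies equal the mean shape.
#'
#' @param mean_shape A k x 2 coordinate matrix (or tidy tibble with
#'   `landmark`, `x`, `y`).
#' @param sigma Isotropic perturbation SD (>= 0).
#' @param n Number of configurations (>= 1).
#' @param seed Integer seed.
#' @return A `twv_configs` object: tidy tibble (`config_id`, `landmark`,
#'   `x`, `y`) with attributes `mean_shape`, `sigma`, `seed`.
#' @export
#' @examples
#' ms <- cbind(cos(1:9), sin(1:9))
#' cs <- simulate_configurations(ms, sigma = 0.01, n = 5, seed = 1)
simulate_configurations <- function(mean_shape, sigma, n, seed = 1L) {
  if (is.data.frame(mean_shape)) {
    mean_shape <- as.matrix(mean_shape[, c("x", "y")])
  }
  mean_shape <- unname(as.matrix(mean_shape))
  if (ncol(mean_shape) != 2) {
    twv_abort("mean_shape must be a k x 2 matrix", "twv_bad_configs")
  }
  if (max(dist(mean_shape)) < .Machine$double.eps) {
    twv_abort("degenerate mean_shape: all points coincident", "twv_bad_configs")
  }
  assert_number(sigma, "sigma", 0)
  assert_number(n, "n", 1)
  k <- nrow(mean_shape)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  lms <- rownames(mean_shape) %||% as.character(seq_len(k))
  out <- purrr::map(seq_len(n), function(i) {
    pert <- mean_shape + matrix(rnorm(2 * k, 0, sigma), k, 2)
    tibble(config_id = sprintf("cfg_%04d", i), landmark = lms,
           x = pert[, 1], y = pert[, 2])
  }) %>% list_rbind()
  structure(out, mean_shape = mean_shape, sigma = sigma, seed = seed,
            class = c("twv_configs", class(out)))
}

#' @export
print.twv_beat <- function(x, ...) {
  cat(sprintf("<twv_beat> rr = %g ms, T apex %g mV at Q+%g ms, noise sd %g mV\n",
              x$rr_ms, x$spec$t_amp,
              x$spec$t_center_ms + x$spec$st_shift_ms, x$spec$noise_sd))
  invisible(x)
}

#' @export
print.twv_cohort <- function(x, ...) {
  cat(sprintf("<twv_cohort> '%s': %d cases x %d beats\n",
              x$spec$label, x$spec$n_cases, x$spec$beats_per_case))
  invisible(x)
}
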