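#' Detect the Q and J points of a beat
#'
#' Q is the point at which the QRS complex first intersects the baseline and
#' J the point at which it last intersects it. Detection walks outward from
#' the R peak (supplied, or taken as the global maximum of the
#' baseline-corrected beat, valid for upright V5-like morphology): Q is the
#' baseline crossing immediately left of the R upstroke, J the first
#' crossing to the right of the final QRS deflection. Crossing abscissae are
#' interpolated between samples and snapped to the 1 ms grid. Manual
#' override coordinates, when supplied, are returned verbatim and detection
#' is skipped.
#'
#' @param beat A baseline-corrected beat (`twv_beat`, `twv_window`, or a
#'   data frame with `time_ms`, `mv`).
#' @param r_peak_ms Optional R peak time (ms, window-local).
#' @param overrides Optional list with `q_ms` and `j_ms` (window-local ms):
#'   manual coordinates returned as-is.
#' @return A list with `q_ms` and `j_ms` (window-local grid times).
#' @export
#' @examples
#' detect_q_j(simulate_beat(beat_spec()))
detect_q_j <- function(beat, r_peak_ms = NULL, overrides = NULL) {
  if (!is.null(overrides)) {
    if (!all(c("q_ms", "j_ms") %in% names(overrides))) {
      twv_abort("overrides must supply q_ms and j_ms", "twv_bad_argument")
    }
    return(list(q_ms = overrides$q_ms, j_ms = overrides$j_ms))
  }
  tr <- as_trace(beat)
  t <- tr$time_ms
  y <- tr$mv
  if (max(y) <= 0) {
    twv_abort("no positive deflection: cannot locate the QRS complex",
              "twv_no_crossing")
  }
  r_idx <- if (is.null(r_peak_ms)) which.max(y) else which.min(abs(t - r_peak_ms))
  # samples within a small fraction of the peak amplitude count as baseline
  tol <- 1e-3 * max(abs(y))
  # Q: last baseline intersection before the R upstroke
  below <- which(y[seq_len(r_idx - 1)] <= tol)
  if (!length(below)) {
    twv_abort("no baseline crossing found before the R peak", "twv_no_crossing")
  }
  i <- max(below)
  q_ms <- if (y[i] <= 0 && y[i + 1] > 0) {
    t[i] + (0 - y[i]) / (y[i + 1] - y[i])
  } else t[i]
  # J: first intersection after the final QRS deflection (S trough if present)
  s_win <- r_idx:min(length(y), r_idx + 120)
  s_idx <- s_win[which.min(y[s_win])]
  start <- if (y[s_idx] < 0) s_idx else r_idx
  after <- which(y[(start + 1):length(y)] >= -tol)
  if (!length(after)) {
    twv_abort("no baseline crossing found after the QRS complex", "twv_no_crossing")
  }
  j <- start + min(after)
  j_ms <- if (y[j] >= 0 && y[j - 1] < 0) {
    t[j - 1] + (0 - y[j - 1]) / (y[j] - y[j - 1])
  } else t[j]
  list(q_ms = round(q_ms), j_ms = round(j_ms))
}

# first grid time >= from_ms where |y| stays below frac*|tp_y| for run_ms;
# a short centred running mean suppresses sample noise around the threshold
.teeye_x <- function(tr, from_ms, tp_y, frac = 0.02, run_ms = 10) {
  t <- tr$time_ms
  y <- tr$mv
  ysm <- as.numeric(stats::filter(y, rep(1 / 5, 5), sides = 2))
  ysm[is.na(ysm)] <- y[is.na(ysm)]
  quiet <- abs(ysm) < frac * abs(tp_y)
  idx <- which(t >= from_ms)
  run <- 0L
  for (i in idx) {
    run <- if (quiet[i]) run + 1L else 0L
    if (run >= run_ms) return(t[i - run_ms + 1L])
  }
  twv_abort("no sustained return to baseline after the T-wave", "twv_no_teeye")
}

#' Detect the five derivative-based T-wave landmarks
#'
#' Locates, on the smoothed derivatives of the beat, the first local maximum
#' (`FdFmax`) and minimum (`FdFmin`) of the first derivative within the
#' T-wave region, the T apex `Tp` (first-derivative zero crossing
#' immediately left of `FdFmin`; with several candidate crossings the one
#' nearest `FdFmin` is taken with a warning), and the two second-derivative
#' maxima: `SdFmax`, searched between `J + offset_ms` and the T apex, and
#' `SdSmax`, searched between `FdFmin` and the automated visual T-end.
#'
#' @param beat Baseline-corrected beat.
#' @param derivs A `twv_derivs` from [beat_derivatives()].
#' @param q_ms,j_ms Q and J times from [detect_q_j()] (window-local ms).
#' @param offset_ms Left margin of the T search window after J (default 30).
#' @param teeye_frac Amplitude fraction defining the automated visual T-end
#'   (default 0.02 of the apex amplitude, sustained 10 ms).
#' @return A tibble (`landmark`, `x_ms`, `y_mv`) for SdFmax, FdFmax, Tp,
#'   FdFmin, SdSmax with x measured from Q, plus attribute `teeye_x_ms`
#'   (window-local).
#' @export
detect_t_landmarks <- function(beat, derivs, q_ms, j_ms,
                               offset_ms = 30, teeye_frac = 0.02) {
  tr <- as_trace(beat)
  t <- derivs$time_ms
  d1 <- derivs$d1
  d2 <- derivs$d2
  in_t <- t >= j_ms + offset_ms
  if (!any(in_t)) twv_abort("empty T-wave search interval", "twv_empty_interval")
  i_fmax <- which(in_t)[which.max(d1[in_t])]
  after <- t > t[i_fmax]
  if (!any(after)) twv_abort("empty interval after FdFmax", "twv_empty_interval")
  i_fmin <- which(after)[which.min(d1[after])]
  # Tp: d1 zero crossing immediately left of FdFmin
  span <- i_fmax:(i_fmin - 1L)
  cross <- span[d1[span] >= 0 & d1[span + 1L] < 0]
  if (!length(cross)) {
    twv_abort("no first-derivative zero crossing left of FdFmin", "twv_no_tp")
  }
  if (length(cross) > 1L) {
    warn("multiple first-derivative zero crossings near the T apex; using the one nearest FdFmin")
  }
  ic <- max(cross)
  tp_x <- if (d1[ic] == 0) t[ic] else t[ic] + d1[ic] / (d1[ic] - d1[ic + 1L])
  tp_y <- approx(tr$time_ms, tr$mv, tp_x)$y
  # SdFmax on [J + offset, Tp]
  w1 <- t >= j_ms + offset_ms & t <= tp_x
  if (!any(w1)) twv_abort("empty SdFmax search interval", "twv_empty_interval")
  i_s1 <- which(w1)[which.max(d2[w1])]
  # automated visual T-end, then SdSmax on [FdFmin, TeEye]
  teeye_x <- .teeye_x(tr, t[i_fmin], tp_y, frac = teeye_frac)
  w2 <- t >= t[i_fmin] & t <= teeye_x
  i_s2 <- which(w2)[which.max(d2[w2])]
  y_at <- function(i) tr$mv[match(t[i], tr$time_ms)]
  out <- tibble(
    landmark = c("SdFmax", "FdFmax", "Tp", "FdFmin", "SdSmax"),
    x_ms = c(t[i_s1], t[i_fmax], tp_x, t[i_fmin], t[i_s2]) - q_ms,
    y_mv = c(y_at(i_s1), y_at(i_fmax), tp_y, y_at(i_fmin), y_at(i_s2))
  )
  attr(out, "teeye_x_ms") <- teeye_x
  out
}

#' T-end by the tangent method, and the automated visual T-end
#'
#' The tangent drawn at the steepest descending point of the T-wave
#' (`FdFmin`, slope taken from the smoothed first derivative) is extended to
#' its baseline intersection: `Tend.x = FdFmin.x - y(FdFmin) / d1(FdFmin)`.
#' `Te` carries the V5 amplitude at that abscissa. `TeEye`, the reproducible
#' stand-in for the visually clicked T-end, is the first grid point after
#' `FdFmin` where the amplitude stays below `teeye_frac` of the apex
#' amplitude for 10 consecutive ms; its y is reported as exactly 0.
#'
#' @param beat Baseline-corrected beat.
#' @param derivs A `twv_derivs`.
#' @param fdfmin_x_ms FdFmin abscissa, window-local ms.
#' @param tp_y Apex amplitude (mV), used by the TeEye threshold.
#' @param q_ms Q time (window-local ms); outputs are reported relative to Q.
#' @param teeye_frac TeEye amplitude fraction (default 0.02).
#' @return A tibble (`landmark`, `x_ms`, `y_mv`) with rows `Te` and `TeEye`.
#' @export
tend_tangent <- function(beat, derivs, fdfmin_x_ms, tp_y, q_ms,
                         teeye_frac = 0.02) {
  tr <- as_trace(beat)
  i <- which.min(abs(derivs$time_ms - fdfmin_x_ms))
  slope <- derivs$d1[i]
  if (slope >= 0) {
    twv_abort("nonnegative slope at FdFmin: tangent cannot reach the baseline",
              "twv_bad_tangent")
  }
  y0 <- approx(tr$time_ms, tr$mv, derivs$time_ms[i])$y
  tend_x <- derivs$time_ms[i] - y0 / slope
  if (tend_x > max(tr$time_ms)) {
    twv_abort("tangent intersection beyond the beat window", "twv_bad_tangent")
  }
  te_y <- approx(tr$time_ms, tr$mv, tend_x)$y
  teeye_x <- .teeye_x(tr, derivs$time_ms[i], tp_y, frac = teeye_frac)
  tibble(landmark = c("Te", "TeEye"),
         x_ms = c(tend_x, teeye_x) - q_ms,
         y_mv = c(te_y, 0))
}

#' Extract the nine landmarks of one beat
#'
#' Runs the full single-beat landmarking chain: Q/J detection, smoothed
#' derivatives, T-wave landmark detection, and the tangent-method T-end. All
#' x coordinates are reported relative to Q (so Q is exactly (0, 0)) and
#' TeEye carries y = 0 exactly. The landmark ordering invariant
#' `0 = Q < J < SdFmax < FdFmax <= Tp <= FdFmin < SdSmax` is verified; a
#' violating beat is rejected with a diagnostic error, never silently
#' reordered.
#'
#' @inheritParams detect_t_landmarks
#' @param spar1 Smoothing parameter for the first derivative (default 0.5).
#' @param rr_ms RR interval (ms); taken from the beat when available.
#' @param r_peak_ms,overrides Passed to [detect_q_j()].
#' @param derivs Optional precomputed `twv_derivs`.
#' @return A `twv_landmarks` object: tibble (`landmark`, `x_ms`, `y_mv`) in
#'   canonical order with attributes `rr_ms`, `q_ms`, `bazett_applied =
#'   FALSE`.
#' @export
#' @examples
#' lm <- extract_landmarks(simulate_beat(beat_spec()))
#' lm
extract_landmarks <- function(beat, derivs = NULL, spar1 = 0.5,
                              offset_ms = 30, teeye_frac = 0.02,
                              rr_ms = NULL, r_peak_ms = NULL,
                              overrides = NULL) {
  tr <- as_trace(beat)
  rr <- rr_ms %||%
    (if (inherits(beat, "twv_beat")) beat$rr_ms else attr(beat, "rr_ms")) %||%
    (max(tr$time_ms) + 1)
  qj <- detect_q_j(beat, r_peak_ms = r_peak_ms, overrides = overrides)
  if (is.null(derivs)) derivs <- beat_derivatives(tr, spar1 = spar1)
  tl <- detect_t_landmarks(beat, derivs, qj$q_ms, qj$j_ms,
                           offset_ms = offset_ms, teeye_frac = teeye_frac)
  te <- tend_tangent(beat, derivs,
                     fdfmin_x_ms = tl$x_ms[tl$landmark == "FdFmin"] + qj$q_ms,
                     tp_y = tl$y_mv[tl$landmark == "Tp"],
                     q_ms = qj$q_ms, teeye_frac = teeye_frac)
  out <- bind_rows(
    tibble(landmark = c("Q", "J"),
           x_ms = c(0, qj$j_ms - qj$q_ms),
           y_mv = c(0, 0)),
    tl, te
  )
  out <- out[match(twv_landmark_names(), out$landmark), ]
  .check_landmark_order(out, offset_ms)
  structure(out, rr_ms = rr, q_ms = qj$q_ms, bazett_applied = FALSE,
            class = c("twv_landmarks", class(out)))
}

.check_landmark_order <- function(lm, offset_ms = 30) {
  x <- setNames(lm$x_ms, lm$landmark)
  chain <- c("Q", "J", "SdFmax", "FdFmax", "Tp", "FdFmin", "SdSmax")
  v <- x[chain]
  strict <- c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE)
  ok <- all(ifelse(strict, diff(v) > 0, diff(v) >= 0)) &&
    x[["SdFmax"]] >= x[["J"]] + offset_ms
  if (!ok) {
    twv_abort(paste0(
      "landmark ordering violated: ",
      paste(sprintf("%s=%.1f", chain, v), collapse = ", ")
    ), "twv_landmark_order")
  }
  invisible(lm)
}

#' Bazett heart-rate correction of landmark abscissae
#'
#' Divides every x coordinate (ms from Q) by the square root of the RR
#' interval in seconds, `x / sqrt(rr_ms / 1000)`, the Bazett convention for
#' normalising repolarisation intervals to heart rate. The y coordinates are
#' not revised. Applying the correction twice is an error.
#'
#' @param landmarks A `twv_landmarks` (or tibble with `landmark`, `x_ms`,
#'   `y_mv`).
#' @param rr_ms RR interval (ms); defaults to the object's `rr_ms` attribute.
#' @return The corrected `twv_landmarks`, with `bazett_applied = TRUE`.
#' @export
#' @examples
#' lm <- extract_landmarks(simulate_beat(beat_spec(rr_ms = 640)))
#' bazett_correct(lm)
bazett_correct <- function(landmarks, rr_ms = NULL) {
  rr <- rr_ms %||% attr(landmarks, "rr_ms")
  if (is.null(rr)) twv_abort("rr_ms not supplied", "twv_bad_argument")
  if (rr <= 0) twv_abort("rr_ms must be positive", "twv_bad_argument")
  if (isTRUE(attr(landmarks, "bazett_applied"))) {
    twv_abort("Bazett correction already applied", "twv_already_bazett")
  }
  out <- landmarks
  out$x_ms <- landmarks$x_ms / sqrt(rr / 1000)
  attr(out, "bazett_applied") <- TRUE
  attr(out, "rr_ms") <- rr
  if (!inherits(out, "twv_landmarks")) {
    class(out) <- c("twv_landmarks", class(out))
  }
  out
}

#' Average landmark sets over the beats of one case
#'
#' The per-case configuration entering the shape analysis is the arithmetic
#' per-coordinate mean of the landmarks of the case's available beats. Beats
#' whose landmarking failed may be passed as `NULL` (or error conditions);
#' they are counted and excluded.
#'
#' @param beat_landmarks A list of `twv_landmarks` (entries may be `NULL` or
#'   conditions for excluded beats).
#' @param case_id,group Optional identifiers carried into the result.
#' @return A `twv_case` object: list with `mean` (tibble `landmark`, `x_ms`,
#'   `y_mv`), `beats` (per-beat long tibble), `n_beats`, `n_excluded`,
#'   `case_id`, `group`.
#' @export
#' @examples
#' b <- simulate_beat(beat_spec())
#' aggregate_case(list(extract_landmarks(b), extract_landmarks(b)))$mean
aggregate_case <- function(beat_landmarks, case_id = NA_character_,
                           group = NA_character_) {
  ok <- purrr::map_lgl(beat_landmarks, function(b) {
    is.data.frame(b) && all(c("landmark", "x_ms", "y_mv") %in% names(b))
  })
  n_excluded <- sum(!ok)
  valid <- beat_landmarks[ok]
  if (!length(valid)) twv_abort("no valid beats to aggregate", "twv_no_valid_beats")
  beats <- imap(valid, function(b, i) {
    mutate(as_tibble(b), beat_index = i, rr_ms = attr(b, "rr_ms") %||% NA_real_)
  }) %>% list_rbind()
  mean_tbl <- beats %>%
    group_by(.data$landmark) %>%
    summarise(x_ms = mean(.data$x_ms), y_mv = mean(.data$y_mv),
              .groups = "drop")
  mean_tbl <- mean_tbl[match(twv_landmark_names(), mean_tbl$landmark), ]
  structure(
    list(mean = mean_tbl, beats = beats, n_beats = length(valid),
         n_excluded = n_excluded, case_id = case_id, group = group),
    class = "twv_case"
  )
}

#' Landmark a whole synthetic cohort
#'
#' Convenience chain for cohorts from [simulate_cohort()]: every beat is
#' baseline-checked, landmarked, optionally Bazett-corrected, and averaged
#' per case. Beats that fail landmarking are excluded with a record.
#'
#' @param cohort A `twv_cohort` (or a list of them, concatenated).
#' @param bazett Apply Bazett correction before averaging (default `TRUE`).
#' @param spar1,offset_ms,teeye_frac Landmarking parameters.
#' @return A list with `beats` (long per-beat landmark tibble), `cases`
#'   (per-case mean landmarks: `case_id`, `group`, `landmark`, `x`, `y`),
#'   and `excluded` (tibble of failed beats with messages).
#' @export
cohort_landmarks <- function(cohort, bazett = TRUE, spar1 = 0.5,
                             offset_ms = 30, teeye_frac = 0.02) {
  beats_tbl <- if (inherits(cohort, "twv_cohort")) cohort$beats
    else purrr::map(cohort, "beats") %>% list_rbind()
  res <- purrr::map(seq_len(nrow(beats_tbl)), function(i) {
    b <- beats_tbl$beat[[i]]
    lm <- tryCatch({
      corrected <- correct_baseline(b$trace)
      l <- extract_landmarks(corrected, spar1 = spar1, offset_ms = offset_ms,
                             teeye_frac = teeye_frac, rr_ms = b$rr_ms)
      if (bazett) l <- bazett_correct(l) else l
    }, twaveshape_error = function(e) e)
    list(row = beats_tbl[i, c("case_id", "group", "beat_index")], lm = lm)
  })
  failed <- purrr::map_lgl(res, ~ inherits(.x$lm, "condition"))
  excluded <- purrr::map(res[failed], function(r) {
    mutate(r$row, message = conditionMessage(r$lm))
  }) %>% list_rbind()
  beats <- purrr::map(res[!failed], function(r) {
    lm <- as_tibble(r$lm)
    mutate(lm, case_id = r$row$case_id, group = r$row$group,
           beat_index = r$row$beat_index,
           rr_ms = attr(r$lm, "rr_ms"))
  }) %>% list_rbind()
  if (!nrow(beats)) twv_abort("all beats failed landmarking", "twv_no_valid_beats")
  cases <- beats %>%
    group_by(.data$case_id, .data$group, .data$landmark) %>%
    summarise(x = mean(.data$x_ms), y = mean(.data$y_mv), .groups = "drop") %>%
    arrange(.data$case_id, match(.data$landmark, twv_landmark_names()))
  list(beats = beats, cases = cases, excluded = excluded)
}

#' @export
print.twv_landmarks <- function(x, ...) {
  cat(sprintf("<twv_landmarks> rr = %s ms, Bazett %s\n",
              format(attr(x, "rr_ms")),
              if (isTRUE(attr(x, "bazett_applied"))) "applied" else "not applied"))
  print(as_tibble(x))
  invisible(x)
}
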