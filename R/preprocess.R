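#' Derive precordial leads V1..V6 from chest channels
#'
#' Applies the lead derivation Vi = Ci + (II + III)/3 (i = 1..6) used when
#' chest electrodes are recorded as bipolar channels C1..C6 against the left
#' leg together with limb leads II and III. Input channels are untouched;
#' the V columns are appended.
#'
#' @param leads A data frame with a shared time grid and channel columns.
#'   Must contain `II`, `III`, and at least one of `C1`..`C6`.
#' @return A tibble: the input with `V1`..`V6` columns appended (for the C
#'   channels present).
#' @export
#' @examples
#' df <- tibble::tibble(time_ms = 0:4, II = 0.3, III = 0.3, C5 = 1)
#' derive_v_leads(df)$V5
derive_v_leads <- function(leads) {
  leads <- as_tibble(leads)
  if (!all(c("II", "III") %in% names(leads))) {
    twv_abort("leads II and III are required", "twv_missing_channel")
  }
  c_names <- intersect(paste0("C", 1:6), names(leads))
  if (!length(c_names)) {
    twv_abort("no chest channels C1..C6 found", "twv_missing_channel")
  }
  lens <- vapply(leads[c("II", "III", c_names)], length, integer(1))
  if (length(unique(lens)) != 1L) {
    twv_abort("channel lengths differ", "twv_bad_leads")
  }
  aug <- (leads$II + leads$III) / 3
  for (cn in c_names) {
    leads[[sub("^C", "V", cn)]] <- leads[[cn]] + aug
  }
  leads
}

#' Segment a trace into beat windows at P-wave onsets
#'
#' Cuts the V5 trace into one window per consecutive pair of P onsets, using
#' 0-based millisecond indexing with an inclusive start and exclusive end,
#' so a window from onset a to onset b holds samples a, a+1, ..., b-1. P
#' onsets are supplied (from annotation or generator ground truth); no
#' automatic P detector is provided.
#'
#' @param v5 Numeric vector sampled on the 1 ms grid, or a data frame with
#'   columns `time_ms` and `mv`.
#' @param p_onsets Strictly increasing onset times (ms, 0-based), at least two.
#' @return A list of `twv_window` objects, each a tibble (`time_ms` local
#'   0-based, `mv`) with attributes `p_onset_ms`, `next_p_onset_ms`, `rr_ms`,
#'   `baseline_corrected`.
#' @export
#' @examples
#' w <- segment_beats(sin(2 * pi * (0:1599) / 800), c(0, 800, 1600))
#' length(w)
segment_beats <- function(v5, p_onsets) {
  if (is.data.frame(v5)) v5 <- as_trace(v5)$mv
  if (length(p_onsets) < 2) {
    twv_abort("need at least two P onsets", "twv_bad_onsets")
  }
  if (any(diff(p_onsets) <= 0)) {
    twv_abort("p_onsets must be strictly increasing", "twv_bad_onsets")
  }
  if (min(p_onsets) < 0 || max(p_onsets) > length(v5)) {
    twv_abort("p_onsets outside the trace", "twv_bad_onsets")
  }
  purrr::map(seq_len(length(p_onsets) - 1), function(i) {
    a <- p_onsets[i]; b <- p_onsets[i + 1]
    w <- tibble(time_ms = seq.int(0, b - a - 1), mv = v5[(a + 1):b])
    structure(w, p_onset_ms = a, next_p_onset_ms = b, rr_ms = b - a,
              baseline_corrected = FALSE,
              class = c("twv_window", class(w)))
  })
}

#' Re-zero the baseline of a beat window
#'
#' Subtracts the straight line through the window's first and last samples
#' (the two P-onset anchors), so both endpoints become exactly zero. The
#' operation is idempotent and, being linear in time, leaves all second
#' differences of the signal untouched.
#'
#' @param window A `twv_window` from [segment_beats()], or any data frame
#'   with `time_ms` and `mv` columns.
#' @return The corrected window (same class), with attribute
#'   `baseline_corrected = TRUE`.
#' @export
#' @examples
#' w <- segment_beats(0.1 + 0.001 * (0:799), c(0, 800))[[1]]
#' range(correct_baseline(w)$mv)
correct_baseline <- function(window) {
  tr <- as_trace(window)
  n <- nrow(tr)
  if (n < 2) twv_abort("zero-length window", "twv_bad_window")
  t <- tr$time_ms
  y <- tr$mv
  line <- y[1] + (y[n] - y[1]) * (t - t[1]) / (t[n] - t[1])
  out <- tr
  out$mv <- y - line
  attrs <- attributes(window)
  for (a in c("p_onset_ms", "next_p_onset_ms", "rr_ms")) {
    attr(out, a) <- attrs[[a]]
  }
  attr(out, "baseline_corrected") <- TRUE
  if (!inherits(out, "twv_window")) {
    class(out) <- c("twv_window", class(out))
  }
  out
}
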