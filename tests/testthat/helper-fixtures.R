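# shared fixtures, all generated in code

# a non-degenerate 9-landmark planar template, roughly T-wave proportioned
template_shape <- function(scale = 1) {
  scale * cbind(c(0, 0.6, 2.1, 2.5, 3.0, 3.5, 3.9, 4.0, 4.4),
                c(0, 0.0, 1.1, 3.0, 5.0, 3.0, 1.1, 0.7, 0.0)) / 5
}

# two-group tidy configurations: group b displaced at one landmark
two_group_configs <- function(n_per = 12, sigma = 0.02, shift = c(0.08, -0.08),
                              shift_landmark = 3, seed = 1) {
  ms <- template_shape()
  ms2 <- ms
  ms2[shift_landmark, ] <- ms2[shift_landmark, ] + shift
  a <- simulate_configurations(ms, sigma, n_per, seed = seed)
  b <- simulate_configurations(ms2, sigma, n_per, seed = seed + 1000)
  dplyr::bind_rows(
    dplyr::mutate(a, case_id = paste0("a_", config_id), group = "a"),
    dplyr::mutate(b, case_id = paste0("b_", config_id), group = "b")
  )[, c("case_id", "group", "landmark", "x", "y")]
}

# apply a similarity transform to a tidy single configuration matrix
similarity_transform <- function(M, angle = 0, scale = 1, shift = c(0, 0)) {
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  t(t(scale * M %*% t(R)) + shift)
}

# small two-cohort simulation for end-to-end tests
small_study <- function(n_cases = 6, beats = 3, seed = 21, shift = 60) {
  list(
    normal = simulate_cohort(cohort_spec(
      "normal", n_cases = n_cases, beats_per_case = beats,
      means = list(st_shift_ms = 0, noise_sd = 0.005),
      sds = list(st_shift_ms = 10, t_center_ms = 10, rr_ms = 50),
      seed = seed)),
    late = simulate_cohort(cohort_spec(
      "late_onset", n_cases = n_cases, beats_per_case = beats,
      means = list(st_shift_ms = shift, t_amp = 0.4, noise_sd = 0.005),
      sds = list(st_shift_ms = 10, t_center_ms = 10, rr_ms = 50),
      seed = seed + 1))
  )
}
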