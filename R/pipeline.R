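#' Pipeline configuration
#'
#' Collects every tunable parameter of the end-to-end analysis with the
#' study defaults: smoothing parameter 0.5 for the first derivative, a
#' 30 ms SdFmax search offset after J, a 2% sustained-amplitude TeEye
#' threshold, Bazett correction on, GPA tolerance 1e-10, 10000 permutation
#' and bootstrap iterations, and icon displacement of 1 standard deviation.
#'
#' @param normal,late_onset [cohort_spec()]s for the two groups (defaults:
#'   12 cases x 10 beats each; the late-onset group has its T-wave delayed
#'   by 60 +/- 10 ms and lowered to 0.4 mV mean amplitude).
#' @param spar1 First-derivative smoothing parameter.
#' @param sdfmax_offset_ms SdFmax search offset after J (ms).
#' @param teeye_frac TeEye amplitude fraction.
#' @param bazett Apply Bazett correction before shape analysis.
#' @param gpa_tol GPA convergence tolerance.
#' @param n_perm,n_boot Goodall resampling iteration counts.
#' @param n_pcs,n_ics Component counts for PCA icons and ICA.
#' @param c_sd Icon displacement (standard deviations).
#' @param seed Master seed; per-stage sub-seeds are drawn from it.
#' @return A `twv_config` list.
#' @export
twv_config <- function(normal = NULL, late_onset = NULL,
                       spar1 = 0.5, sdfmax_offset_ms = 30, teeye_frac = 0.02,
                       bazett = TRUE, gpa_tol = 1e-10,
                       n_perm = 10000, n_boot = 10000,
                       n_pcs = 3, n_ics = 3, c_sd = 1, seed = 1L) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, 4)
  structure(
    list(
      normal = normal %||% cohort_spec(
        "normal", n_cases = 12, beats_per_case = 10,
        means = list(st_shift_ms = 0, t_amp = 0.5, noise_sd = 0.005),
        sds = list(st_shift_ms = 10, t_amp = 0.05, t_center_ms = 10, rr_ms = 50),
        seed = sub[1]),
      late_onset = late_onset %||% cohort_spec(
        "late_onset", n_cases = 12, beats_per_case = 10,
        means = list(st_shift_ms = 60, t_amp = 0.4, noise_sd = 0.005),
        sds = list(st_shift_ms = 10, t_amp = 0.05, t_center_ms = 10, rr_ms = 50),
        seed = sub[2]),
      spar1 = spar1, sdfmax_offset_ms = sdfmax_offset_ms,
      teeye_frac = teeye_frac, bazett = bazett, gpa_tol = gpa_tol,
      n_perm = n_perm, n_boot = n_boot, n_pcs = n_pcs, n_ics = n_ics,
      c_sd = c_sd, seed = as.integer(seed),
      goodall_seed = sub[3], stage_seed = sub[4]
    ),
    class = "twv_config"
  )
}

#' Run the full T-wave shape analysis pipeline
#'
#' Executes simulate -> baseline correction -> derivatives -> landmarks ->
#' Bazett -> per-case averaging -> GPA -> Goodall's F -> shape PCA -> JADE
#' ICA -> per-landmark group statistics -> best-subset logistic
#' discrimination, and returns every intermediate product together with a
#' machine-readable run manifest. Identical configuration and seed yield
#' identical outputs.
#'
#' @param config A [twv_config()].
#' @return A `twv_pipeline` object: list with `cohorts`, `landmarks`
#'   (beat-level), `cases` (per-case mean landmarks), `excluded`, `gpa`,
#'   `goodall`, `pca`, `ica`, `covariates`, `comparisons`, `ellipses`,
#'   `tps`, `models_pca`, `models_ica`, `manifest`.
#' @export
#' @examples
#' \donttest{
#' cfg <- twv_config(n_perm = 99, n_boot = 99, seed = 7)
#' res <- run_twave_pipeline(cfg)
#' res$goodall
#' }
run_twave_pipeline <- function(config = twv_config()) {
  stopifnot(inherits(config, "twv_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
            class = "twv_pipeline_error")
    })
  }
  stages_done <- character()
  note <- function(s) stages_done <<- c(stages_done, s)

  cohorts <- stage("simulate", list(normal = simulate_cohort(config$normal),
                                    late_onset = simulate_cohort(config$late_onset)))
  note("simulate")
  lmres <- stage("landmarks", {
    a <- cohort_landmarks(cohorts$normal, bazett = config$bazett,
                          spar1 = config$spar1,
                          offset_ms = config$sdfmax_offset_ms,
                          teeye_frac = config$teeye_frac)
    b <- cohort_landmarks(cohorts$late_onset, bazett = config$bazett,
                          spar1 = config$spar1,
                          offset_ms = config$sdfmax_offset_ms,
                          teeye_frac = config$teeye_frac)
    list(beats = bind_rows(a$beats, b$beats),
         cases = bind_rows(a$cases, b$cases),
         excluded = bind_rows(a$excluded, b$excluded))
  })
  note("landmarks")
  configs <- mutate(lmres$cases, landmark = as.character(.data$landmark))
  fit <- stage("gpa", gpa(configs, tol = config$gpa_tol))
  note("gpa")
  gf <- stage("goodall", goodall_f(configs, n_perm = config$n_perm,
                                   n_boot = config$n_boot,
                                   seed = config$goodall_seed))
  note("goodall")
  pca <- stage("pca", shape_pca(fit, c_sd = config$c_sd, n_icons = config$n_pcs))
  note("pca")
  ica <- stage("ica", ica_jade(pca, n_components = config$n_ics))
  note("ica")
  covariates <- stage("covariates", {
    cov <- fit$info %>%
      dplyr::rename(s = "centroid_size") %>%
      left_join(pca$scores[, c("case_id", paste0("PC", seq_len(min(config$n_pcs, ncol(pca$scores) - 2))))],
                by = "case_id") %>%
      left_join(ica$scores[, c("case_id", paste0("IC", seq_len(config$n_ics)))],
                by = "case_id")
    mutate(cov, y = as.integer(.data$group == "normal"))
  })
  note("covariates")
  comparisons <- stage("groupstats", compare_landmarks(lmres$cases))
  note("groupstats")
  ellipses <- stage("ellipses", {
    purrr::map(setdiff(twv_landmark_names(), c("Q")), function(lm) {
      purrr::map(unique(configs$group), function(g) {
        sub <- configs[configs$landmark == lm & configs$group == g, ]
        tryCatch(confidence_ellipse(cbind(sub$x, sub$y), landmark = lm, group = g),
                 twaveshape_error = function(e) NULL)
      }) %>% list_rbind()
    }) %>% list_rbind()
  })
  note("ellipses")
  tps <- stage("tps", {
    means <- configs %>%
      group_by(.data$group, .data$landmark) %>%
      summarise(x = mean(.data$x), y = mean(.data$y), .groups = "drop")
    ord <- function(g) {
      sub <- means[means$group == g, ]
      sub[match(twv_landmark_names(), sub$landmark), ]
    }
    tps_grid(ord("normal"), ord("late_onset"))
  })
  note("tps")
  pc_names <- paste0("PC", seq_len(min(config$n_pcs, sum(startsWith(names(covariates), "PC")))))
  ic_names <- paste0("IC", seq_len(config$n_ics))
  models_pca <- stage("classify_pca",
                      best_subset(covariates, "y", c("s", "rho", pc_names)))
  models_ica <- stage("classify_ica",
                      best_subset(covariates, "y", c("s", "rho", ic_names)))
  note("classify")
  manifest <- list(
    package = "twaveshape",
    version = as.character(utils::packageVersion("twaveshape")),
    r_version = R.version.string,
    seed = config$seed,
    parameters = config[c("spar1", "sdfmax_offset_ms", "teeye_frac", "bazett",
                          "gpa_tol", "n_perm", "n_boot", "n_pcs", "n_ics", "c_sd")],
    stages = stages_done,
    n_cases = nrow(fit$info),
    n_beats_excluded = nrow(lmres$excluded)
  )
  structure(
    list(cohorts = cohorts, landmarks = lmres$beats, cases = lmres$cases,
         excluded = lmres$excluded, gpa = fit, goodall = gf, pca = pca,
         ica = ica, covariates = covariates, comparisons = comparisons,
         ellipses = ellipses, tps = tps,
         models_pca = models_pca, models_ica = models_ica,
         manifest = manifest),
    class = "twv_pipeline"
  )
}

#' @export
print.twv_pipeline <- function(x, ...) {
  cat("<twv_pipeline>\n")
  cat(sprintf("  cases: %d (%s)\n", nrow(x$gpa$info),
              paste(unique(x$gpa$info$group), collapse = " vs ")))
  print(x$goodall)
  cat(sprintf("  best PCA-covariate model: %s (AIC %.3g)\n",
              x$models_pca$models$subset[1], x$models_pca$models$aic[1]))
  cat(sprintf("  best ICA-covariate model: %s (AIC %.3g)\n",
              x$models_ica$models$subset[1], x$models_ica$models$aic[1]))
  invisible(x)
}
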