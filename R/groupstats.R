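# Jeffreys-Zellner-Siow two-sample Bayes factor from the t statistic,
# Cauchy prior scale r on the standardised effect; numerical integration
.jzs_bf10 <- function(t, n1, n2, r = sqrt(2) / 2, rel_tol = 1e-9) {
  N <- n1 * n2 / (n1 + n2)
  nu <- n1 + n2 - 2
  log_lik_null <- -(nu + 1) / 2 * log1p(t^2 / nu)
  integrand <- function(g) {
    exp(-0.5 * log1p(N * g) -
          (nu + 1) / 2 * log1p(t^2 / ((1 + N * g) * nu)) -
          log_lik_null) *          # scaled for numerical stability
      (r^2 / 2)^(1 / 2) / gamma(1 / 2) * g^(-3 / 2) * exp(-r^2 / (2 * g))
  }
  val <- integrate(integrand, 0, Inf, rel.tol = rel_tol)$value
  val     # BF10 = val (the null likelihood cancels by the scaling)
}

# Yuen's trimmed-mean two-sample test
.yuen <- function(a, b, trim = 0.2) {
  g <- floor(trim * length(a))
  h1 <- length(a) - 2 * g
  g2 <- floor(trim * length(b))
  h2 <- length(b) - 2 * g2
  win_var <- function(x, tr) {
    n <- length(x)
    gg <- floor(tr * n)
    xs <- sort(x)
    xs[seq_len(gg)] <- xs[gg + 1]
    xs[(n - gg + 1):n] <- xs[n - gg]
    var(xs)
  }
  d1 <- (length(a) - 1) * win_var(a, trim) / (h1 * (h1 - 1))
  d2 <- (length(b) - 1) * win_var(b, trim) / (h2 * (h2 - 1))
  tstat <- (mean(a, trim = trim) - mean(b, trim = trim)) / sqrt(d1 + d2)
  df <- (d1 + d2)^2 / (d1^2 / (h1 - 1) + d2^2 / (h2 - 1))
  2 * pt(-abs(tstat), df)
}

#' Compare one landmark coordinate between two groups
#'
#' Parametric, nonparametric, robust and Bayesian two-sample comparisons of
#' a per-case landmark coordinate: Welch's t test, the Wilcoxon rank-sum
#' test, Yuen's 20%-trimmed-mean test, and the Jeffreys-Zellner-Siow Bayes
#' factor with Cauchy prior scale sqrt(2)/2 on the standardised effect,
#' reported as `log_e(BF01)` (evidence for the null over the alternative;
#' large negative values are decisive evidence for a group difference).
#'
#' @param a,b Numeric vectors of per-case values (each length >= 2).
#' @param landmark,axis Optional labels carried into the output.
#' @param trim Trimming proportion for the robust test (default 0.2).
#' @return A one-row tibble: group means/SDs, Welch `t`, `df`, `p_welch`,
#'   `p_wilcoxon`, `p_yuen`, `log_bf01`.
#' @export
#' @examples
#' compare_landmark(rnorm(12), rnorm(12, 2), landmark = "SdFmax", axis = "x")
compare_landmark <- function(a, b, landmark = NA_character_,
                             axis = NA_character_, trim = 0.2) {
  if (length(a) < 2 || length(b) < 2) {
    twv_abort("each group needs at least 2 values", "twv_bad_argument")
  }
  if (sd(a) == 0 && sd(b) == 0) {
    twv_abort("zero variance in both groups", "twv_degenerate_groups")
  }
  wt <- t.test(a, b, var.equal = FALSE)
  wx <- suppressWarnings(wilcox.test(a, b))
  bf10 <- .jzs_bf10(unname(wt$statistic), length(a), length(b))
  tibble(
    landmark = landmark, axis = axis,
    n_a = length(a), n_b = length(b),
    mean_a = mean(a), mean_b = mean(b),
    sd_a = sd(a), sd_b = sd(b),
    t = unname(wt$statistic), df = unname(wt$parameter),
    p_welch = wt$p.value,
    p_wilcoxon = wx$p.value,
    p_yuen = .yuen(a, b, trim = trim),
    log_bf01 = -log(bf10)
  )
}

#' Per-landmark group comparisons for a case table
#'
#' Runs [compare_landmark()] on the x and y coordinate of every landmark in
#' a per-case landmark table (as produced by [cohort_landmarks()]).
#'
#' @param cases Tibble with `case_id`, `group`, `landmark`, `x`, `y`
#'   (exactly two groups).
#' @param landmarks Landmarks to compare (default all present).
#' @return A tibble with one row per landmark and axis.
#' @export
compare_landmarks <- function(cases, landmarks = NULL) {
  lev <- unique(cases$group)
  if (length(lev) != 2) twv_abort("exactly two groups required", "twv_bad_argument")
  lms <- landmarks %||% {
    u <- unique(as.character(cases$landmark))
    c(intersect(twv_landmark_names(), u), setdiff(u, twv_landmark_names()))
  }
  rows <- purrr::map(lms, function(lm) {
    sub <- cases[cases$landmark == lm, ]
    a <- sub[sub$group == lev[1], ]
    b <- sub[sub$group == lev[2], ]
    bind_rows(
      tryCatch(compare_landmark(a$x, b$x, lm, "x"),
               twv_degenerate_groups = function(e) NULL),
      tryCatch(compare_landmark(a$y, b$y, lm, "y"),
               twv_degenerate_groups = function(e) NULL)
    )
  })
  list_rbind(rows)
}

#' Hotelling confidence ellipse for a planar mean
#'
#' The confidence region for the mean of n planar points: the ellipse whose
#' semi-axes follow the eigenstructure of the sample covariance with radii
#' `sqrt(eigenvalue * T2crit / n)`, where `T2crit = p (n - 1) / (n - p) *
#' qf(level, p, n - p)` is the Hotelling T-squared critical value (p = 2).
#'
#' @param points An n x 2 matrix or data frame (n >= 3).
#' @param level Confidence level (default 0.95).
#' @param landmark,group Optional labels.
#' @return A one-row tibble: `center_x`, `center_y`, semi-axes `a` >= `b`,
#'   orientation `angle` (radians, major axis), `level`, `n`.
#' @export
#' @examples
#' confidence_ellipse(matrix(rnorm(40), 20, 2))
confidence_ellipse <- function(points, level = 0.95,
                               landmark = NA_character_, group = NA_character_) {
  P <- as.matrix(points)
  n <- nrow(P)
  if (n < 3) twv_abort("need at least 3 points", "twv_bad_argument")
  S <- stats::cov(P)
  eg <- eigen(S, symmetric = TRUE)
  if (eg$values[2] <= max(eg$values[1], .Machine$double.eps) * 1e-10) {
    twv_abort("singular covariance: points are collinear", "twv_singular_cov")
  }
  t2crit <- 2 * (n - 1) / (n - 2) * qf(level, 2, n - 2)
  radii <- sqrt(eg$values * t2crit / n)
  tibble(
    landmark = landmark, group = group,
    center_x = mean(P[, 1]), center_y = mean(P[, 2]),
    a = radii[1], b = radii[2],
    angle = atan2(eg$vectors[2, 1], eg$vectors[1, 1]),
    level = level, n = n
  )
}

#' Demographic summary of a clinical characteristics table
#'
#' Summarises a patient characteristics table (case number, T-wave shape
#' label, sex, age, symptoms, mexiletine status, heart rate): arithmetic
#' mean and population standard deviation (divisor n) of age, sex counts,
#' T-wave morphology counts, and antiarrhythmic (mexiletine) counts.
#'
#' @param table1 A data frame with columns `shape`, `sex`, `age`,
#'   `mexiletine` (and optionally `heart_rate_bpm`), one row per case.
#' @return A one-row tibble: `n`, `age_mean`, `age_sd` (population SD),
#'   `n_male`, `n_female`, `n_late_onset`, `n_asymmetric`,
#'   `n_mexiletine_on`, `hr_mean`.
#' @export
#' @examples
#' cohort_demographics(lqts3_table1())
cohort_demographics <- function(table1) {
  need <- c("shape", "sex", "age", "mexiletine")
  if (!is.data.frame(table1) || !nrow(table1)) {
    twv_abort("empty characteristics table", "twv_bad_argument")
  }
  miss <- setdiff(need, names(table1))
  if (length(miss)) {
    twv_abort(paste("missing fields:", paste(miss, collapse = ", ")),
              "twv_bad_argument")
  }
  if (anyNA(table1[need])) twv_abort("missing values in required fields",
                                     "twv_bad_argument")
  n <- nrow(table1)
  tibble(
    n = n,
    age_mean = mean(table1$age),
    age_sd = sqrt(mean((table1$age - mean(table1$age))^2)),
    n_male = sum(table1$sex == "M"),
    n_female = sum(table1$sex == "F"),
    n_late_onset = sum(table1$shape == "Late-onset"),
    n_asymmetric = sum(table1$shape == "Asymmetric"),
    n_mexiletine_on = sum(table1$mexiletine == "On"),
    hr_mean = if ("heart_rate_bpm" %in% names(table1))
      mean(table1$heart_rate_bpm) else NA_real_
  )
}

#' Bundled LQTS3 clinical characteristics table
#'
#' The packaged fixture of the clinical characteristics of the 12 LQTS3
#' (E1784K) patients: case number, V5 T-wave shape label, sex, age,
#' symptoms, mexiletine status and heart rate.
#'
#' @return A tibble with 12 rows.
#' @export
lqts3_table1 <- function() {
  path <- system.file("extdata", "lqts3_table1.csv", package = "twaveshape",
                      mustWork = TRUE)
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
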