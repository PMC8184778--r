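#' Logistic regression with explicit complete-separation handling
#'
#' Maximum-likelihood logistic fit by iteratively reweighted least squares
#' (at most 25 iterations, stopping when the deviance change falls below
#' 1e-8). With complete separation the likelihood has no finite maximiser:
#' the solver stops at the iteration cap with the fitted probabilities
#' driven to 0/1 and a near-zero deviance, which is reported as attained
#' together with a `separation` flag. Coefficient magnitudes under
#' separation are solver-dependent and should not be interpreted; the AIC,
#' `deviance + 2 * (number of coefficients)`, converges to twice the
#' coefficient count and remains meaningful as a model-size floor.
#'
#' @param data A data frame holding the response and predictors.
#' @param response Name of the binary response column (two levels; factors,
#'   logicals or 0/1 numerics accepted).
#' @param predictors Character vector of predictor column names (may be
#'   empty for the intercept-only model).
#' @return A `twv_logit` object: list with `coefficients`, `deviance`,
#'   `aic`, `converged`, `separation`, `fitted`, `subset`, `n`,
#'   `n_coefficients`.
#' @export
#' @examples
#' d <- data.frame(y = rep(0:1, each = 12), x = c(rnorm(12), rnorm(12, 3)))
#' fit_logistic(d, "y", "x")
fit_logistic <- function(data, response, predictors = character()) {
  y_raw <- data[[response]]
  if (is.factor(y_raw) || is.character(y_raw)) {
    lev <- unique(as.character(y_raw))
    if (length(lev) != 2) twv_abort("response must have exactly two classes",
                                    "twv_bad_response")
    y <- as.numeric(as.character(y_raw) == sort(lev)[2])
  } else {
    y <- as.numeric(y_raw)
  }
  if (length(unique(y)) != 2 || !all(y %in% c(0, 1))) {
    twv_abort("response must be binary with both classes present", "twv_bad_response")
  }
  X <- cbind(`(Intercept)` = 1,
             as.matrix(data[, predictors, drop = FALSE]))
  if (qr(X)$rank < ncol(X)) {
    twv_abort("rank-deficient design matrix", "twv_rank_deficient")
  }
  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(),
            control = glm.control(epsilon = 1e-8, maxit = 25))
  )
  p <- fit$fitted.values
  extreme <- all(p < 1e-6 | p > 1 - 1e-6)
  perfect <- all((p > 0.5) == (y == 1))
  k <- ncol(X)
  structure(
    list(coefficients = coef(fit),
         deviance = fit$deviance,
         aic = fit$deviance + 2 * k,
         converged = fit$converged,
         separation = extreme && perfect,
         fitted = p,
         subset = predictors,
         n = length(y),
         n_coefficients = k),
    class = "twv_logit"
  )
}

#' Exhaustive best-subset logistic regression by AIC
#'
#' Fits every subset of the candidate predictors (including the
#' intercept-only model) by [fit_logistic()] and ranks the fits by AIC
#' (`deviance + 2 * number of coefficients`, intercept included in the
#' count). Ties are broken toward fewer predictors. Individual subset
#' failures (e.g. a rank-deficient design) are recorded without aborting
#' the sweep.
#'
#' @param data A data frame holding the response and candidates.
#' @param response Name of the binary response column.
#' @param candidates Candidate predictor names (at most 15).
#' @return A `twv_best_subset` object: list with `models` (one row per
#'   subset: `subset`, `n_predictors`, `deviance`, `aic`, `converged`,
#'   `separation`, `error`), `best` (the winning `twv_logit`), `response`,
#'   `candidates`.
#' @export
#' @examples
#' d <- data.frame(y = rep(0:1, each = 12),
#'                 x1 = c(rnorm(12), rnorm(12, 3)), x2 = rnorm(24))
#' best_subset(d, "y", c("x1", "x2"))$best$subset
best_subset <- function(data, response, candidates) {
  if (length(candidates) > 15) {
    twv_abort("exhaustive enumeration limited to 15 candidates", "twv_bad_argument")
  }
  subsets <- list(character())
  for (m in seq_along(candidates)) {
    subsets <- c(subsets,
                 apply(combn(candidates, m), 2, identity, simplify = FALSE))
  }
  fits <- purrr::map(subsets, function(s) {
    tryCatch(fit_logistic(data, response, s),
             twaveshape_error = function(e) e)
  })
  rows <- purrr::map2(subsets, fits, function(s, f) {
    if (inherits(f, "condition")) {
      tibble(subset = paste(s, collapse = " + "), n_predictors = length(s),
             deviance = NA_real_, aic = NA_real_, converged = NA,
             separation = NA, error = conditionMessage(f))
    } else {
      tibble(subset = if (length(s)) paste(s, collapse = " + ") else "(intercept)",
             n_predictors = length(s),
             deviance = f$deviance, aic = f$aic, converged = f$converged,
             separation = f$separation, error = NA_character_)
    }
  }) %>% list_rbind()
  ok <- which(!is.na(rows$aic))
  if (!length(ok)) twv_abort("every subset failed to fit", "twv_all_failed")
  ord <- ok[order(rows$aic[ok], rows$n_predictors[ok])]
  rows <- mutate(rows, rank = match(seq_len(nrow(rows)), ord))
  structure(
    list(models = arrange(rows, .data$rank),
         best = fits[[ord[1]]],
         response = response, candidates = candidates),
    class = "twv_best_subset"
  )
}

#' @export
print.twv_logit <- function(x, ...) {
  cat(sprintf("<twv_logit> %s; deviance %.4g, AIC %.4g%s%s\n",
              if (length(x$subset)) paste(x$subset, collapse = " + ") else "(intercept)",
              x$deviance, x$aic,
              if (x$separation) "; complete separation" else "",
              if (!x$converged) "; iteration cap reached" else ""))
  invisible(x)
}

#' @export
print.twv_best_subset <- function(x, ...) {
  cat(sprintf("<twv_best_subset> %d models over {%s}\n",
              nrow(x$models), paste(x$candidates, collapse = ", ")))
  print(head(x$models, 5))
  invisible(x)
}
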