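#' Tidy a GPA fit
#'
#' One row per configuration: centroid size and Riemannian distance to the
#' mean shape.
#'
#' @param x A `twv_gpa`.
#' @param ... Unused.
#' @return A tibble (`case_id`, `group`, `centroid_size`, `rho`).
#' @export
tidy.twv_gpa <- function(x, ...) x$info

#' @rdname tidy.twv_gpa
#' @export
glance.twv_gpa <- function(x, ...) {
  tibble(n = x$n, k = x$k,
         mean_rho = mean(x$info$rho),
         total_procrustes_ss = sum(sin(x$info$rho)^2))
}

#' Tidy a Goodall test
#'
#' @param x A `twv_goodall`.
#' @param ... Unused.
#' @return A tibble with one row per p-value flavour (tabular, permutation,
#'   bootstrap).
#' @export
tidy.twv_goodall <- function(x, ...) {
  tibble(
    method = c("tabular", "permutation", "bootstrap"),
    p.value = c(x$p_tabular, x$p_permutation, x$p_bootstrap),
    iterations = c(NA_integer_, x$n_perm, x$n_boot)
  )
}

#' @rdname tidy.twv_goodall
#' @export
glance.twv_goodall <- function(x, ...) {
  tibble(statistic = x$statistic, df1 = x$df1, df2 = x$df2,
         p_tabular = x$p_tabular, p_permutation = x$p_permutation,
         p_bootstrap = x$p_bootstrap, n1 = x$n1, n2 = x$n2,
         degenerate = x$degenerate)
}

#' Tidy a shape PCA
#'
#' @param x A `twv_shape_pca`.
#' @param ... Unused.
#' @return A tibble (`component`, `eigenvalue`, `percent_variance`,
#'   `cumulative_percent`).
#' @export
tidy.twv_shape_pca <- function(x, ...) {
  tibble(component = paste0("PC", seq_along(x$eigenvalues)),
         eigenvalue = x$eigenvalues,
         percent_variance = x$percent_variance,
         cumulative_percent = cumsum(x$percent_variance))
}

#' Tidy a fitted logistic model
#'
#' @param x A `twv_logit`.
#' @param ... Unused.
#' @return A tibble (`term`, `estimate`).
#' @export
tidy.twv_logit <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @rdname tidy.twv_logit
#' @export
glance.twv_logit <- function(x, ...) {
  tibble(deviance = x$deviance, aic = x$aic, n = x$n,
         n_coefficients = x$n_coefficients,
         converged = x$converged, separation = x$separation)
}

#' Tidy a best-subset sweep
#'
#' @param x A `twv_best_subset`.
#' @param ... Unused.
#' @return The ranked model table.
#' @export
tidy.twv_best_subset <- function(x, ...) x$models

#' @rdname tidy.twv_best_subset
#' @export
glance.twv_best_subset <- function(x, ...) glance(x$best)

#' Tidy an ICA decomposition
#'
#' @param x A `twv_ica`.
#' @param ... Unused.
#' @return The IC score tibble.
#' @export
tidy.twv_ica <- function(x, ...) x$scores

#' Tidy a case-averaged landmark set
#'
#' @param x A `twv_case`.
#' @param ... Unused.
#' @return The per-case mean landmark tibble.
#' @export
tidy.twv_case <- function(x, ...) {
  mutate(x$mean, case_id = x$case_id, group = x$group)
}
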