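#' Principal component analysis of shape in the tangent space
#'
#' Eigendecomposition of the covariance of the Procrustes tangent
#' coordinates of a GPA fit. For planar configurations of k landmarks the
#' tangent space has dimension 2k - 4, so at most `min(n - 1, 2k - 4)`
#' components carry variance; the percent-variance column is normalised
#' over the nonzero eigenvalues and sums to 100. For each retained
#' component an icon shape is produced by adding `c` standard deviations of
#' that component to the mean shape and mapping the vector back to a
#' configuration (`c = 1` by default).
#'
#' @param fit A `twv_gpa` from [gpa()].
#' @param c_sd Icon displacement in standard deviations along each PC
#'   (default 1).
#' @param n_icons Number of components to build icons for (default 3).
#' @return A `twv_shape_pca` object: list with `eigenvalues`,
#'   `percent_variance`, `loadings` (2k x m), `scores` (tibble `case_id`,
#'   `group`, `PC1`...), `icons` (tidy tibble `component`, `landmark`, `x`,
#'   `y`), `mean_shape`, `c_sd`.
#' @export
#' @examples
#' cs <- simulate_configurations(cbind(cos(1:9), sin(1:9)), 0.02, 12, seed = 3)
#' p <- shape_pca(gpa(cs))
#' p$percent_variance[1:3]
shape_pca <- function(fit, c_sd = 1, n_icons = 3) {
  stopifnot(inherits(fit, "twv_gpa"))
  if (fit$n < 3) twv_abort("need at least 3 configurations for shape PCA",
                           "twv_bad_argument")
  Tm <- scale(fit$tangent, center = TRUE, scale = FALSE)
  n <- nrow(Tm)
  cv <- crossprod(Tm) / (n - 1)
  eg <- eigen(cv, symmetric = TRUE)
  tol <- max(eg$values) * 1e-10
  keep <- which(eg$values > tol)
  vals <- eg$values[keep]
  vecs <- eg$vectors[, keep, drop = FALSE]
  # deterministic sign: largest-|loading| entry positive
  for (j in seq_along(keep)) {
    i0 <- which.max(abs(vecs[, j]))
    if (vecs[i0, j] < 0) vecs[, j] <- -vecs[, j]
  }
  scores <- Tm %*% vecs
  colnames(scores) <- paste0("PC", seq_along(keep))
  pct <- 100 * vals / sum(vals)
  k <- fit$k
  mu_vec <- c(fit$mean_shape$x, fit$mean_shape$y)
  m_icons <- min(n_icons, length(keep))
  icons <- purrr::map(seq_len(m_icons), function(j) {
    v <- mu_vec + c_sd * sqrt(vals[j]) * vecs[, j]
    tibble(component = paste0("PC", j), landmark = fit$landmarks,
           x = v[1:k], y = v[k + 1:k])
  }) %>% list_rbind()
  score_tbl <- bind_cols(
    fit$info[, c("case_id", "group")],
    as_tibble(scores)
  )
  structure(
    list(eigenvalues = vals, percent_variance = pct,
         loadings = vecs, scores = score_tbl, icons = icons,
         mean_shape = fit$mean_shape, c_sd = c_sd,
         landmarks = fit$landmarks, k = k, n = fit$n),
    class = "twv_shape_pca"
  )
}

#' @export
print.twv_shape_pca <- function(x, ...) {
  cat(sprintf("<twv_shape_pca> %d configurations; variance explained: %s\n",
              x$n,
              paste(sprintf("PC%d %.1f%%", seq_len(min(3, length(x$percent_variance))),
                            x$percent_variance[seq_len(min(3, length(x$percent_variance)))]),
                    collapse = ", ")))
  invisible(x)
}
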