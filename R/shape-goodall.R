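# Goodall F statistic from preshape columns and two index sets
.goodall_stat <- function(Z, idx1, idx2, tol = 1e-10) {
  n1 <- length(idx1)
  n2 <- length(idx2)
  f1 <- .fp_mean(Z[, idx1, drop = FALSE], tol = tol)
  f2 <- .fp_mean(Z[, idx2, drop = FALSE], tol = tol)
  d2 <- 1 - pmin(1, Mod(sum(Conj(f1$mu) * f2$mu))^2)   # squared full Procrustes distance
  ssw <- (n1 - f1$lambda) + (n2 - f2$lambda)           # pooled within-group Procrustes SS
  list(F = (d2 / (1 / n1 + 1 / n2)) / (ssw / (n1 + n2 - 2)),
       ssw = ssw, d2 = d2, mu1 = f1$mu, mu2 = f2$mu)
}

#' Goodall's F test for a mean shape difference between two groups
#'
#' Under isotropic landmark variation the scaled ratio of the between-mean
#' full Procrustes distance to the pooled within-group Procrustes sum of
#' squares, `F = [d_F^2(mu1, mu2) / (1/n1 + 1/n2)] / [SS_within /
#' (n1 + n2 - 2)]`, follows an F distribution with `q` and `(n1 + n2 - 2) q`
#' degrees of freedom, `q = 2k - 4` for planar configurations of k
#' landmarks. Because isotropy rarely holds exactly, a permutation p-value
#' (group labels reshuffled) and a bootstrap p-value (cases resampled with
#' replacement within group after translating each group's configurations
#' to the pooled mean, enforcing the null) are also reported, both with
#' resolution 1/(iterations + 1).
#'
#' @param configs Tidy configurations with a `group` column (exactly two
#'   levels), or a k x 2 x n array with `groups` supplied.
#' @param groups Group labels (needed for array input).
#' @param n_perm,n_boot Resampling iteration counts (default 10000 each).
#' @param seed Integer seed for the resampling.
#' @return A `twv_goodall` object: list with `statistic`, `df1`, `df2`,
#'   `p_tabular`, `p_permutation`, `p_bootstrap`, `n_perm`, `n_boot`,
#'   `n1`, `n2`, `k`, `degenerate`, `seed`.
#' @export
#' @examples
#' ms <- cbind(cos(1:9), sin(1:9))
#' a <- simulate_configurations(ms, 0.02, 10, seed = 1)
#' b <- simulate_configurations(ms + 0.05, 0.02, 10, seed = 2)
#' cfg <- dplyr::bind_rows(dplyr::mutate(a, group = "a"),
#'                         dplyr::mutate(b, group = "b"))
#' goodall_f(cfg, n_perm = 99, n_boot = 99, seed = 1)
goodall_f <- function(configs, groups = NULL, n_perm = 10000, n_boot = 10000,
                      seed = 1L) {
  ca <- config_array(configs)
  groups <- groups %||% ca$groups
  if (is.null(groups)) {
    twv_abort("group labels are required", "twv_bad_argument")
  }
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) twv_abort("exactly two groups required", "twv_bad_argument")
  idx1 <- which(groups == lev[1])
  idx2 <- which(groups == lev[2])
  if (length(idx1) < 2 || length(idx2) < 2) {
    twv_abort("each group needs at least 2 configurations", "twv_bad_argument")
  }
  k <- dim(ca$arr)[1]
  n <- length(groups)
  Z <- .preshapes(ca$arr)$Z
  obs <- .goodall_stat(Z, idx1, idx2)
  if (obs$ssw < 1e-12) {
    return(structure(
      list(statistic = NA_real_, df1 = 2 * k - 4, df2 = (n - 2) * (2 * k - 4),
           p_tabular = NA_real_, p_permutation = NA_real_,
           p_bootstrap = NA_real_, n_perm = n_perm, n_boot = n_boot,
           n1 = length(idx1), n2 = length(idx2), k = k,
           degenerate = TRUE, seed = seed),
      class = "twv_goodall"
    ))
  }
  q <- 2 * k - 4
  df2 <- (n - 2) * q
  p_tab <- pf(obs$F, q, df2, lower.tail = FALSE)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  p_perm <- NA_real_
  if (n_perm > 0) {
    cnt <- 0L
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n)
      Fb <- .goodall_stat(Z, idx[seq_along(idx1)], idx[-seq_along(idx1)])$F
      if (Fb >= obs$F) cnt <- cnt + 1L
    }
    p_perm <- (cnt + 1) / (n_perm + 1)
  }
  p_boot <- NA_real_
  if (n_boot > 0) {
    # null enforcement: align each configuration to its group mean, carry its
    # residual to the pooled mean, renormalise to a preshape
    pooled <- .fp_mean(Z)$mu
    null_Z <- Z
    for (g in list(list(idx = idx1, mu = obs$mu1), list(idx = idx2, mu = obs$mu2))) {
      a <- as.vector(crossprod(Conj(Z[, g$idx, drop = FALSE]), g$mu))
      fits <- sweep(Z[, g$idx, drop = FALSE], 2, a, `*`)
      shifted <- fits - g$mu + pooled
      nz <- sqrt(colSums(Mod(shifted)^2))
      null_Z[, g$idx] <- sweep(shifted, 2, nz, `/`)
    }
    cnt <- 0L
    for (b in seq_len(n_boot)) {
      i1 <- sample(idx1, replace = TRUE)
      i2 <- sample(idx2, replace = TRUE)
      Zb <- cbind(null_Z[, i1, drop = FALSE], null_Z[, i2, drop = FALSE])
      st <- tryCatch(
        .goodall_stat(Zb, seq_along(i1), length(i1) + seq_along(i2)),
        twaveshape_error = function(e) NULL
      )
      if (!is.null(st) && st$ssw > 1e-12 && st$F >= obs$F) cnt <- cnt + 1L
    }
    p_boot <- (cnt + 1) / (n_boot + 1)
  }
  structure(
    list(statistic = obs$F, df1 = q, df2 = df2,
         p_tabular = p_tab, p_permutation = p_perm, p_bootstrap = p_boot,
         n_perm = n_perm, n_boot = n_boot,
         n1 = length(idx1), n2 = length(idx2), k = k,
         degenerate = FALSE, seed = seed),
    class = "twv_goodall"
  )
}

#' @export
print.twv_goodall <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("<twv_goodall> degenerate: zero within-group shape variation\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<twv_goodall> F(%d, %d) = %.4g; p: tabular %.4g, permutation %.4g (%d), bootstrap %.4g (%d)\n",
    x$df1, x$df2, x$statistic, x$p_tabular, x$p_permutation, x$n_perm,
    x$p_bootstrap, x$n_boot))
  invisible(x)
}
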