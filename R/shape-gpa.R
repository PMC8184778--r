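# ---- complex (planar) shape helpers ------------------------------------
# A centred planar configuration is represented as a complex k-vector;
# similarity transformations act as complex affine maps, which makes full
# Procrustes alignment a rank-one Hermitian eigenproblem.

# k x 2 matrix -> centred complex vector and centroid size
.to_complex <- function(M) {
  z <- complex(real = M[, 1], imaginary = M[, 2])
  z <- z - mean(z)
  s <- sqrt(sum(Mod(z)^2))
  list(z = z, size = s)
}

.from_complex <- function(z) cbind(Re(z), Im(z))

# preshape matrix: k x n complex, each column centred and unit-size
.preshapes <- function(arr) {
  n <- dim(arr)[3]
  Z <- matrix(0i, nrow = dim(arr)[1], ncol = n)
  sizes <- numeric(n)
  for (i in seq_len(n)) {
    cz <- .to_complex(arr[, , i])
    if (cz$size < sqrt(.Machine$double.eps)) {
      twv_abort(sprintf("configuration %d is degenerate (all points coincident)", i),
                "twv_degenerate_config")
    }
    Z[, i] <- cz$z / cz$size
    sizes[i] <- cz$size
  }
  list(Z = Z, sizes = sizes)
}

# full Procrustes mean of preshape columns: dominant eigenvector of Z Z^H,
# by power iteration (identical fixed point to iterative align-and-average)
.fp_mean <- function(Z, tol = 1e-10, max_iter = 1000) {
  S <- Z %*% Conj(t(Z))
  v <- Z[, 1]
  lam <- 0
  for (it in seq_len(max_iter)) {
    w <- S %*% v
    lam <- sqrt(sum(Mod(w)^2))
    w <- w / lam
    # compare up to rotation (phase)
    ph <- sum(Conj(v) * w)
    ph <- if (Mod(ph) > 0) ph / Mod(ph) else 1
    delta <- sqrt(sum(Mod(w - v * ph)^2))
    v <- as.vector(w)
    if (delta < tol) break
  }
  if (delta >= tol) {
    twv_abort("Procrustes mean estimation did not converge", "twv_gpa_no_convergence")
  }
  list(mu = v, lambda = Re(sum(Conj(v) * (S %*% v))))
}

# |<z, mu>| for unit preshapes = cosine of the Riemannian shape distance
.match_cos <- function(Z, mu) {
  pmin(1, Mod(as.vector(crossprod(Conj(Z), mu))))
}

#' Generalized Procrustes analysis of planar landmark configurations
#'
#' Registers the configurations by translation, scaling and rotation to
#' minimise the total sum of squared distances to their common mean shape
#' (full GPA). Internally each centred configuration is a complex vector;
#' the full Procrustes mean is the dominant eigenvector of the complex
#' sum-of-squares matrix, found by power iteration to the requested
#' tolerance, and each configuration is aligned onto it by its optimal
#' complex similarity. The mean is rotated back towards the raw average
#' orientation of the inputs, so output coordinates remain comparable to
#' the input frame.
#'
#' Outputs include the centroid sizes `s` of the raw configurations, the
#' Riemannian distances `rho = acos |<z, mu>|` of each configuration to the
#' mean (in `[0, pi/2]`), and Procrustes tangent coordinates: the aligned
#' configurations vectorised and projected orthogonally to the similarity
#' directions (translations, scaling, rotation) at the mean shape.
#'
#' @param configs Tidy configurations (`case_id`/`config_id`, optional
#'   `group`, `landmark`, `x`, `y`) or a k x 2 x n array.
#' @param tol Convergence tolerance on the mean shape (default 1e-10).
#' @param max_iter Iteration cap (default 1000).
#' @return A `twv_gpa` object: list with `mean_shape` (tibble, unit centroid
#'   size, centred), `aligned` (tidy tibble of aligned configurations),
#'   `info` (tibble `case_id`, `group`, `centroid_size`, `rho`), `tangent`
#'   (n x 2k matrix), `landmarks`, `k`, `n`.
#' @export
#' @examples
#' cs <- simulate_configurations(cbind(cos(1:9), sin(1:9)), 0.02, 10, seed = 2)
#' fit <- gpa(cs)
#' fit$info
gpa <- function(configs, tol = 1e-10, max_iter = 1000) {
  ca <- config_array(configs)
  n <- dim(ca$arr)[3]
  k <- dim(ca$arr)[1]
  if (n < 2) twv_abort("need at least 2 configurations", "twv_bad_configs")
  if (k < 3) twv_abort("need at least 3 landmarks", "twv_bad_configs")
  ps <- .preshapes(ca$arr)
  Z <- ps$Z
  fm <- .fp_mean(Z, tol = tol, max_iter = max_iter)
  mu <- fm$mu
  # canonical orientation: rotate mean to match the raw average of preshapes
  avg <- rowMeans(Z)
  ph <- sum(Conj(avg) * mu)
  if (Mod(ph) > 0) mu <- mu * Conj(ph) / Mod(ph)
  mu <- mu / sqrt(sum(Mod(mu)^2))
  # full Procrustes fits onto the mean: w_i = <z_i, mu> z_i
  a <- as.vector(crossprod(Conj(Z), mu))      # <z_i, mu>
  W <- sweep(Z, 2, a, `*`)
  # rho from the fit residual norm: asin(d_F) is accurate near zero, where
  # acos(|<z, mu>|) loses half the machine digits
  d_full <- sqrt(colSums(Mod(W - mu)^2))
  rho <- asin(pmin(1, d_full))
  # tangent coordinates: vectorised fits, projected off the similarity
  # directions at the mean
  gamma <- c(Re(mu), Im(mu))
  gamma_rot <- c(-Im(mu), Re(mu))
  ones <- rep(1, k)
  B <- cbind(c(ones, 0 * ones), c(0 * ones, ones), gamma, gamma_rot)
  Q <- qr.Q(qr(B))
  V <- rbind(Re(W), Im(W))                    # 2k x n
  Vt <- V - Q %*% crossprod(Q, V)
  tangent <- t(Vt)
  ids <- ca$ids
  rownames(tangent) <- ids
  mean_tbl <- tibble(landmark = ca$landmarks,
                     x = Re(mu), y = Im(mu))
  aligned_arr <- array(0, dim = c(k, 2, n),
                       dimnames = list(ca$landmarks, c("x", "y"), ids))
  for (i in seq_len(n)) aligned_arr[, , i] <- .from_complex(W[, i])
  structure(
    list(mean_shape = mean_tbl,
         aligned = array_to_tidy(aligned_arr, ids, ca$groups),
         info = tibble(case_id = ids,
                       group = ca$groups %||% NA_character_,
                       centroid_size = ps$sizes,
                       rho = rho),
         tangent = tangent,
         landmarks = ca$landmarks, k = k, n = n),
    class = "twv_gpa"
  )
}

#' Procrustes distance between two planar configurations
#'
#' The full Procrustes distance `d_F` (minimised over translation, scale
#' and rotation) and the Riemannian shape distance `rho = asin(d_F)`
#' between two configurations with corresponding landmarks.
#'
#' @param a,b k x 2 matrices or tidy single configurations.
#' @return A list with `rho` (in `[0, pi/2]`) and `d_full`.
#' @export
#' @examples
#' procrustes_distance(cbind(c(0, 1, 0), c(0, 0, 1)),
#'                     cbind(c(0, 2, 0), c(0, 0, 1)))
procrustes_distance <- function(a, b) {
  if (is.data.frame(a)) a <- as.matrix(a[, c("x", "y")])
  if (is.data.frame(b)) b <- as.matrix(b[, c("x", "y")])
  za <- .to_complex(unname(as.matrix(a)))
  zb <- .to_complex(unname(as.matrix(b)))
  if (za$size < sqrt(.Machine$double.eps) || zb$size < sqrt(.Machine$double.eps)) {
    twv_abort("degenerate configuration", "twv_degenerate_config")
  }
  z1 <- za$z / za$size
  z2 <- zb$z / zb$size
  d_full <- sqrt(sum(Mod(z1 * sum(Conj(z1) * z2) - z2)^2))
  list(rho = asin(pmin(1, d_full)), d_full = d_full)
}

#' @export
print.twv_gpa <- function(x, ...) {
  cat(sprintf("<twv_gpa> %d configurations, %d landmarks; mean rho = %.4g\n",
              x$n, x$k, mean(x$info$rho)))
  invisible(x)
}
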