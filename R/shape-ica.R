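# joint approximate diagonalization of a list of symmetric matrices by
# Jacobi (Givens) rotations, maximising the sum of squared diagonals
.joint_diag <- function(mats, tol = 1e-8, max_sweeps = 100) {
  m <- nrow(mats[[1]])
  V <- diag(m)
  for (sweep in seq_len(max_sweeps)) {
    done <- TRUE
    for (p in seq_len(m - 1)) for (q in (p + 1):m) {
      g <- vapply(mats, function(A) c(A[p, p] - A[q, q], A[p, q] + A[q, p]),
                  numeric(2))
      ton <- sum(g[1, ]^2) - sum(g[2, ]^2)
      toff <- 2 * sum(g[1, ] * g[2, ])
      theta <- 0.5 * atan2(toff, ton + sqrt(ton^2 + toff^2))
      if (abs(theta) > tol) {
        done <- FALSE
        cth <- cos(theta); sth <- sin(theta)
        G <- diag(m)
        G[p, p] <- cth; G[q, q] <- cth; G[p, q] <- -sth; G[q, p] <- sth
        mats <- lapply(mats, function(A) crossprod(G, A) %*% G)
        V <- V %*% G
      }
    }
    if (done) break
  }
  V
}

# fourth-order cumulant matrices of whitened data Z (n x m), the full
# symmetric-basis set used by JADE
.cumulant_matrices <- function(Z) {
  n <- nrow(Z)
  m <- ncol(Z)
  mats <- list()
  idx <- 0L
  for (i in seq_len(m)) for (j in seq_len(i)) {
    Q <- crossprod(Z * (Z[, i] * Z[, j]), Z) / n
    M <- matrix(0, m, m)
    M[i, j] <- 1
    Q <- Q - M - t(M) - diag(m) * (i == j)
    if (i != j) Q <- Q * sqrt(2)
    idx <- idx + 1L
    mats[[idx]] <- Q
  }
  mats
}

#' Independent component analysis by JADE
#'
#' Joint Approximate Diagonalization of Eigenmatrices: the data are
#' whitened, the full set of fourth-order cumulant matrices is estimated,
#' and an orthogonal rotation jointly diagonalising them is found by Jacobi
#' sweeps. The recovered components are the maximally non-Gaussian
#' directions (in the fourth-cumulant sense). Components are canonicalised
#' deterministically: ordered by descending magnitude of excess kurtosis,
#' with sign chosen so each component's skewness is nonnegative (falling
#' back to a positive largest-magnitude score when the skewness is
#' negligible). IC scores have unit variance by construction.
#'
#' When `x` is a GPA fit, the ICA is run on the shape PC scores retaining
#' at least 99.9% of the tangent-space variance (at most `n - 1`
#' dimensions), since the tangent space itself is rank-deficient and
#' whitening requires full rank.
#'
#' With all-Gaussian inputs the rotation is unidentifiable; the
#' decomposition still returns, with a warning, when no component shows
#' appreciable excess kurtosis.
#'
#' @param x A `twv_gpa` fit, a `twv_shape_pca`, or a numeric data matrix
#'   (rows = observations).
#' @param n_components Number of components to extract (default 3).
#' @return A `twv_ica` object: list with `scores` (tibble `case_id`,
#'   `group`, `IC1`...), `unmixing` (maps the input columns to components),
#'   `kurtosis`, `order`, `signs`, `n_components`.
#' @export
#' @examples
#' set.seed(1)
#' S <- cbind(runif(300, -1, 1), sample(c(-1, 1), 300, TRUE))
#' X <- S %*% matrix(c(1, 0.6, -0.4, 1), 2, 2)
#' ica_jade(X, n_components = 2)
ica_jade <- function(x, n_components = 3) {
  ids <- NULL
  if (inherits(x, "twv_gpa")) x <- shape_pca(x)
  if (inherits(x, "twv_shape_pca")) {
    cum <- cumsum(x$percent_variance)
    m_keep <- min(which(cum >= 99.9), x$n - 1, length(x$eigenvalues))
    ids <- x$scores[, c("case_id", "group")]
    X <- as.matrix(x$scores[, paste0("PC", seq_len(m_keep)), drop = FALSE])
  } else {
    X <- as.matrix(x)
  }
  n <- nrow(X)
  if (n < 8) twv_abort("need at least 8 observations for ICA", "twv_bad_argument")
  Xc <- scale(X, center = TRUE, scale = FALSE)
  cv <- crossprod(Xc) / (n - 1)
  eg <- eigen(cv, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  if (sum(pos) < n_components) {
    twv_abort(sprintf("rank %d below the requested %d components",
                      sum(pos), n_components), "twv_rank_deficient")
  }
  m <- n_components
  W0 <- diag(1 / sqrt(eg$values[1:m]), m) %*% t(eg$vectors[, 1:m, drop = FALSE])
  Z <- Xc %*% t(W0)
  V <- .joint_diag(.cumulant_matrices(Z))
  S <- Z %*% V
  # canonicalisation: order by |excess kurtosis| descending, skewness >= 0
  kurt <- apply(S, 2, function(s) mean(s^4) / mean(s^2)^2 - 3)
  ord <- order(abs(kurt), decreasing = TRUE)
  S <- S[, ord, drop = FALSE]
  kurt <- kurt[ord]
  signs <- vapply(seq_len(m), function(j) {
    sk <- mean(S[, j]^3)
    if (abs(sk) > 1e-8) sign(sk) else sign(S[which.max(abs(S[, j])), j])
  }, numeric(1))
  signs[signs == 0] <- 1
  S <- sweep(S, 2, signs, `*`)
  W <- sweep(t(V)[ord, , drop = FALSE], 1, signs, `*`) %*% W0
  if (all(abs(kurt) < 0.5)) {
    warn("no component shows appreciable excess kurtosis; the rotation is weakly identified (near-Gaussian sources)")
  }
  # unit sample variance
  sds <- apply(S, 2, sd)
  S <- sweep(S, 2, sds, `/`)
  W <- sweep(W, 1, sds, `/`)
  colnames(S) <- paste0("IC", seq_len(m))
  score_tbl <- if (!is.null(ids)) bind_cols(ids, as_tibble(S)) else as_tibble(S)
  structure(
    list(scores = score_tbl, unmixing = W, kurtosis = kurt,
         order = ord, signs = signs, n_components = m),
    class = "twv_ica"
  )
}

#' @export
print.twv_ica <- function(x, ...) {
  cat(sprintf("<twv_ica> %d components; excess kurtosis: %s\n",
              x$n_components, paste(sprintf("%.2f", x$kurtosis), collapse = ", ")))
  invisible(x)
}
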