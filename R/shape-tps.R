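# thin-plate spline radial basis U(r) = r^2 log r (0 at r = 0)
.tps_U <- function(r) ifelse(r > 0, r^2 * log(r), 0)

# solve the TPS interpolation system for one target coordinate vector
.tps_solve <- function(src, v) {
  k <- nrow(src)
  K <- .tps_U(as.matrix(dist(src)))
  P <- cbind(1, src)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- c(v, 0, 0, 0)
  sol <- tryCatch(solve(L, rhs), error = function(e) {
    twv_abort("singular thin-plate-spline system (repeated source landmarks?)",
              "twv_tps_singular")
  })
  list(w = sol[1:k], a = sol[k + 1:3], K = K)
}

.tps_eval <- function(src, w, a, pts) {
  D <- .tps_U(outer(seq_len(nrow(pts)), seq_len(nrow(src)),
                    function(i, j) sqrt((pts[i, 1] - src[j, 1])^2 +
                                        (pts[i, 2] - src[j, 2])^2)))
  as.vector(a[1] + pts %*% a[2:3] + D %*% w)
}

#' Thin-plate-spline deformation grid between two shapes
#'
#' Fits the pair of thin-plate splines (one per coordinate) that
#' interpolate the source landmarks exactly onto the target landmarks while
#' minimising bending energy, and applies the map to a square grid laid
#' over the source shape. The returned bending energy is `W_x' K W_x +
#' W_y' K W_y` (zero exactly when the target is an affine transform of the
#' source, since the affine part carries no bending).
#'
#' @param source_shape,target_shape k x 2 matrices or tibbles with
#'   `landmark`, `x`, `y` (same landmark count and order).
#' @param grid_density Grid lines per side (default 20).
#' @param margin Fractional margin around the source bounding box (default
#'   0.15).
#' @return A `twv_tps` object: list with `grid` (tibble `row`, `col`, `x0`,
#'   `y0`, `x`, `y`), `displacements` (per-landmark source, target and
#'   arrow), `bending_energy`, and the spline coefficients.
#' @export
#' @examples
#' src <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
#' tps <- tps_grid(src, src + 0.1)     # pure translation: zero bending
#' tps$bending_energy
tps_grid <- function(source_shape, target_shape, grid_density = 20,
                     margin = 0.15) {
  if (is.data.frame(source_shape)) source_shape <- as.matrix(source_shape[, c("x", "y")])
  if (is.data.frame(target_shape)) target_shape <- as.matrix(target_shape[, c("x", "y")])
  src <- unname(as.matrix(source_shape))
  tgt <- unname(as.matrix(target_shape))
  if (!all(dim(src) == dim(tgt)) || ncol(src) != 2) {
    twv_abort("source and target must be k x 2 with matching k", "twv_bad_configs")
  }
  if (min(dist(src)) < .Machine$double.eps^0.5) {
    twv_abort("repeated source landmarks make the TPS system singular",
              "twv_tps_singular")
  }
  fx <- .tps_solve(src, tgt[, 1])
  fy <- .tps_solve(src, tgt[, 2])
  be <- as.numeric(t(fx$w) %*% fx$K %*% fx$w + t(fy$w) %*% fy$K %*% fy$w)
  rx <- range(src[, 1]); ry <- range(src[, 2])
  mx <- margin * diff(rx); my <- margin * diff(ry)
  gx <- seq(rx[1] - mx, rx[2] + mx, length.out = grid_density)
  gy <- seq(ry[1] - my, ry[2] + my, length.out = grid_density)
  g0 <- as.matrix(expand.grid(x0 = gx, y0 = gy))
  warped <- cbind(.tps_eval(src, fx$w, fx$a, g0), .tps_eval(src, fy$w, fy$a, g0))
  grid_tbl <- tibble(
    row = rep(seq_along(gy), each = length(gx)),
    col = rep(seq_along(gx), times = length(gy)),
    x0 = g0[, 1], y0 = g0[, 2],
    x = warped[, 1], y = warped[, 2]
  )
  disp <- tibble(
    landmark = rownames(source_shape) %||% as.character(seq_len(nrow(src))),
    x0 = src[, 1], y0 = src[, 2], x1 = tgt[, 1], y1 = tgt[, 2],
    dx = tgt[, 1] - src[, 1], dy = tgt[, 2] - src[, 2]
  )
  structure(
    list(grid = grid_tbl, displacements = disp, bending_energy = be,
         coefficients = list(x = fx[c("w", "a")], y = fy[c("w", "a")]),
         source = src, target = tgt, grid_density = grid_density),
    class = "twv_tps"
  )
}

#' Evaluate a fitted TPS map at new points
#'
#' @param tps A `twv_tps` from [tps_grid()].
#' @param points An m x 2 matrix of source-plane points.
#' @return An m x 2 matrix of deformed points.
#' @export
tps_transform <- function(tps, points) {
  pts <- unname(as.matrix(points))
  cbind(.tps_eval(tps$source, tps$coefficients$x$w, tps$coefficients$x$a, pts),
        .tps_eval(tps$source, tps$coefficients$y$w, tps$coefficients$y$a, pts))
}

#' @export
print.twv_tps <- function(x, ...) {
  cat(sprintf("<twv_tps> %d landmarks, bending energy %.4g\n",
              nrow(x$displacements), x$bending_energy))
  invisible(x)
}
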