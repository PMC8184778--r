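test_that("GPA is invariant under similarity transforms of its inputs", {
  ms <- template_shape()
  set.seed(6)
  arr <- array(0, dim = c(9, 2, 8))
  for (i in 1:8) {
    arr[, , i] <- similarity_transform(ms, angle = runif(1, 0, 2 * pi),
                                       scale = runif(1, 0.5, 3),
                                       shift = rnorm(2, 0, 5))
  }
  fit <- gpa(arr)
  expect_lt(max(fit$info$rho), 1e-8)
  # aligned configurations coincide to round-off
  al <- fit$aligned
  spread <- al %>% dplyr::group_by(landmark) %>%
    dplyr::summarise(sx = sd(x), sy = sd(y))
  expect_lt(max(c(spread$sx, spread$sy)), 1e-8)
})

test_that("GPA mean has unit size, zero centroid, and order invariance", {
  cfg <- two_group_configs(n_per = 6, seed = 3)
  fit <- gpa(cfg)
  expect_equal(sum(fit$mean_shape$x^2 + fit$mean_shape$y^2), 1, tolerance = 1e-10)
  expect_lt(abs(mean(fit$mean_shape$x)) + abs(mean(fit$mean_shape$y)), 1e-10)
  # permuting input order leaves the mean unchanged
  ids <- unique(cfg$case_id)
  set.seed(1)
  perm <- sample(ids)
  cfg2 <- cfg[order(match(cfg$case_id, perm)), ]
  fit2 <- gpa(cfg2)
  expect_equal(fit$mean_shape$x, fit2$mean_shape$x, tolerance = 1e-9)
  expect_equal(fit$mean_shape$y, fit2$mean_shape$y, tolerance = 1e-9)
})

test_that("pairwise Procrustes distance matches a grid-search oracle", {
  tri1 <- cbind(c(0, 1, 0), c(0, 0, 1))
  tri2 <- cbind(c(0, 1.4, -0.2), c(0, 0.2, 0.9))
  got <- procrustes_distance(tri1, tri2)
  # oracle: brute-force similarity registration of unit preshapes over a
  # refined (angle, scale) grid
  pre <- function(M) { M <- scale(M, scale = FALSE); M / sqrt(sum(M^2)) }
  z1 <- pre(tri1); z2 <- pre(tri2)
  dist_at <- function(th, b) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    sqrt(sum((z2 - b * z1 %*% t(R))^2))
  }
  best <- Inf; th0 <- pi; b0 <- 1; span_t <- pi; span_b <- 0.9
  for (ref in 1:5) {
    ths <- seq(th0 - span_t, th0 + span_t, length.out = 61)
    bs <- seq(max(0.05, b0 - span_b), b0 + span_b, length.out = 61)
    for (th in ths) for (b in bs) {
      d <- dist_at(th, b)
      if (d < best) { best <- d; th0 <- th; b0 <- b }
    }
    span_t <- span_t / 12; span_b <- span_b / 12
  }
  expect_lt(abs(got$d_full - best), 1e-4)
  expect_lt(abs(got$rho - asin(best)), 1e-4)
})

test_that("tangent coordinates are orthogonal to the similarity directions", {
  cfg <- two_group_configs(n_per = 8, seed = 5)
  fit <- gpa(cfg)
  k <- fit$k
  mu <- c(fit$mean_shape$x, fit$mean_shape$y)
  mu_rot <- c(-fit$mean_shape$y, fit$mean_shape$x)
  tx <- c(rep(1, k), rep(0, k))
  ty <- c(rep(0, k), rep(1, k))
  for (dir in list(mu, mu_rot, tx, ty)) {
    expect_lt(max(abs(fit$tangent %*% dir)), 1e-8)
  }
})

test_that("degenerate configurations are rejected", {
  arr <- array(1, dim = c(9, 2, 3))   # every point coincident
  expect_error(gpa(arr), class = "twv_degenerate_config")
  expect_error(gpa(array(rnorm(18), dim = c(9, 2, 1))), class = "twv_bad_configs")
})
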