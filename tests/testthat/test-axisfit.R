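test_that("outlier trim keeps the 1.9-sigma band", {
  expect_true(all(trim_outliers(rep(0.5, 20))))
  vals <- c(rep(0, 999), 10)
  keep <- trim_outliers(vals)
  expect_identical(which(!keep), 1000L)
  # trimmed fraction of a standard normal sample: 2 * Phi(-1.9)
  set.seed(123)
  x <- rnorm(1e5)
  frac <- mean(!trim_outliers(x))
  expect_lt(abs(frac - 2 * pnorm(-1.9)), 0.003)
  expect_error(trim_outliers(numeric(0)), "empty-cluster")
})

test_that("SVD initialization recovers centroid and dominant direction", {
  est <- initial_axis_svd(rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2)))
  expect_equal(est$n_b, c(0, 0, 1))
  expect_equal(est$p_b, c(0, 0, 1))
  est2 <- initial_axis_svd(rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(est2$p_b, c(1, 0, 0))
  u <- c(sin(10 * pi / 180), 0, cos(10 * pi / 180))
  pts <- cylinder_cloud(5000, 0.015, 0.2, u, seed = 4)
  est3 <- initial_axis_svd(pts)
  expect_lt(angle_deg(est3$n_b, u), 0.5)
  expect_error(initial_axis_svd(rbind(c(1, 1, 1), c(1, 1, 1))), "degenerate")
})

test_that("weight profile follows the parabola with shift h", {
  zeta <- seq(-0.1, 0.1, length.out = 21)
  wp <- compute_weights(zeta, z_range = c(0, 0.3), z_el_range = c(0.146, 0.154),
                        z_m = 0.15)
  expect_equal(wp$f, 0.15^2 / 4)
  h_expect <- ((0.15 - 0.146)^2 + (0.154 - 0.15)^2) / (8 * wp$f)
  expect_equal(wp$h, h_expect)
  expect_equal(wp$w[11], wp$h)                # apex value
  expect_equal(wp$w, rev(wp$w))               # even in zeta - mean(zeta)
  wp0 <- compute_weights(zeta, c(0, 0.3), c(0.15, 0.15), z_m = 0.15)
  expect_equal(wp0$h, 0)
  expect_equal(wp0$w, (zeta - mean(zeta))^2 / (4 * wp0$f))
  expect_error(compute_weights(zeta, c(0.15, 0.3), c(0.15, 0.15), 0.15),
               "geometry")
  # plane-focused profile is the reflected parabola, maximal at the apex
  wpi <- compute_weights(zeta, c(0, 0.3), c(0.146, 0.154), 0.15,
                         invert = TRUE)
  expect_equal(which.max(wpi$w), 11L)
  expect_equal(wpi$w[11], 1 + wpi$h)
})

test_that("cylinder fit recovers a noise-free shell exactly", {
  u <- c(0, 0, 1)
  # symmetric shell sampling: angular grid at evenly spaced heights
  th <- rep(2 * pi * (0:39) / 40, times = 10)
  zz <- rep(seq(-0.1, 0.1, length.out = 10), each = 40)
  pts <- cbind(0.015 * cos(th), 0.015 * sin(th), zz)
  init <- initial_axis_svd(pts)
  fit <- fit_cylinder(pts, init, weight_ctx = NULL, r0 = 0.015, z_ref = 0)
  expect_lt(angle_deg(fit$n_b, u) * pi / 180, 1e-4)
  expect_equal(fit$eps_r, 400, tolerance = 1e-6)   # unit residual per point
  # positive rescaling of r0 rescales the objective, not the argmin
  fit2 <- fit_cylinder(pts, init, weight_ctx = NULL, r0 = 0.03, z_ref = 0)
  expect_lt(sqrt(sum((fit2$p_b - fit$p_b)^2)), 1e-6)
  expect_lt(angle_deg(fit2$n_b, fit$n_b), 1e-3)
})

test_that("noisy tilted cylinders are fit within a degree of a grid oracle", {
  u <- c(sin(5 * pi / 180), 0, cos(5 * pi / 180))
  pts <- cylinder_cloud(2000, 0.015, 0.2, u, seed = 9)
  set.seed(10)
  pts <- pts * (1 + 0.05 * matrix(rnorm(length(pts)), nrow(pts)))
  init <- initial_axis_svd(pts)
  fit <- fit_cylinder(pts, init, weight_ctx = NULL, r0 = 0.015, z_ref = 0)
  expect_lt(angle_deg(fit$n_b, u), 1)
  # dense grid-search oracle over axis slopes on the same objective
  obj <- function(a, b) {
    n <- c(a, b, 1); n <- n / sqrt(sum(n^2))
    pb <- fit$p_b
    d <- sweep(pts, 2, pb)
    zeta <- as.numeric(d %*% n)
    sum(rowSums((d - outer(zeta, n))^2)) / 0.015^2
  }
  grid <- expand.grid(a = seq(-0.2, 0.2, by = 0.01),
                      b = seq(-0.2, 0.2, by = 0.01))
  vals <- mapply(obj, grid$a, grid$b)
  best <- grid[which.min(vals), ]
  n_or <- c(best$a, best$b, 1); n_or <- n_or / sqrt(sum(n_or^2))
  expect_lt(angle_deg(fit$n_b, n_or), 1)   # within the grid resolution
})

test_that("bone tilt is recovered from synthetic clusters within 0.2 degree", {
  # synthetic bone clusters: stratified grid filling the bone cylinder
  rg <- 0.015 * sqrt(seq(0.1, 1, length.out = 6))
  grid <- expand.grid(r = rg, th = 2 * pi * (0:15) / 16,
                      z = seq(-0.1, 0.1, length.out = 15))
  for (tilt in c(0, 2, 5)) {
    t <- tilt * pi / 180
    u <- c(sin(t), 0, cos(t))
    e1 <- c(cos(t), 0, -sin(t)); e2 <- c(0, 1, 0)
    pts <- outer(grid$z, u) + outer(grid$r * cos(grid$th), e1) +
      outer(grid$r * sin(grid$th), e2)
    init <- initial_axis_svd(pts)
    fit <- fit_cylinder(pts, init, weight_ctx = NULL, r0 = 0.015, z_ref = 0)
    expect_lt(angle_deg(fit$n_b, u), 0.2)
    expect_lte(fit$eps_r, fit$eps_r_initial + 1e-9)
  }
})

test_that("bone tilt from labelled phantom elements is resolution-limited", {
  # element-centroid clusters carry the labelling quantization of the mesh;
  # at this density the axis is still recovered to about a degree
  for (tilt in c(0, 5)) {
    ph <- build_phantom("cylinder", mesh_density = 0.014, length = 0.2,
                        bone_tilt_deg = tilt, outer_ring_nodes = 48L)
    ctr <- tet_centroids(ph$mesh)
    pts <- ctr[ph$tissue %in% c("bone", "marrow"), , drop = FALSE]
    fit <- fit_cylinder(pts, initial_axis_svd(pts), weight_ctx = NULL,
                        r0 = 0.015, z_ref = ph$z_m)
    expect_lt(angle_deg(fit$n_b, ph$true_axis$n), 1)
  }
})

test_that("axis estimates transform rigidly with the points", {
  u <- c(sin(0.05), 0.05, 1); u <- u / sqrt(sum(u^2))
  pts <- cylinder_cloud(1500, 0.012, 0.15, u, seed = 21)
  init <- initial_axis_svd(pts)
  f0 <- fit_cylinder(pts, init, r0 = 0.015, z_ref = 0)
  shift <- c(0.01, -0.02, 0.005)
  f1 <- fit_cylinder(sweep(pts, 2, -shift), initial_axis_svd(sweep(pts, 2, -shift)),
                     r0 = 0.015, z_ref = shift[3])
  expect_equal(f1$p_b - shift, f0$p_b, tolerance = 1e-5)
  expect_lt(angle_deg(f1$n_b, f0$n_b), 1e-3)
  th <- 0.3
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  f2 <- fit_cylinder(pts %*% t(R), initial_axis_svd(pts %*% t(R)),
                     r0 = 0.015, z_ref = 0)
  expect_lt(angle_deg(f2$n_b, as.numeric(R %*% f0$n_b)), 0.05)
})

test_that("bone-cluster selection follows extent, mean and range", {
  mk <- function(ext, mean_da, range_da) {
    list(estimate = list(zeta_extent = ext), mean_da = mean_da,
         range_da = range_da)
  }
  single <- mk(0.1, -0.1, 0.1)
  expect_identical(select_bone_cluster(list(single)), single)
  a <- mk(0.2, -0.05, 0.1); b <- mk(0.04, -0.5, 0.6)
  expect_identical(select_bone_cluster(list(b, a)), a)
  c1 <- mk(0.2, -0.30, 0.1); c2 <- mk(0.195, -0.05, 0.4)
  expect_identical(select_bone_cluster(list(c2, c1)), c1)
  expect_error(select_bone_cluster(list()), "no-bone-found")
})
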