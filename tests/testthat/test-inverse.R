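test_that("zero voltage difference reconstructs the zero field", {
  fx <- demo_fixture()
  r <- reconstruct_delta_sigma(rep(0, nrow(fx$jacobian$J)), fx$jacobian,
                               fx$phantom$mesh)
  expect_equal(r$delta_sigma, rep(0, ncol(fx$jacobian$J)))
  expect_true(r$converged)
})

test_that("penalty dominance shrinks the solution monotonically in lambda", {
  # the graph Laplacian does not penalize the constant mode, so the
  # shrinking part of the solution is its deviation from the mean
  fx <- demo_fixture()
  devn <- smooth <- numeric(0)
  L <- graph_laplacian(fx$phantom$mesh)
  for (lam in c(1e-2, 1, 100)) {
    r <- suppressWarnings(reconstruct_delta_sigma(
      fx$delta_v, fx$jacobian, fx$phantom$mesh,
      reg_config(lambda = lam, max_iter = 4000)))
    x <- r$delta_sigma
    devn <- c(devn, sqrt(sum((x - mean(x))^2)))
    smooth <- c(smooth, sum(as.numeric(L %*% x)^2))
  }
  expect_true(all(diff(devn) < 0))
  expect_true(all(diff(smooth) < 0))
  r6 <- suppressWarnings(reconstruct_delta_sigma(
    fx$delta_v, fx$jacobian, fx$phantom$mesh,
    reg_config(lambda = 1e6, max_iter = 4000)))
  x6 <- r6$delta_sigma
  expect_lt(sqrt(sum((x6 - mean(x6))^2)), 1e-4 * devn[1])
})

test_that("consistent data is recovered as the minimum-norm solution", {
  fx <- demo_fixture()
  J <- fx$jacobian$J
  ctr <- tet_centroids(fx$phantom$mesh)
  # smooth synthetic conductivity difference
  xstar <- -0.2 * exp(-((ctr[, 1] - 0.01)^2 + ctr[, 2]^2) / 0.002 -
                        (ctr[, 3] - fx$phantom$z_m)^2 / 0.004)
  dv <- as.numeric(J %*% xstar)
  r <- suppressWarnings(reconstruct_delta_sigma(
    dv, J, fx$phantom$mesh, reg_config(lambda = 1e-9, tol = 1e-12,
                                       max_iter = 5000)))
  # independent dense oracle: minimum-norm consistent solution via the
  # SVD pseudoinverse (the opposite-pair protocol drives each electrode
  # pair twice, so J is row-rank deficient; the comparison is restricted
  # to the numerically resolvable singular subspace)
  sv <- svd(J)
  pos <- sv$d > 1e-4 * sv$d[1]
  x_or <- as.numeric(sv$v[, pos] %*% (crossprod(sv$u[, pos], dv) / sv$d[pos]))
  P <- function(x) as.numeric(sv$v[, pos] %*% crossprod(sv$v[, pos], x))
  expect_lt(sqrt(sum((P(r$delta_sigma) - x_or)^2)) / sqrt(sum(x_or^2)), 1e-6)
})

test_that("returned objective never exceeds the trivial solution's", {
  fx <- demo_fixture()
  r <- suppressWarnings(reconstruct_delta_sigma(fx$delta_v, fx$jacobian,
                                                fx$phantom$mesh))
  eps0 <- reconstruction_objective(fx$delta_v, fx$jacobian,
                                   fx$phantom$mesh, rep(0, ncol(fx$jacobian$J)))
  expect_lte(r$residual_norm, eps0)
})

test_that("solution is invariant to measurement-row permutation", {
  fx <- demo_fixture()
  set.seed(3)
  perm <- sample(nrow(fx$jacobian$J))
  # compare converged solutions (truncated iterates are permutation
  # invariant only up to floating-point summation order)
  r1 <- suppressWarnings(reconstruct_delta_sigma(
    fx$delta_v, fx$jacobian$J, fx$phantom$mesh,
    reg_config(lambda = 0.1, max_iter = 4000)))
  r2 <- suppressWarnings(reconstruct_delta_sigma(
    fx$delta_v[perm], fx$jacobian$J[perm, ], fx$phantom$mesh,
    reg_config(lambda = 0.1, max_iter = 4000)))
  expect_equal(r1$delta_sigma, r2$delta_sigma, tolerance = 1e-6)
})

test_that("reconstructing the phantom's bone yields a conductivity drop", {
  fx <- demo_fixture_cfg2()
  r <- suppressWarnings(reconstruct_delta_sigma(fx$delta_v, fx$jacobian,
                                                fx$phantom$mesh))
  bone <- fx$phantom$tissue %in% c("bone", "marrow")
  expect_lt(mean(r$delta_sigma[bone]), 0)
  expect_lt(mean(r$delta_sigma[bone]),
            mean(r$delta_sigma[fx$phantom$tissue == "muscle"]))
})

test_that("dimension mismatches are reported as shape errors", {
  fx <- demo_fixture()
  expect_error(reconstruct_delta_sigma(fx$delta_v[-1], fx$jacobian,
                                       fx$phantom$mesh), "shape error")
})
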