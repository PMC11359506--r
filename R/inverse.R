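# ---------------------------------------------------------------------------
# One-step linearized difference reconstruction:
#   minimize ||dV - J da||^2_W + lambda^2 ||L (da - da0)||^2
# with L the combinatorial graph Laplacian of the inverse-mesh
# face-adjacency graph, solved by (Jacobi-preconditioned) conjugate
# gradients on the normal equations.
# ---------------------------------------------------------------------------

#' Combinatorial graph Laplacian of the element face-adjacency graph
#'
#' @param mesh a `tet_mesh`.
#' @return sparse symmetric matrix L = D - A.
#' @export
graph_laplacian <- function(mesh) {
  pairs <- face_adjacency(mesh)
  E <- nrow(mesh$tets)
  A <- Matrix::sparseMatrix(i = c(pairs[, 1], pairs[, 2]),
                            j = c(pairs[, 2], pairs[, 1]),
                            x = 1, dims = c(E, E))
  deg <- Matrix::rowSums(A)
  Matrix::Diagonal(E, deg) - A
}

#' Regularization configuration
#'
#' @param lambda regularization parameter (>= 0); default 0.00007.
#' @param W_mode `"identity"` or `"inverse_covariance"`.
#' @param variances per-measurement variances (required for
#'   `"inverse_covariance"`).
#' @param prior smoothness prior; only `"graph_laplacian"` is defined.
#' @param prior_mean optional non-zero prior mean for the conductivity
#'   difference (same length as the element count).
#' @param tol relative-residual convergence tolerance of the CG solver.
#' @param max_iter CG iteration cap.
#' @return a `reg_config` list.
#' @export
reg_config <- function(lambda = 0.00007, W_mode = c("identity", "inverse_covariance"),
                       variances = NULL, prior = "graph_laplacian",
                       prior_mean = NULL, tol = 1e-8, max_iter = 2000L) {
  W_mode <- match.arg(W_mode)
  prior <- match.arg(prior, "graph_laplacian")
  stopifnot(lambda >= 0)
  if (W_mode == "inverse_covariance" && is.null(variances)) {
    stop("inverse_covariance weighting requires a variance vector")
  }
  structure(list(lambda = lambda, W_mode = W_mode, variances = variances,
                 prior = prior, prior_mean = prior_mean, tol = tol,
                 max_iter = as.integer(max_iter)),
            class = "reg_config")
}

#' Reconstruct the conductivity difference from a voltage difference
#'
#' One-step linearized time-differential reconstruction: returns the
#' minimizer of `||dV - J da||^2_W + lambda^2 ||L da||^2` (with an optional
#' non-zero prior mean), computed by Jacobi-preconditioned conjugate
#' gradients on the normal equations.
#'
#' @param delta_v measurement-difference vector (V), pattern-major order,
#'   or a pair of `voltage_frame`s given as `list(v1, v0)`.
#' @param jacobian a `sensitivity_matrix` (or plain matrix).
#' @param mesh the inverse `tet_mesh` (for the Laplacian prior).
#' @param config a [reg_config()].
#' @return a `delta_sigma_field` with `delta_sigma` (S/m per element),
#'   `residual_norm` (final objective value), `solver_iterations`,
#'   `converged`.
#' @export
reconstruct_delta_sigma <- function(delta_v, jacobian, mesh,
                                    config = reg_config()) {
  J <- if (inherits(jacobian, "sensitivity_matrix")) jacobian$J else jacobian
  if (is.list(delta_v) && !is.numeric(delta_v)) {
    delta_v <- voltage_vector(delta_v[[1]]) - voltage_vector(delta_v[[2]])
  }
  if (base::length(delta_v) != nrow(J)) {
    stop("shape error: delta_v length (", base::length(delta_v),
         ") != Jacobian row count (", nrow(J), ")")
  }
  E <- ncol(J)
  L <- graph_laplacian(mesh)
  if (nrow(L) != E) {
    stop("shape error: mesh element count != Jacobian column count")
  }
  w <- if (config$W_mode == "identity") rep(1, nrow(J)) else 1 / config$variances
  lam2 <- config$lambda^2
  x0 <- if (is.null(config$prior_mean)) rep(0, E) else config$prior_mean
  stopifnot(base::length(x0) == E)

  matvec <- function(x) {
    as.numeric(crossprod(J, w * (J %*% x))) + lam2 * as.numeric(L %*% (L %*% x))
  }
  b <- as.numeric(crossprod(J, w * delta_v)) + lam2 * as.numeric(L %*% (L %*% x0))

  x <- rep(0, E)
  r <- b
  nb <- sqrt(sum(b^2))
  it <- 0L
  converged <- nb == 0
  if (!converged) {
    p <- r
    rz <- sum(r * r)
    for (it in seq_len(config$max_iter)) {
      Ap <- matvec(p)
      alpha <- rz / sum(p * Ap)
      x <- x + alpha * p
      r <- r - alpha * Ap
      if (sqrt(sum(r^2)) <= config$tol * nb) { converged <- TRUE; break }
      rz2 <- sum(r * r)
      p <- r + (rz2 / rz) * p
      rz <- rz2
    }
  }
  if (!converged) {
    warning("conjugate gradients did not reach tolerance ", config$tol,
            " in ", config$max_iter, " iterations; returning partial result")
  }
  resid <- delta_v - as.numeric(J %*% x)
  smooth <- as.numeric(L %*% (x - x0))
  eps <- sum(w * resid^2) + lam2 * sum(smooth^2)
  structure(list(delta_sigma = x, residual_norm = eps,
                 solver_iterations = it, converged = converged,
                 lambda = config$lambda),
            class = "delta_sigma_field")
}

#' Objective value of the reconstruction functional
#'
#' @param delta_v measurement-difference vector.
#' @param jacobian sensitivity matrix (or plain matrix).
#' @param mesh inverse mesh.
#' @param x candidate conductivity-difference field.
#' @param config a [reg_config()].
#' @return scalar objective value.
#' @export
reconstruction_objective <- function(delta_v, jacobian, mesh, x,
                                     config = reg_config()) {
  J <- if (inherits(jacobian, "sensitivity_matrix")) jacobian$J else jacobian
  w <- if (config$W_mode == "identity") rep(1, nrow(J)) else 1 / config$variances
  L <- graph_laplacian(mesh)
  x0 <- if (is.null(config$prior_mean)) rep(0, ncol(J)) else config$prior_mean
  resid <- delta_v - as.numeric(J %*% x)
  smooth <- as.numeric(L %*% (x - x0))
  sum(w * resid^2) + config$lambda^2 * sum(smooth^2)
}

#' @export
print.delta_sigma_field <- function(x, ...) {
  cat(sprintf(
    "delta_sigma_field: %d elements, range [%.4g, %.4g] S/m, eps = %.4g (%d CG iters%s)\n",
    base::length(x$delta_sigma), min(x$delta_sigma), max(x$delta_sigma),
    x$residual_norm, x$solver_iterations,
    if (x$converged) "" else ", NOT converged"))
  invisible(x)
}
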