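# ---------------------------------------------------------------------------
# Bone-axis estimation from a candidate cluster: outlier trim of the
# cluster's conductivity differences, SVD line initialization, parabolic
# off-plane weights, and a bounded quasi-Newton weighted cylinder fit.
# ---------------------------------------------------------------------------

#' Trim conductivity-difference outliers from a cluster
#'
#' Retains the elements whose value lies strictly inside
#' mean +- 1.9 standard deviations of the cluster's values.  If the values
#' have zero spread nothing is trimmed.
#'
#' @param values conductivity differences of the cluster's elements.
#' @return logical keep mask (same length as `values`).
#' @export
trim_outliers <- function(values) {
  if (base::length(values) == 0) stop("empty-cluster error: no values to trim")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) return(rep(TRUE, base::length(values)))
  m <- mean(values)
  keep <- values > m - 1.9 * s & values < m + 1.9 * s
  if (!any(keep)) stop("empty-cluster error: all elements trimmed")
  keep
}

new_axis_estimate <- function(p_b, n_b, zeta, stage, eps_r = NA_real_,
                              converged = TRUE) {
  n_b <- n_b / sqrt(sum(n_b^2))
  if (n_b[3] < 0 || (n_b[3] == 0 && any(n_b != 0) && n_b[which(n_b != 0)[1]] < 0)) {
    n_b <- -n_b
    zeta <- -zeta
  }
  structure(list(p_b = p_b, n_b = n_b, zeta = zeta,
                 zeta_extent = if (base::length(zeta)) max(zeta) - min(zeta) else 0,
                 stage = stage, eps_r = eps_r, converged = converged),
            class = "axis_estimate")
}

#' Initial axis estimate by singular value decomposition
#'
#' The centre is the centroid of the points; the axis is the right singular
#' vector of the centred point matrix with the largest singular value
#' (the cluster's direction of largest extension), sign-normalized to a
#' positive z component.
#'
#' @param points n x 3 matrix of element centre points (m).
#' @return an `axis_estimate` with `stage = "initial"`.
#' @export
initial_axis_svd <- function(points) {
  points <- as.matrix(points)
  if (nrow(unique(points)) < 2) {
    stop("degenerate-geometry error: all points identical")
  }
  p_b <- colMeans(points)
  ctr <- sweep(points, 2, p_b)
  sv <- svd(ctr, nu = 0, nv = 3)
  n_b <- sv$v[, 1]
  zeta <- as.numeric(ctr %*% n_b)
  new_axis_estimate(p_b, n_b, zeta, stage = "initial")
}

#' Parabolic off-plane weights
#'
#' Weight profile over the axial coordinates zeta: a parabola in
#' (zeta - mean zeta) with curvature set by the mesh z extent
#' (`f = min(z_m - z_min, z_max - z_m)^2 / 4`) and vertical shift set by
#' the electrode vertex heights
#' (`h = [(z_m - min z_el)^2 + (max z_el - z_m)^2] / (8 f)`).
#'
#' Two readings of the profile are provided.  The literal profile
#' `w = (zeta - mean zeta)^2 / (4 f) + h` has its apex as a minimum at the
#' electrode plane, so weight grows with distance from the plane.  The
#' plane-focused profile `w = max(0, 1 - (zeta - mean zeta)^2 / (4 f)) + h`
#' is the same parabola with its apex as a maximum at the plane, falling
#' to `h` at the nearer mesh end: it down-weights points far off the
#' electrode plane, where the reconstructed conductivity difference is
#' least reliable, and is the default used by the pipeline.
#'
#' @param zeta axial coordinates of the points along the current axis (m).
#' @param z_range mesh z extent `c(z_min, z_max)` (m).
#' @param z_el_range electrode vertex height extent `c(min, max)` (m).
#' @param z_m electrode-plane height (m).
#' @param invert FALSE for the literal profile, TRUE for the plane-focused
#'   profile.
#' @return a `weight_profile` list with `f`, `h`, `w`.
#' @export
compute_weights <- function(zeta, z_range, z_el_range, z_m, invert = FALSE) {
  f <- min(z_m - z_range[1], z_range[2] - z_m)^2 / 4
  if (f <= 0) {
    stop("geometry error: electrode plane coincides with the mesh boundary")
  }
  h <- ((z_m - z_el_range[1])^2 / (4 * f) + (z_el_range[2] - z_m)^2 / (4 * f)) / 2
  par <- (zeta - mean(zeta))^2 / (4 * f)
  w <- if (invert) pmax(0, 1 - par) + h else par + h
  structure(list(f = f, h = h, w = w, invert = invert),
            class = "weight_profile")
}

#' Weighted cylinder-axis fit
#'
#' Minimizes `eps_r = sum_i w_i^2 ||p_i - p_b - zeta_i n_b||^2 / r0^2`
#' over the axis (p_b, n_b) with L-BFGS-B, starting from the SVD estimate.
#' The axis is parameterized as `n_b = (a, b, 1)/||.||` (non-singular
#' around the near-vertical solutions) and `p_b = (px, py, z_ref)` with the
#' axial position of the centre fixed at the electrode plane, which removes
#' the gauge freedom of a line representation.  The axial coordinates zeta
#' are recomputed from the current axis at every objective evaluation; the
#' weights are frozen at the initial axis by default, because refreshing
#' them makes the objective degenerate (turning the axis perpendicular to
#' the cluster drives every zeta towards its mean, hence every weight
#' towards the small shift h, and the objective towards zero regardless of
#' fit quality).
#'
#' @param points n x 3 matrix of element centre points (m).
#' @param initial an `axis_estimate` (stage "initial").
#' @param weight_ctx NULL (unit weights), a fixed numeric weight vector, or
#'   a list `list(z_range =, z_el_range =, z_m =, invert =)` describing the
#'   parabolic profile of [compute_weights()].
#' @param r0 fitted cylinder radius (m), default 0.015.
#' @param z_ref height (m) at which `p_b` is anchored; defaults to the
#'   weight context's `z_m`, else the initial centre height.
#' @param freeze_weights keep the weights of the initial axis fixed.
#' @param slope_bound,center_bound box half-widths of the bounded optimizer
#'   around the initialization: axis slopes (dimensionless, default 0.18,
#'   about 10 degrees) and in-plane centre offsets (m, default 0.02).  The
#'   bounds keep the refinement local to the SVD initialization; without
#'   them a weighted orthogonal-distance line objective can escape to
#'   degenerate far-away configurations on near-isotropic clusters.
#' @param maxit,pgtol L-BFGS-B controls.
#' @return an `axis_estimate` with `stage = "optimal"` plus fields
#'   `eps_r_initial` and `weights`.
#' @export
fit_cylinder <- function(points, initial, weight_ctx = NULL, r0 = 0.015,
                         z_ref = NULL, freeze_weights = TRUE,
                         slope_bound = 0.18, center_bound = 0.02,
                         maxit = 500L, pgtol = 1e-9) {
  points <- as.matrix(points)
  stopifnot(nrow(points) >= 6)
  if (is.null(z_ref)) {
    z_ref <- if (is.list(weight_ctx) && !is.null(weight_ctx$z_m)) {
      weight_ctx$z_m
    } else initial$p_b[3]
  }
  invert <- is.list(weight_ctx) && isTRUE(weight_ctx$invert)

  weights_for <- function(zeta) {
    if (is.null(weight_ctx)) {
      rep(1, base::length(zeta))
    } else if (is.numeric(weight_ctx)) {
      weight_ctx
    } else {
      compute_weights(zeta, weight_ctx$z_range, weight_ctx$z_el_range,
                      weight_ctx$z_m, invert = invert)$w
    }
  }

  # anchor the initial centre on the reference plane along the initial axis
  n0 <- initial$n_b
  if (abs(n0[3]) < 1e-9) {
    stop("geometry error: initial axis parallel to the electrode plane")
  }
  p0 <- initial$p_b + (z_ref - initial$p_b[3]) / n0[3] * n0
  par0 <- c(n0[1] / n0[3], n0[2] / n0[3], p0[1], p0[2])

  frozen_w <- if (freeze_weights) weights_for(initial$zeta) else NULL

  objective <- function(par) {
    n <- c(par[1], par[2], 1)
    n <- n / sqrt(sum(n^2))
    pb <- c(par[3], par[4], z_ref)
    d <- sweep(points, 2, pb)
    zeta <- as.numeric(d %*% n)
    w <- if (freeze_weights) frozen_w else weights_for(zeta)
    res <- d - outer(zeta, n)
    sum(w^2 * rowSums(res^2)) / r0^2
  }

  eps0 <- objective(par0)
  lower <- par0 - c(slope_bound, slope_bound, center_bound, center_bound)
  upper <- par0 + c(slope_bound, slope_bound, center_bound, center_bound)
  opt <- tryCatch(
    stats::optim(par0, objective, method = "L-BFGS-B",
                 lower = lower, upper = upper,
                 control = list(maxit = maxit, pgtol = pgtol, factr = 10)),
    error = function(e) NULL
  )
  if (is.null(opt)) {
    est <- new_axis_estimate(p0, n0, initial$zeta, stage = "optimal",
                             eps_r = eps0, converged = FALSE)
    est$eps_r_initial <- eps0
    return(est)
  }
  par <- opt$par
  n <- c(par[1], par[2], 1); n <- n / sqrt(sum(n^2))
  pb <- c(par[3], par[4], z_ref)
  d <- sweep(points, 2, pb)
  zeta <- as.numeric(d %*% n)
  est <- new_axis_estimate(pb, n, zeta, stage = "optimal", eps_r = opt$value,
                           converged = TRUE)
  est$eps_r_initial <- eps0
  est$weights <- if (freeze_weights) frozen_w else weights_for(est$zeta)
  est
}

#' Select the bone cluster among fitted candidates
#'
#' Picks the candidate with the largest axial extent `zeta_extent`.  If
#' other candidates come within `rel_tol` (default 10%) of that extent, the
#' one with the lowest mean conductivity difference wins; remaining ties go
#' to the largest value range.
#'
#' @param candidates list of candidate records, each with fields `estimate`
#'   (an `axis_estimate`), `mean_da`, `range_da`.
#' @param rel_tol relative extent tolerance for the tie-break.
#' @return the chosen candidate record.
#' @export
select_bone_cluster <- function(candidates, rel_tol = 0.1) {
  if (base::length(candidates) == 0) {
    stop("no-bone-found error: no candidate clusters")
  }
  ext <- vapply(candidates, function(cc) cc$estimate$zeta_extent, 0)
  best <- max(ext)
  tied <- which(ext >= (1 - rel_tol) * best)
  if (base::length(tied) == 1L) return(candidates[[tied]])
  mda <- vapply(candidates[tied], function(cc) cc$mean_da, 0)
  lo <- which(mda == min(mda))
  if (base::length(lo) == 1L) return(candidates[[tied[lo]]])
  rng <- vapply(candidates[tied[lo]], function(cc) cc$range_da, 0)
  candidates[[tied[lo[which.max(rng)]]]]
}

#' @export
print.axis_estimate <- function(x, ...) {
  cat(sprintf(
    "axis_estimate (%s%s): p_b = (%.2f, %.2f, %.2f) mm, n_b = (%.4f, %.4f, %.4f), dzeta = %.1f mm%s\n",
    x$stage, if (x$converged) "" else ", unconverged",
    1000 * x$p_b[1], 1000 * x$p_b[2], 1000 * x$p_b[3],
    x$n_b[1], x$n_b[2], x$n_b[3], 1000 * x$zeta_extent,
    if (is.na(x$eps_r)) "" else sprintf(", eps_r = %.4g", x$eps_r)))
  invisible(x)
}

#' Broom-style tidier for axis estimates
#' @param x an `axis_estimate`.
#' @param ... unused.
#' @return one-row tibble (positions in mm).
#' @export
tidy.axis_estimate <- function(x, ...) {
  tibble::tibble(
    stage = x$stage,
    pb_x_mm = 1000 * x$p_b[1], pb_y_mm = 1000 * x$p_b[2],
    pb_z_mm = 1000 * x$p_b[3],
    nb_x = x$n_b[1], nb_y = x$n_b[2], nb_z = x$n_b[3],
    zeta_extent_mm = 1000 * x$zeta_extent,
    eps_r = x$eps_r, converged = x$converged
  )
}
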