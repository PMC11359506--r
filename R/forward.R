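# ---------------------------------------------------------------------------
# EIT forward problem: complete electrode model (CEM) on P1 tetrahedra.
#
# Unknowns are the nodal potentials plus one potential per belt electrode;
# the common-ground patch is kept at zero potential (gauge fix) and acts as
# the current return for the single-ended basis solves.  All drive and
# measurement fields are superpositions of the 16 basis solves (unit
# current into one belt electrode, returned through ground), so one sparse
# Cholesky factorization serves voltages and Jacobian alike.
# ---------------------------------------------------------------------------

# triangle areas of a face table
face_areas <- function(V, faces) {
  u <- V[faces$v2, , drop = FALSE] - V[faces$v1, , drop = FALSE]
  w <- V[faces$v3, , drop = FALSE] - V[faces$v1, , drop = FALSE]
  sqrt(rowSums(cross3(u, w)^2)) / 2
}

#' Assemble and factorize the complete-electrode-model system
#'
#' @param mesh a `tet_mesh`.
#' @param sigma per-element conductivity (S/m), all positive.
#' @param electrodes electrode list (belt electrodes + `ground`), as stored
#'   in a `thigh_phantom`.
#' @param contact_impedance electrode contact impedance (Ohm m^2);
#'   default 0.01 (100 Ohm cm^2).
#' @return a `cem_system`: factorization plus the 16 basis solutions
#'   (`W` nodal fields, `U` electrode potentials, basis j = unit current
#'   into belt electrode j, return through ground).
#' @export
cem_system <- function(mesh, sigma, electrodes, contact_impedance = 0.01) {
  if (inherits(sigma, "conductivity_field")) sigma <- sigma$sigma
  E <- nrow(mesh$tets)
  stopifnot(base::length(sigma) == E)
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("solver error: conductivity must be positive and finite everywhere")
  }
  if (!is.numeric(contact_impedance) || contact_impedance <= 0) {
    stop("parameter error: contact impedance must be positive")
  }
  n <- nrow(mesh$vertices)
  roles <- vapply(electrodes, function(e) e$role, "")
  belt <- which(roles == "belt")
  gnd <- which(roles == "ground")
  n_el <- base::length(belt)
  ndof <- n + n_el

  g <- tet_gradients(mesh)
  coef <- sigma * g$vol
  ii <- jj <- xx <- vector("list", 16L)
  k <- 0L
  G <- list(g$gx, g$gy, g$gz)
  for (a in 1:4) for (b in 1:4) {
    k <- k + 1L
    ii[[k]] <- mesh$tets[, a]
    jj[[k]] <- mesh$tets[, b]
    xx[[k]] <- coef * (g$gx[, a] * g$gx[, b] + g$gy[, a] * g$gy[, b] +
                         g$gz[, a] * g$gz[, b])
  }
  i_all <- unlist(ii); j_all <- unlist(jj); x_all <- unlist(xx)

  # electrode surface terms
  z <- contact_impedance
  for (el in seq_along(electrodes)) {
    f <- electrodes[[el]]$faces
    ar <- face_areas(mesh$vertices, f)
    vv <- cbind(f$v1, f$v2, f$v3)
    for (a in 1:3) for (b in 1:3) {
      i_all <- c(i_all, vv[, a]); j_all <- c(j_all, vv[, b])
      x_all <- c(x_all, ar / (if (a == b) 6 else 12) / z)
    }
    if (el %in% belt) {
      col <- n + match(el, belt)
      for (a in 1:3) {
        i_all <- c(i_all, vv[, a], rep(col, nrow(vv)))
        j_all <- c(j_all, rep(col, nrow(vv)), vv[, a])
        x_all <- c(x_all, rep(-ar / 3 / z, 2L))
      }
      i_all <- c(i_all, col); j_all <- c(j_all, col)
      x_all <- c(x_all, sum(ar) / z)
    }
    # ground electrode: potential fixed at 0, only the nodal block remains
  }

  A <- Matrix::sparseMatrix(i = i_all, j = j_all, x = x_all,
                            dims = c(ndof, ndof))
  A <- Matrix::forceSymmetric((A + Matrix::t(A)) / 2)
  ch <- tryCatch(Matrix::Cholesky(A, LDL = FALSE, perm = TRUE),
                 error = function(e) stop("solver error: ", conditionMessage(e)))
  B <- matrix(0, ndof, n_el)
  B[cbind(n + seq_len(n_el), seq_len(n_el))] <- 1
  sol <- as.matrix(Matrix::solve(ch, B))
  structure(list(
    W = sol[seq_len(n), , drop = FALSE],
    U = sol[n + seq_len(n_el), , drop = FALSE],
    n_nodes = n, n_el = n_el, contact_impedance = contact_impedance,
    mesh = mesh, sigma = sigma, gradients = g
  ), class = "cem_system")
}

#' Solve the EIT forward problem
#'
#' Simulates the differential electrode voltages of a stimulation protocol
#' on a phantom (or on a raw mesh + electrode list) for a given
#' conductivity field.
#'
#' @param phantom a `thigh_phantom`, or a `tet_mesh` (then `electrodes`
#'   must be given).
#' @param sigma a `conductivity_field` or numeric per-element vector (S/m).
#' @param protocol a `stim_protocol`.
#' @param contact_impedance electrode contact impedance (Ohm m^2).
#' @param provenance provenance tag stored with the frame.
#' @param system optional precomputed [cem_system()] (avoids refactorizing).
#' @param electrodes electrode list when `phantom` is a raw mesh.
#' @return a `voltage_frame`: `voltages` (pattern x measurement matrix, V),
#'   the protocol, and the per-pattern electrode potentials `U_pattern`.
#' @export
solve_forward <- function(phantom, sigma, protocol,
                          contact_impedance = 0.01,
                          provenance = "simulated", system = NULL,
                          electrodes = NULL) {
  if (inherits(phantom, "thigh_phantom")) {
    mesh <- phantom$mesh
    electrodes <- phantom$electrodes
  } else {
    mesh <- phantom
    if (is.null(electrodes)) stop("electrodes must be supplied with a raw mesh")
  }
  if (is.null(system)) {
    system <- cem_system(mesh, sigma, electrodes, contact_impedance)
  }
  if (protocol$n_electrodes != system$n_el) {
    stop("protocol electrode count does not match the mesh electrodes")
  }
  P <- nrow(protocol$patterns)
  U <- system$U
  Upat <- matrix(0, P, system$n_el)
  for (p in seq_len(P)) {
    Upat[p, ] <- protocol$patterns$amplitude[p] *
      (U[, protocol$patterns$src[p]] - U[, protocol$patterns$snk[p]])
  }
  mm <- protocol$measurements
  Mn <- max(mm$meas)
  volt <- matrix(NA_real_, P, Mn)
  volt[cbind(mm$pattern, mm$meas)] <-
    Upat[cbind(mm$pattern, mm$e_pos)] - Upat[cbind(mm$pattern, mm$e_neg)]
  structure(list(voltages = volt, protocol = protocol,
                 provenance = provenance, U_pattern = Upat),
            class = "voltage_frame")
}

#' Flatten a voltage frame to the canonical measurement vector
#'
#' Pattern-major, measurement-minor ordering (the row order of
#' `protocol$measurements`), matching the Jacobian row ordering.
#'
#' @param vf a `voltage_frame`.
#' @return numeric vector of length `nrow(protocol$measurements)`.
#' @export
voltage_vector <- function(vf) {
  mm <- vf$protocol$measurements
  vf$voltages[cbind(mm$pattern, mm$meas)]
}

#' @export
print.voltage_frame <- function(x, ...) {
  v <- voltage_vector(x)
  cat(sprintf("voltage_frame (%s): %d patterns x %d measurements, |V| in [%.3g, %.3g] V\n",
              x$provenance, nrow(x$voltages), ncol(x$voltages),
              min(abs(v)), max(abs(v))))
  invisible(x)
}

#' @method as_tibble voltage_frame
#' @export
as_tibble.voltage_frame <- function(x, ...) {
  mm <- x$protocol$measurements
  dplyr::mutate(mm, volts = x$voltages[cbind(mm$pattern, mm$meas)])
}

#' Sensitivity (Jacobian) matrix by the adjoint-field method
#'
#' Column e approximates the derivative of the flattened measurement vector
#' with respect to the conductivity of element e, evaluated at `sigma0`:
#' `J[m, e] = -vol_e * grad(u_drive) . grad(u_meas)` with the measurement
#' field driven by a unit current through the measurement pair.
#'
#' @param mesh the inverse-problem `tet_mesh` (or a `thigh_phantom`).
#' @param sigma0 reference conductivity field on that mesh.
#' @param protocol a `stim_protocol`.
#' @param contact_impedance electrode contact impedance (Ohm m^2).
#' @param system optional precomputed [cem_system()] at `sigma0`.
#' @param electrodes electrode list when `mesh` is a raw mesh.
#' @return a `sensitivity_matrix`: `J` ((measurements) x (elements)),
#'   plus protocol and reference metadata.
#' @export
compute_jacobian <- function(mesh, sigma0, protocol,
                             contact_impedance = 0.01, system = NULL,
                             electrodes = NULL) {
  if (inherits(mesh, "thigh_phantom")) {
    electrodes <- mesh$electrodes
    mesh <- mesh$mesh
  }
  if (is.null(system)) {
    system <- cem_system(mesh, sigma0, electrodes, contact_impedance)
  }
  g <- system$gradients
  W <- system$W
  Tt <- mesh$tets
  E <- nrow(Tt)
  nb <- system$n_el
  Bx <- matrix(0, E, nb); By <- matrix(0, E, nb); Bz <- matrix(0, E, nb)
  for (jb in seq_len(nb)) {
    wv <- W[, jb]
    w4 <- cbind(wv[Tt[, 1]], wv[Tt[, 2]], wv[Tt[, 3]], wv[Tt[, 4]])
    Bx[, jb] <- rowSums(g$gx * w4)
    By[, jb] <- rowSums(g$gy * w4)
    Bz[, jb] <- rowSums(g$gz * w4)
  }
  mm <- protocol$measurements
  pat <- protocol$patterns
  M <- nrow(mm)
  J <- matrix(0, M, E)
  vol <- g$vol
  for (p in seq_len(nrow(pat))) {
    amp <- pat$amplitude[p]
    dx <- amp * (Bx[, pat$src[p]] - Bx[, pat$snk[p]])
    dy <- amp * (By[, pat$src[p]] - By[, pat$snk[p]])
    dz <- amp * (Bz[, pat$src[p]] - Bz[, pat$snk[p]])
    rows <- which(mm$pattern == p)
    for (r in rows) {
      a <- mm$e_pos[r]; b <- mm$e_neg[r]
      J[r, ] <- -vol * (dx * (Bx[, a] - Bx[, b]) +
                          dy * (By[, a] - By[, b]) +
                          dz * (Bz[, a] - Bz[, b]))
    }
  }
  structure(list(J = J, protocol = protocol,
                 contact_impedance = system$contact_impedance,
                 n_elements = E),
            class = "sensitivity_matrix")
}

#' @export
print.sensitivity_matrix <- function(x, ...) {
  cat(sprintf("sensitivity_matrix: %d measurements x %d elements\n",
              nrow(x$J), ncol(x$J)))
  invisible(x)
}
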