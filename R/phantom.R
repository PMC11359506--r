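# ---------------------------------------------------------------------------
# Thigh phantoms: structured tet meshes with skin / subcutaneous fat /
# muscle / intramuscular fat / cortical bone / marrow compartments, a
# 16-electrode belt at the mid-plane, and an analytic ground-truth
# marrow-centre axis.  All geometry in SI metres; reporting in mm/degrees.
# ---------------------------------------------------------------------------

#' Default deformation parameters for the realistic cross-section phantom
#'
#' The realistic phantom is produced by a smooth planar map applied to the
#' cylinder phantom: anisotropic scaling plus low-order harmonic radial
#' perturbations whose amplitude grows as (r/R)^2, so the outer boundary is
#' strongly reshaped while the bone region deforms almost linearly.
#'
#' @param scale x/y scale factors.
#' @param amp harmonic amplitudes (relative radius perturbation at r = R).
#' @param order angular orders of the harmonics.
#' @param phase phase angles (radians); if NULL they are drawn from `seed`.
#' @param shift lateral interior shift (m): applied with weight
#'   `1 - (r/R)^2`, so the outer boundary stays put while the bone region
#'   is displaced off-centre (mimicking the off-axis femur of a real thigh).
#' @param seed integer seed used when `phase` is NULL.
#' @return list of deformation parameters.
#' @export
deform_params <- function(scale = c(1.25, 0.85), amp = c(0.08, 0.05),
                          order = c(2L, 3L), phase = NULL,
                          shift = c(0.012, 0.004), seed = 1L) {
  if (is.null(phase)) {
    set.seed(seed)
    phase <- runif(length(order), 0, 2 * pi)
  }
  list(scale = scale, amp = amp, order = order, phase = phase, shift = shift)
}

# alias usable where an argument named `deform_params` shadows the function
default_deform_params <- deform_params

# planar deformation map; xy is an n x 2 matrix, R0 the undeformed outer radius
apply_deformation <- function(xy, dp, R0) {
  if (is.null(dp)) return(xy)
  r <- sqrt(xy[, 1]^2 + xy[, 2]^2)
  th <- atan2(xy[, 2], xy[, 1])
  fac <- rep(1, nrow(xy))
  for (j in seq_along(dp$order)) {
    fac <- fac + (r / R0)^2 * dp$amp[j] * cos(dp$order[j] * th + dp$phase[j])
  }
  sh <- if (is.null(dp$shift)) c(0, 0) else dp$shift
  wgt <- pmax(0, 1 - (r / R0)^2)
  cbind(xy[, 1] * fac * dp$scale[1] + wgt * sh[1],
        xy[, 2] * fac * dp$scale[2] + wgt * sh[2])
}

# perpendicular distance from points (n x 3) to the line o + s*n_unit
dist_to_line <- function(p, o, n_unit) {
  d <- sweep(p, 2, o)
  s <- d %*% n_unit
  res <- d - outer(as.vector(s), as.vector(n_unit))
  sqrt(rowSums(res^2))
}

# total-least-squares line through points: list(o = point at z = z0, n = unit)
fit_line_svd <- function(p, z0 = NULL) {
  ctr <- colMeans(p)
  sv <- svd(sweep(p, 2, ctr), nu = 0, nv = 3)
  n <- sv$v[, 1]
  if (n[3] < 0) n <- -n
  o <- ctr
  if (!is.null(z0) && abs(n[3]) > 1e-12) o <- ctr + (z0 - ctr[3]) / n[3] * n
  list(o = o, n = n)
}

#' Build a tetrahedral thigh phantom
#'
#' Generates a conforming tetrahedral mesh of a thigh (a cylinder, or a
#' cylinder put through a smooth planar deformation for the realistic
#' cross-section), labels every element with a tissue, places a belt of
#' equi-angular surface electrodes at the electrode plane `z_m = length/2`
#' plus a common-ground patch, and records the ground-truth marrow-centre
#' axis.
#'
#' @param shape `"cylinder"` or `"realistic"`.
#' @param outer_radius,bone_radius,marrow_radius radii in metres.
#' @param length thigh length (m); z runs from 0 to `length`.
#' @param bone_offset length-2 xy offset (m) of the bone axis at the
#'   electrode plane.
#' @param bone_tilt_deg tilt of the bone axis about the y axis (degrees).
#' @param mesh_density target element size h (m); smaller is finer.
#' @param deform_params deformation parameters (see [deform_params()]);
#'   only used for `shape = "realistic"` (defaults drawn from `seed`).
#' @param seed integer seed for the deformation phases and the
#'   intramuscular-fat inclusions.
#' @param skin_thickness,fat_thickness shell thicknesses (m).
#' @param n_electrodes number of belt electrodes (16).
#' @param electrode_diameter electrode diameter (m), 7 mm.
#' @param intra_fat include seeded ellipsoidal intramuscular-fat inclusions;
#'   defaults to TRUE for the realistic shape.
#' @param outer_ring_nodes boundary-ring node count (fixed independently of
#'   `mesh_density` so different-density meshes of the same geometry carry
#'   identical electrode patches).
#' @param belt_hz,belt_halfwidth z-layer spacing (m) and half-width (m) of
#'   the refined band around the electrode plane (fixed for the same reason).
#' @param hz_max cap on the z-layer spacing away from the belt (m); fixed
#'   independently of `mesh_density` so all meshes share one z grid and the
#'   thin skin/fat shells are discretized identically everywhere.
#' @return a `thigh_phantom` object.
#' @export
build_phantom <- function(shape = c("cylinder", "realistic"),
                          outer_radius = 0.07, bone_radius = 0.015,
                          marrow_radius = 0.007, length = 0.3,
                          bone_offset = c(0, 0),
                          bone_tilt_deg = if (match.arg(shape) == "realistic") 2 else 0,
                          mesh_density = 0.009, deform_params = NULL,
                          seed = 1L, skin_thickness = 0.002,
                          fat_thickness = 0.008, n_electrodes = 16L,
                          electrode_diameter = 0.007,
                          intra_fat = NULL, outer_ring_nodes = 64L,
                          belt_hz = 0.0045, belt_halfwidth = 0.018,
                          hz_max = 0.024) {
  shape <- match.arg(shape)
  stopifnot(0 < marrow_radius, marrow_radius < bone_radius,
            bone_radius < outer_radius, length > 0)
  if (is.null(intra_fat)) intra_fat <- (shape == "realistic")
  z_m <- length / 2
  tilt <- bone_tilt_deg * pi / 180
  n_ax <- c(sin(tilt), 0, cos(tilt))
  o_ax <- c(bone_offset[1], bone_offset[2], z_m)

  # bone must stay inside the outer surface along the whole length
  excur <- max(abs(c(0, length) - z_m)) * abs(tan(tilt))
  if (sqrt(sum(bone_offset^2)) + excur + bone_radius >=
      outer_radius - skin_thickness - fat_thickness) {
    stop("infeasible geometry: bone axis leaves the muscle compartment ",
         "within the modelled length")
  }

  fat_inner <- outer_radius - skin_thickness - fat_thickness
  skin_inner <- outer_radius - skin_thickness
  # the electrode-zone discretization (outer-ring node count, belt z
  # layers) is fixed independently of the interior density so that every
  # mesh of the same geometry carries identical electrode patches
  mesh <- cylinder_mesh(
    boundary_radii = c(fat_inner, skin_inner, outer_radius),
    length = length, z_m = z_m, h = mesh_density,
    hz_fine = belt_hz, hz_max = hz_max,
    fine_halfwidth = belt_halfwidth,
    n_electrodes = n_electrodes,
    outer_ring_nodes = outer_ring_nodes
  )

  ctr <- tet_centroids(mesh)
  r <- sqrt(ctr[, 1]^2 + ctr[, 2]^2)
  tissue <- rep("muscle", nrow(mesh$tets))
  tissue[r > fat_inner] <- "fat_subcut"
  tissue[r > skin_inner] <- "skin"
  db <- dist_to_line(ctr, o_ax, n_ax)
  inside_shells <- r <= fat_inner
  tissue[inside_shells & db <= bone_radius] <- "bone"
  tissue[inside_shells & db <= marrow_radius] <- "marrow"

  if (intra_fat) {
    set.seed(seed + 1000L)
    n_inc <- 3L
    ang <- runif(n_inc, 0, 2 * pi)
    rad <- runif(n_inc, 0.42, 0.62) * fat_inner
    zc <- runif(n_inc, 0.3, 0.7) * length
    ax <- cbind(runif(n_inc, 0.005, 0.007), runif(n_inc, 0.004, 0.006),
                runif(n_inc, 0.03, 0.05))
    for (j in seq_len(n_inc)) {
      cx <- rad[j] * cos(ang[j]); cy <- rad[j] * sin(ang[j])
      q <- ((ctr[, 1] - cx) / ax[j, 1])^2 + ((ctr[, 2] - cy) / ax[j, 2])^2 +
        ((ctr[, 3] - zc[j]) / ax[j, 3])^2
      tissue[q < 1 & tissue == "muscle"] <- "fat_intra"
    }
  }

  # electrodes: selected on the undeformed cylinder surface
  electrodes <- place_electrodes(mesh, outer_radius, z_m, n_electrodes,
                                 electrode_diameter)

  dp <- NULL
  if (shape == "realistic") {
    dp <- if (is.null(deform_params)) {
      default_deform_params(seed = seed)
    } else deform_params
    mesh$vertices[, 1:2] <- apply_deformation(mesh$vertices[, 1:2, drop = FALSE],
                                              dp, outer_radius)
    for (el in seq_along(electrodes)) {
      nd <- electrodes[[el]]$nodes
      electrodes[[el]]$center <- colMeans(mesh$vertices[nd, , drop = FALSE])
    }
    # ground-truth marrow axis after deformation: map the analytic axis and
    # refit a straight line (the map is nearly linear over the bone region)
    zs <- seq(0, length, length.out = 101)
    axis_pts <- cbind(o_ax[1] + (zs - z_m) * n_ax[1] / n_ax[3],
                      o_ax[2] + (zs - z_m) * n_ax[2] / n_ax[3])
    mapped <- apply_deformation(axis_pts, dp, outer_radius)
    truth <- fit_line_svd(cbind(mapped, zs), z0 = z_m)
  } else {
    truth <- list(o = o_ax, n = n_ax)
  }

  structure(list(
    mesh = mesh, tissue = tissue, electrodes = electrodes,
    z_m = z_m, true_axis = truth, shape = shape,
    params = list(outer_radius = outer_radius, bone_radius = bone_radius,
                  marrow_radius = marrow_radius, length = length,
                  bone_offset = bone_offset, bone_tilt_deg = bone_tilt_deg,
                  mesh_density = mesh_density, skin_thickness = skin_thickness,
                  fat_thickness = fat_thickness, n_electrodes = n_electrodes,
                  electrode_diameter = electrode_diameter,
                  deform = dp, seed = seed, intra_fat = intra_fat)
  ), class = "thigh_phantom")
}

# Select boundary faces for each belt electrode (and the common ground
# patch) on the undeformed cylinder surface.  Each electrode patch is the
# set of lateral faces spanned by a 3 x 3 node block (ring position +-1,
# z layer +-1) centred on the boundary node nearest the electrode centre,
# which keeps patches symmetric about the electrode plane.  The nominal
# 7 mm diameter is stored as metadata; the modelled patch size is limited
# by the surface mesh resolution.
place_electrodes <- function(mesh, outer_radius, z_m, n_electrodes,
                             electrode_diameter) {
  bf <- boundary_faces(mesh)
  V <- mesh$vertices
  orn <- mesh$outer_ring_nodes            # layer x ring position
  nl <- nrow(orn); nr <- ncol(orn)
  lateral_nodes <- unique(as.vector(orn))
  is_lat <- logical(nrow(V)); is_lat[lateral_nodes] <- TRUE
  on_lat <- is_lat[bf$v1] & is_lat[bf$v2] & is_lat[bf$v3]
  lat <- bf[on_lat, , drop = FALSE]
  ang <- mesh$outer_ang
  layer_m <- which.min(abs(mesh$z_levels - z_m))

  pick_patch <- function(theta0, layer0) {
    ip <- which.min(abs(((ang - theta0 + pi) %% (2 * pi)) - pi))
    cols <- ((ip - 1L) + c(-1L, 0L, 1L)) %% nr + 1L
    rows <- pmin(pmax(layer0 + c(-1L, 0L, 1L), 1L), nl)
    block <- as.vector(orn[rows, cols])
    inb <- logical(nrow(V)); inb[block] <- TRUE
    which(inb[lat$v1] & inb[lat$v2] & inb[lat$v3])
  }

  electrodes <- vector("list", n_electrodes + 1L)
  for (i in seq_len(n_electrodes)) {
    theta0 <- 2 * pi * (i - 1L) / n_electrodes
    faces <- lat[pick_patch(theta0, layer_m), , drop = FALSE]
    nodes <- sort(unique(c(faces$v1, faces$v2, faces$v3)))
    electrodes[[i]] <- list(
      nodes = nodes, faces = faces,
      center = c(outer_radius * cos(theta0), outer_radius * sin(theta0), z_m),
      diameter = electrode_diameter, role = "belt"
    )
  }
  # common ground: lateral patch between electrodes 1 and 2, well below the belt
  theta_g <- pi / n_electrodes
  z_g <- max(min(mesh$z_levels) + 0.03, z_m - 0.1)
  layer_g <- which.min(abs(mesh$z_levels - z_g))
  faces <- lat[pick_patch(theta_g, layer_g), , drop = FALSE]
  electrodes[[n_electrodes + 1L]] <- list(
    nodes = sort(unique(c(faces$v1, faces$v2, faces$v3))), faces = faces,
    center = c(outer_radius * cos(theta_g), outer_radius * sin(theta_g),
               mesh$z_levels[layer_g]),
    diameter = electrode_diameter, role = "ground"
  )
  names(electrodes) <- c(paste0("E", seq_len(n_electrodes)), "ground")
  electrodes
}

#' Assign reference (all-tissue) conductivities to a phantom
#'
#' The reference field drives the simulated measurement state: every
#' compartment carries its tabulated 100 kHz conductivity
#' (skin 0.065, fat 0.03, muscle 0.37, cortical bone 0.02, marrow 0.002 S/m).
#'
#' @param phantom a `thigh_phantom`.
#' @param config reference-model configuration tag stored with the field
#'   (`"cfg1_homogeneous"`, `"cfg2_skin_fat"`, `"cfg3_skin_fat_intra"`;
#'   prefixes allowed).
#' @param frequency excitation frequency (Hz); only 100 kHz is tabulated.
#' @return a `conductivity_field` (numeric sigma per element + metadata).
#' @export
assign_conductivities <- function(phantom, config = "cfg1_homogeneous",
                                  frequency = 1e5) {
  config <- match.arg(config, CONFIGS)
  if (!isTRUE(all.equal(frequency, 1e5))) {
    stop("unsupported frequency: conductivities are tabulated at 100 kHz only")
  }
  unknown <- setdiff(unique(phantom$tissue), TISSUES)
  if (base::length(unknown) > 0) {
    stop("unknown tissue label(s): ", paste(unknown, collapse = ", "))
  }
  sigma <- unname(TISSUE_SIGMA[phantom$tissue])
  structure(list(sigma = sigma, config = config, frequency = frequency,
                 reference = TRUE),
            class = "conductivity_field")
}

#' Boneless reference conductivity field
#'
#' Builds the conductivity distribution of the digital boneless thigh used
#' to simulate the reference state: bone and marrow are always replaced by
#' muscle; which of the remaining tissues keep their tabulated values
#' depends on the configuration (cfg1 = fully homogeneous muscle; cfg2
#' keeps skin + subcutaneous fat; cfg3 additionally keeps intramuscular fat).
#'
#' @inheritParams assign_conductivities
#' @return a `conductivity_field`.
#' @export
make_boneless <- function(phantom, config = "cfg1_homogeneous",
                          frequency = 1e5) {
  config <- match.arg(config, CONFIGS)
  unknown <- setdiff(unique(phantom$tissue), TISSUES)
  if (base::length(unknown) > 0) {
    stop("unknown tissue label(s): ", paste(unknown, collapse = ", "))
  }
  keep <- switch(config,
    cfg1_homogeneous = character(0),
    cfg2_skin_fat = c("skin", "fat_subcut"),
    cfg3_skin_fat_intra = c("skin", "fat_subcut", "fat_intra")
  )
  sigma <- rep(unname(TISSUE_SIGMA["muscle"]), base::length(phantom$tissue))
  for (t in keep) sigma[phantom$tissue == t] <- unname(TISSUE_SIGMA[t])
  structure(list(sigma = sigma, config = config, frequency = frequency,
                 reference = FALSE),
            class = "conductivity_field")
}

#' Mean edge length of a mesh
#' @param mesh a `tet_mesh`.
#' @return mean tet edge length (m).
#' @export
mean_edge_length <- function(mesh) {
  T <- mesh$tets; V <- mesh$vertices
  pairs <- rbind(T[, c(1, 2)], T[, c(1, 3)], T[, c(1, 4)],
                 T[, c(2, 3)], T[, c(2, 4)], T[, c(3, 4)])
  d <- V[pairs[, 1], , drop = FALSE] - V[pairs[, 2], , drop = FALSE]
  mean(sqrt(rowSums(d^2)))
}

#' @export
print.thigh_phantom <- function(x, ...) {
  cat(sprintf("thigh_phantom (%s): %d tets, %d vertices\n", x$shape,
              nrow(x$mesh$tets), nrow(x$mesh$vertices)))
  tt <- table(x$tissue)
  cat("  tissues:", paste(sprintf("%s=%d", names(tt), tt), collapse = ", "), "\n")
  cat(sprintf("  electrodes: %d + ground, plane z_m = %.0f mm\n",
              x$params$n_electrodes, 1000 * x$z_m))
  cat(sprintf("  true axis: o_m = (%.1f, %.1f, %.1f) mm, n_f = (%.4f, %.4f, %.4f)\n",
              1000 * x$true_axis$o[1], 1000 * x$true_axis$o[2],
              1000 * x$true_axis$o[3],
              x$true_axis$n[1], x$true_axis$n[2], x$true_axis$n[3]))
  invisible(x)
}

#' @export
print.conductivity_field <- function(x, ...) {
  cat(sprintf("conductivity_field (%s, %s): %d elements, sigma in [%g, %g] S/m\n",
              x$config, if (x$reference) "reference/all tissues" else "boneless",
              base::length(x$sigma), min(x$sigma), max(x$sigma)))
  invisible(x)
}
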