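# ---------------------------------------------------------------------------
# End-to-end orchestration: phantom -> reference forward solve (V1, fine
# mesh, all tissues) -> boneless forward solve + Jacobian (V0, independent
# coarser inverse mesh) -> difference reconstruction -> segmentation ->
# axis fit -> deviation against the ground-truth marrow-centre axis.
# ---------------------------------------------------------------------------

#' Positional and angular deviation of an axis estimate
#'
#' Positional deviation is the Euclidean distance, inside the electrode
#' plane z = z_m, between the intersection points of the two axes with
#' that plane; the angular deviation is `acos(|<n_b, n_f>|)` folded to
#' [0, 90] degrees.  The 3D distance from the truth's plane point to the
#' estimated line is also reported.
#'
#' @param estimate an `axis_estimate` (or any list with `p_b`, `n_b`).
#' @param truth ground-truth axis `list(o =, n =)` (marrow-centre line).
#' @param z_m electrode-plane height (m).
#' @return list with `delta_p_mm`, `phi_deg`, `delta_p3d_mm`.
#' @export
compute_deviation <- function(estimate, truth, z_m) {
  plane_point <- function(p, n) {
    if (abs(n[3]) < 1e-9) {
      stop("geometry error: axis parallel to the electrode plane")
    }
    p + (z_m - p[3]) / n[3] * n
  }
  pe <- plane_point(estimate$p_b, estimate$n_b)
  pt <- plane_point(truth$o, truth$n)
  delta_p <- sqrt(sum((pe[1:2] - pt[1:2])^2))
  cosang <- abs(sum(estimate$n_b * truth$n)) /
    sqrt(sum(estimate$n_b^2) * sum(truth$n^2))
  phi <- acos(pmin(1, cosang)) * 180 / pi
  d <- pt - estimate$p_b
  nb <- estimate$n_b / sqrt(sum(estimate$n_b^2))
  d3 <- sqrt(sum((d - sum(d * nb) * nb)^2))
  list(delta_p_mm = 1000 * delta_p, phi_deg = phi, delta_p3d_mm = 1000 * d3)
}

#' Segment a reconstruction and fit axis candidates
#'
#' Runs the bin partition, region growing and cluster filtering, then for
#' every surviving cluster (ascending size) trims outliers, computes the
#' SVD initialization and the weighted cylinder fit, and finally selects
#' the bone cluster by the largest-axial-extent heuristic.
#'
#' @param delta_sigma a `delta_sigma_field` (or numeric vector).
#' @param mesh the inverse `tet_mesh`.
#' @param electrodes electrode list of the inverse mesh.
#' @param z_m electrode-plane height (m).
#' @param seg_options [segmentation_options()].
#' @param r0 cylinder-fit radius (m).
#' @param invert_weights use the plane-focused weight profile (default);
#'   FALSE selects the literal parabola (see [compute_weights()]).
#' @param rel_tol extent tie-break tolerance of [select_bone_cluster()].
#' @return list with `chosen`, `candidates`, `partition`, `clusters`.
#' @export
estimate_axes <- function(delta_sigma, mesh, electrodes, z_m,
                          seg_options = segmentation_options(), r0 = 0.015,
                          invert_weights = TRUE, rel_tol = 0.1) {
  ds <- if (inherits(delta_sigma, "delta_sigma_field")) delta_sigma$delta_sigma else delta_sigma
  partition <- compute_bin_partition(ds, mesh, electrodes, seg_options)
  clusters <- filter_clusters(grow_clusters(partition, mesh), mesh,
                              electrodes, seg_options)
  if (base::length(clusters) == 0) {
    stop("no-bone-found error: no cluster survives the discard rules")
  }
  ctr <- tet_centroids(mesh)
  belt <- Filter(function(e) e$role == "belt", electrodes)
  z_el <- range(mesh$vertices[unique(unlist(lapply(belt, `[[`, "nodes"))), 3])
  wctx <- list(z_range = range(mesh$vertices[, 3]), z_el_range = z_el,
               z_m = z_m, invert = invert_weights)
  candidates <- list()
  for (cl in clusters) {
    vals <- ds[cl$element_ids]
    keep <- tryCatch(trim_outliers(vals), error = function(e) NULL)
    if (is.null(keep)) next
    ids <- cl$element_ids[keep]
    if (base::length(ids) < 6) next
    pts <- ctr[ids, , drop = FALSE]
    init <- tryCatch(initial_axis_svd(pts), error = function(e) NULL)
    if (is.null(init)) next
    opt <- fit_cylinder(pts, init, weight_ctx = wctx, r0 = r0)
    candidates[[base::length(candidates) + 1L]] <- list(
      estimate = opt, initial = init, element_ids = ids,
      size = cl$size, mean_da = mean(vals[keep]),
      range_da = max(vals[keep]) - min(vals[keep]),
      touches_surface = cl$touches_surface,
      touches_electrode = cl$touches_electrode
    )
  }
  if (base::length(candidates) == 0) {
    stop("no-bone-found error: no cluster yields a valid axis fit")
  }
  chosen <- select_bone_cluster(candidates, rel_tol = rel_tol)
  list(chosen = chosen, candidates = candidates, partition = partition,
       clusters = clusters)
}

#' Pipeline configuration
#'
#' Collects every tunable of an end-to-end run with the study defaults:
#' 16 electrodes, opposite-pair 10 mA drive at 100 kHz, lambda = 0.00007,
#' tabulated 100 kHz tissue conductivities, a finer simulation mesh and an
#' independently generated coarser inverse mesh.
#'
#' @param shape `"cylinder"` or `"realistic"`.
#' @param config boneless reference configuration (see [make_boneless()]).
#' @param fine_density,inverse_density target element sizes (m) of the
#'   simulation and inverse meshes.
#' @param lambda regularization parameter.
#' @param seed integer seed (deformation phases, fat inclusions).
#' @param amplitude,frequency drive current (A) and frequency (Hz).
#' @param contact_impedance electrode contact impedance (Ohm m^2).
#' @param invert_weights use the plane-focused cylinder-fit weight profile
#'   (default); FALSE selects the literal parabola, whose weight grows with
#'   distance from the electrode plane (see [compute_weights()]).
#' @param bone_offset,bone_tilt_deg bone-axis placement (m, degrees).
#' @param r0 cylinder-fit radius (m).
#' @param seg_options [segmentation_options()].
#' @param keep_intermediates retain meshes, Jacobian and reconstruction in
#'   the run result.
#' @param phantom_args extra arguments passed to [build_phantom()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(shape = "cylinder", config = "cfg1_homogeneous",
                            fine_density = 0.011, inverse_density = 0.013,
                            lambda = 0.00007, seed = 1L, amplitude = 10e-3,
                            frequency = 1e5, contact_impedance = 0.01,
                            invert_weights = TRUE, bone_offset = NULL,
                            bone_tilt_deg = NULL, r0 = 0.015,
                            seg_options = segmentation_options(),
                            keep_intermediates = FALSE,
                            phantom_args = list()) {
  config <- match.arg(config, CONFIGS)
  shape <- match.arg(shape, c("cylinder", "realistic"))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full localization pipeline
#'
#' @param cfg a [pipeline_config()].
#' @param shared optional list of precomputed stages shared between
#'   configurations of the same shape (fields `fine`, `v1`, `inverse`),
#'   as produced by a previous run's `$shared`.
#' @return a `deit_run`: `report` (one-row tibble with initial/optimal
#'   positional and angular deviations), `chosen`, `candidates`, `truth`,
#'   `shared`, and (optionally) intermediates.
#' @export
run_pipeline <- function(cfg = pipeline_config(), shared = NULL) {
  protocol <- build_protocol(amplitude = cfg$amplitude,
                             frequency = cfg$frequency)
  if (is.null(shared)) shared <- list()
  bone_args <- list()
  if (!is.null(cfg$bone_offset)) bone_args$bone_offset <- cfg$bone_offset
  if (!is.null(cfg$bone_tilt_deg)) bone_args$bone_tilt_deg <- cfg$bone_tilt_deg
  if (is.null(shared$fine)) {
    shared$fine <- do.call(build_phantom, c(list(
      shape = cfg$shape, mesh_density = cfg$fine_density, seed = cfg$seed
    ), bone_args, cfg$phantom_args))
  }
  fine <- shared$fine
  if (is.null(shared$v1)) {
    ref_field <- assign_conductivities(fine, cfg$config, cfg$frequency)
    shared$v1 <- solve_forward(fine, ref_field, protocol,
                               contact_impedance = cfg$contact_impedance,
                               provenance = "simulated_reference_V1")
  }
  v1 <- shared$v1
  if (is.null(shared$inverse)) {
    shared$inverse <- do.call(build_phantom, c(list(
      shape = cfg$shape, mesh_density = cfg$inverse_density, seed = cfg$seed
    ), bone_args, cfg$phantom_args))
  }
  inv <- shared$inverse

  sigma0 <- make_boneless(inv, cfg$config, cfg$frequency)
  sys0 <- cem_system(inv$mesh, sigma0, inv$electrodes,
                     cfg$contact_impedance)
  v0 <- solve_forward(inv, sigma0, protocol, system = sys0,
                      provenance = "simulated_boneless_V0")
  jac <- compute_jacobian(inv$mesh, sigma0, protocol, system = sys0,
                          electrodes = inv$electrodes)
  delta_v <- voltage_vector(v1) - voltage_vector(v0)
  ds <- reconstruct_delta_sigma(delta_v, jac, inv$mesh,
                                reg_config(lambda = cfg$lambda))
  seg <- estimate_axes(ds, inv$mesh, inv$electrodes, inv$z_m,
                       seg_options = cfg$seg_options, r0 = cfg$r0,
                       invert_weights = cfg$invert_weights)
  truth <- fine$true_axis
  dev_init <- compute_deviation(seg$chosen$initial, truth, inv$z_m)
  dev_opt <- compute_deviation(seg$chosen$estimate, truth, inv$z_m)
  report <- tibble::tibble(
    model = cfg$shape, config = cfg$config,
    delta_p_initial_mm = dev_init$delta_p_mm,
    delta_p_optimal_mm = dev_opt$delta_p_mm,
    phi_initial_deg = dev_init$phi_deg,
    phi_optimal_deg = dev_opt$phi_deg,
    delta_p3d_initial_mm = dev_init$delta_p3d_mm,
    delta_p3d_optimal_mm = dev_opt$delta_p3d_mm,
    n_fine = nrow(fine$mesh$tets), n_inverse = nrow(inv$mesh$tets),
    lambda = cfg$lambda, seed = cfg$seed,
    cg_iterations = ds$solver_iterations
  )
  out <- list(report = report, chosen = seg$chosen,
              candidates = seg$candidates, truth = truth,
              config = cfg, shared = shared)
  if (cfg$keep_intermediates) {
    out$delta_sigma <- ds
    out$partition <- seg$partition
    out$jacobian <- jac
    out$v0 <- v0
    out$v1 <- v1
  }
  class(out) <- "deit_run"
  out
}

#' @export
print.deit_run <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "deit_run (%s, %s): dp initial %.2f mm -> optimal %.2f mm; phi %.2f -> %.2f deg\n",
    r$model, r$config, r$delta_p_initial_mm, r$delta_p_optimal_mm,
    r$phi_initial_deg, r$phi_optimal_deg))
  invisible(x)
}

#' Run the five-model study
#'
#' The study tests five thigh model / reference configuration combinations:
#' cylinder with cfg1 and cfg2, realistic cross-section with cfg1, cfg2 and
#' cfg3.  Expensive stages (fine phantom, reference voltages, inverse mesh)
#' are shared across configurations of the same shape.
#'
#' @param seed integer seed.
#' @param fine_density,inverse_density mesh densities (m).
#' @param ... further arguments forwarded to [pipeline_config()].
#' @return a `deit_study`: `report` (five rows plus a `mean` row) and the
#'   individual runs.
#' @export
run_study <- function(seed = 1L, fine_density = 0.011,
                      inverse_density = 0.013, ...) {
  combos <- list(
    list(shape = "cylinder", config = "cfg1_homogeneous"),
    list(shape = "cylinder", config = "cfg2_skin_fat"),
    list(shape = "realistic", config = "cfg1_homogeneous"),
    list(shape = "realistic", config = "cfg2_skin_fat"),
    list(shape = "realistic", config = "cfg3_skin_fat_intra")
  )
  runs <- list()
  shared_by_shape <- list()
  for (cb in combos) {
    cfg <- pipeline_config(shape = cb$shape, config = cb$config,
                           fine_density = fine_density,
                           inverse_density = inverse_density,
                           seed = seed, ...)
    run <- run_pipeline(cfg, shared = shared_by_shape[[cb$shape]])
    shared_by_shape[[cb$shape]] <- run$shared
    runs[[base::length(runs) + 1L]] <- run
  }
  report <- dplyr::bind_rows(lapply(runs, `[[`, "report"))
  mean_row <- dplyr::summarise(report, model = "mean", config = "",
    dplyr::across(dplyr::where(is.numeric), mean))
  report <- dplyr::bind_rows(report, mean_row)
  structure(list(report = report, runs = runs, seed = seed),
            class = "deit_study")
}

#' @export
print.deit_study <- function(x, ...) {
  cat("deit_study of the five model/configuration combinations\n")
  print(as.data.frame(dplyr::select(
    x$report, model, config, delta_p_initial_mm, delta_p_optimal_mm,
    phi_initial_deg, phi_optimal_deg)), digits = 3)
  invisible(x)
}

#' Broom-style tidier for study results
#' @param x a `deit_study` or `deit_run`.
#' @param ... unused.
#' @return tibble of per-run deviations.
#' @export
tidy.deit_study <- function(x, ...) x$report

#' @export
tidy.deit_run <- function(x, ...) x$report

#' One-line summary of a study
#' @param x a `deit_study`.
#' @param ... unused.
#' @return one-row tibble with the study-level summary metrics.
#' @export
glance.deit_study <- function(x, ...) {
  r <- x$report[x$report$model != "mean", ]
  tibble::tibble(
    n_runs = nrow(r),
    max_delta_p_initial_mm = max(r$delta_p_initial_mm),
    max_phi_optimal_deg = max(r$phi_optimal_deg),
    mean_phi_optimal_deg = mean(r$phi_optimal_deg),
    mean_delta_p_optimal_mm = mean(r$delta_p_optimal_mm)
  )
}

#' Tiny demonstration / test fixture
#'
#' Builds a small cylinder phantom (a few thousand elements) and
#' precomputes the boneless system, voltage pair and Jacobian on it, so
#' segmentation and axis-fit examples run in seconds without a full
#' forward solve.  Both voltage frames are simulated on the same mesh
#' (fine enough for demonstrations; the full pipeline uses an independent
#' inverse mesh).
#'
#' @param seed integer seed.
#' @param mesh_density element size (m) of the fixture mesh.
#' @param length thigh length (m).
#' @param config boneless reference configuration.
#' @return list with `phantom`, `protocol`, `v1`, `v0`, `delta_v`,
#'   `jacobian`.
#' @export
make_demo_fixture <- function(seed = 1L, mesh_density = 0.028,
                              length = 0.18, config = "cfg1_homogeneous") {
  ph <- build_phantom("cylinder", mesh_density = mesh_density,
                      length = length, seed = seed,
                      outer_ring_nodes = 48L, belt_hz = 0.008,
                      belt_halfwidth = 0.016, hz_max = 0.03)
  protocol <- build_protocol()
  s0 <- make_boneless(ph, config)
  sys0 <- cem_system(ph$mesh, s0, ph$electrodes)
  v0 <- solve_forward(ph, s0, protocol, system = sys0,
                      provenance = "simulated_boneless_V0")
  v1 <- solve_forward(ph, assign_conductivities(ph, config), protocol,
                      provenance = "simulated_reference_V1")
  jac <- compute_jacobian(ph$mesh, s0, protocol, system = sys0,
                          electrodes = ph$electrodes)
  list(phantom = ph, protocol = protocol, v1 = v1, v0 = v0,
       delta_v = voltage_vector(v1) - voltage_vector(v0), jacobian = jac)
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
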