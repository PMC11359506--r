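# ---------------------------------------------------------------------------
# ggplot2 views of phantoms, reconstructions and study reports.
# ---------------------------------------------------------------------------

#' Cross-section plot of a per-element field
#'
#' Scatter of element centroids in a slab around height `z`, coloured by a
#' per-element value (tissue label, conductivity, reconstructed difference).
#'
#' @param mesh a `tet_mesh` or `thigh_phantom`.
#' @param values per-element values; defaults to the phantom's tissues.
#' @param z slab centre height (m); defaults to the mid-plane.
#' @param half_width slab half-width (m).
#' @return a ggplot object.
#' @export
plot_cross_section <- function(mesh, values = NULL, z = NULL,
                               half_width = 0.008) {
  if (inherits(mesh, "thigh_phantom")) {
    if (is.null(values)) values <- mesh$tissue
    if (is.null(z)) z <- mesh$z_m
    mesh <- mesh$mesh
  }
  if (is.null(z)) z <- mean(range(mesh$vertices[, 3]))
  if (inherits(values, "delta_sigma_field")) values <- values$delta_sigma
  ctr <- tet_centroids(mesh)
  sel <- abs(ctr[, 3] - z) <= half_width
  df <- tibble::tibble(x_mm = 1000 * ctr[sel, 1], y_mm = 1000 * ctr[sel, 2],
                       value = values[sel])
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm,
                                        colour = .data$value)) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x [mm]", y = "y [mm]",
                  title = sprintf("cross-section at z = %.0f mm", 1000 * z))
  if (is.numeric(df$value)) {
    p <- p + ggplot2::scale_colour_gradient2(low = "navy", mid = "grey90",
                                             high = "firebrick")
  }
  p
}

#' Deviation overview of a study
#'
#' Dot plot of positional and angular deviations per model/configuration
#' and stage.
#'
#' @param object a `deit_study`.
#' @param ... unused.
#' @return a ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.deit_study <- function(object, ...) {
  r <- object$report[object$report$model != "mean", ]
  long <- dplyr::bind_rows(
    tibble::tibble(run = paste(r$model, sub("_.*", "", r$config)),
                   metric = "positional deviation [mm]",
                   stage = "initial", value = r$delta_p_initial_mm),
    tibble::tibble(run = paste(r$model, sub("_.*", "", r$config)),
                   metric = "positional deviation [mm]",
                   stage = "optimal", value = r$delta_p_optimal_mm),
    tibble::tibble(run = paste(r$model, sub("_.*", "", r$config)),
                   metric = "angular deviation [deg]",
                   stage = "initial", value = r$phi_initial_deg),
    tibble::tibble(run = paste(r$model, sub("_.*", "", r$config)),
                   metric = "angular deviation [deg]",
                   stage = "optimal", value = r$phi_optimal_deg)
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$run, .data$value,
                                     shape = .data$stage,
                                     colour = .data$stage)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Sorted-value curve of a reconstruction with the fitted flat band
#'
#' @param partition a `bin_partition`.
#' @param delta_sigma the field the partition was computed from.
#' @return a ggplot object.
#' @export
plot_sorted_values <- function(partition, delta_sigma) {
  ds <- if (inherits(delta_sigma, "delta_sigma_field")) delta_sigma$delta_sigma else delta_sigma
  retained <- setdiff(seq_along(ds), partition$excluded_elements)
  sv <- sort(ds[retained])
  df <- tibble::tibble(index = seq_along(sv), value = sv)
  fs <- partition$flat_stats
  ggplot2::ggplot(df, ggplot2::aes(.data$index, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = fs["y0"] + c(-1, 1) * fs["rms"],
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "sorted element index",
                  y = expression(Delta * sigma ~ "[S/m]"))
}
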