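# ---------------------------------------------------------------------------
# Plain-text interchange: Gmsh MSH v2.2 meshes (physical tag = tissue),
# legacy ASCII VTK for visualization, CSV fields, JSON ground truth.
# ---------------------------------------------------------------------------

#' Write a mesh (with optional tissue labels) as Gmsh MSH v2.2 ASCII
#'
#' Tetrahedra are written as element type 4 with the physical tag carrying
#' the tissue code (1 = skin, 2 = fat_subcut, 3 = fat_intra, 4 = muscle,
#' 5 = bone, 6 = marrow; 0 if no labels are given).
#'
#' @param mesh a `tet_mesh` or `thigh_phantom`.
#' @param file output path.
#' @param tissue optional per-element tissue labels.
#' @return `file`, invisibly.
#' @export
write_msh <- function(mesh, file, tissue = NULL) {
  if (inherits(mesh, "thigh_phantom")) {
    tissue <- mesh$tissue
    mesh <- mesh$mesh
  }
  V <- mesh$vertices
  T <- mesh$tets
  tag <- if (is.null(tissue)) rep(0L, nrow(T)) else unname(TISSUE_CODES[tissue])
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
               as.character(nrow(V))), con)
  writeLines(sprintf("%d %.12g %.12g %.12g", seq_len(nrow(V)),
                     V[, 1], V[, 2], V[, 3]), con)
  writeLines(c("$EndNodes", "$Elements", as.character(nrow(T))), con)
  writeLines(sprintf("%d 4 2 %d %d %d %d %d %d", seq_len(nrow(T)), tag, tag,
                     T[, 1], T[, 2], T[, 3], T[, 4]), con)
  writeLines("$EndElements", con)
  invisible(file)
}

#' Read a Gmsh MSH v2.2 ASCII mesh
#'
#' Reads nodes and tetrahedral elements (type 4); the physical tag is
#' mapped back to tissue labels where it matches a known code.
#'
#' @param file path to an MSH v2.2 file.
#' @return list with `mesh` (a `tet_mesh`) and `tissue` (labels or NULL).
#' @export
read_msh <- function(file) {
  lines <- readLines(file)
  sect <- function(name) {
    i0 <- match(paste0("$", name), lines)
    i1 <- match(paste0("$End", name), lines)
    if (is.na(i0) || is.na(i1)) stop("malformed MSH file: missing ", name)
    lines[(i0 + 1L):(i1 - 1L)]
  }
  fmt <- strsplit(sect("MeshFormat")[1], " ")[[1]]
  if (!startsWith(fmt[1], "2.")) {
    stop("only MSH v2.x ASCII is supported (got version ", fmt[1], ")")
  }
  nd <- sect("Nodes")
  n <- as.integer(nd[1])
  nodes <- matrix(scan(text = nd[-1], quiet = TRUE), ncol = 4, byrow = TRUE)
  stopifnot(nrow(nodes) == n)
  el <- sect("Elements")
  body <- el[-1]
  parts <- strsplit(body, " ")
  tets <- list(); tags <- integer(0); k <- 0L
  for (p in parts) {
    p <- as.integer(p)
    if (p[2] != 4L) next                  # only tetrahedra
    ntags <- p[3]
    k <- k + 1L
    tags[k] <- if (ntags >= 1L) p[4] else 0L
    tets[[k]] <- p[(4L + ntags):(7L + ntags)]
  }
  T <- do.call(rbind, tets)
  z <- sort(unique(nodes[, 4]))
  mesh <- structure(list(vertices = nodes[, 2:4, drop = FALSE], tets = T,
                         z_levels = z), class = "tet_mesh")
  tissue <- if (all(tags %in% TISSUE_CODES)) names(TISSUE_CODES)[tags] else NULL
  list(mesh = mesh, tissue = tissue)
}

#' Write a mesh with cell data as legacy ASCII VTK
#'
#' @param mesh a `tet_mesh` or `thigh_phantom`.
#' @param file output path.
#' @param cell_data named list of per-element numeric vectors.
#' @return `file`, invisibly.
#' @export
write_vtk <- function(mesh, file, cell_data = list()) {
  if (inherits(mesh, "thigh_phantom")) {
    cell_data <- c(list(tissue = unname(TISSUE_CODES[mesh$tissue])), cell_data)
    mesh <- mesh$mesh
  }
  V <- mesh$vertices
  T <- mesh$tets - 1L
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "tet mesh", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(V))), con)
  writeLines(sprintf("%.9g %.9g %.9g", V[, 1], V[, 2], V[, 3]), con)
  writeLines(sprintf("CELLS %d %d", nrow(T), 5L * nrow(T)), con)
  writeLines(sprintf("4 %d %d %d %d", T[, 1], T[, 2], T[, 3], T[, 4]), con)
  writeLines(sprintf("CELL_TYPES %d", nrow(T)), con)
  writeLines(rep("10", nrow(T)), con)
  if (base::length(cell_data) > 0) {
    writeLines(sprintf("CELL_DATA %d", nrow(T)), con)
    for (nm in names(cell_data)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
                 con)
      writeLines(sprintf("%.9g", cell_data[[nm]]), con)
    }
  }
  invisible(file)
}

#' Write a voltage frame as CSV with a JSON metadata sidecar
#'
#' @param vf a `voltage_frame`.
#' @param file CSV output path (`<file>.json` holds protocol metadata).
#' @return `file`, invisibly.
#' @export
write_voltage_frame <- function(vf, file) {
  tb <- as_tibble.voltage_frame(vf)
  utils::write.csv(tb, file, row.names = FALSE)
  meta <- list(provenance = vf$provenance,
               n_electrodes = vf$protocol$n_electrodes,
               pattern = vf$protocol$pattern_name,
               amplitude_A = vf$protocol$amplitude,
               frequency_Hz = vf$protocol$frequency)
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' Read a voltage frame written by [write_voltage_frame()]
#' @param file CSV path.
#' @return a `voltage_frame`.
#' @export
read_voltage_frame <- function(file) {
  tb <- utils::read.csv(file)
  meta <- jsonlite::read_json(paste0(file, ".json"))
  protocol <- build_protocol(n_electrodes = meta$n_electrodes,
                             pattern_name = meta$pattern,
                             amplitude = meta$amplitude_A,
                             frequency = meta$frequency_Hz)
  volt <- matrix(NA_real_, max(tb$pattern), max(tb$meas))
  volt[cbind(tb$pattern, tb$meas)] <- tb$volts
  structure(list(voltages = volt, protocol = protocol,
                 provenance = meta$provenance, U_pattern = NULL),
            class = "voltage_frame")
}

#' Write a conductivity-difference field as CSV
#' @param ds a `delta_sigma_field` or numeric vector.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_delta_sigma <- function(ds, file) {
  v <- if (inherits(ds, "delta_sigma_field")) ds$delta_sigma else ds
  utils::write.csv(data.frame(element = seq_along(v), delta_sigma = v),
                   file, row.names = FALSE)
  invisible(file)
}

#' Write an axis estimate (or study report) as JSON
#' @param x an `axis_estimate`, `deit_run` or `deit_study`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_report_json <- function(x, file) {
  obj <- if (inherits(x, "axis_estimate")) {
    as.list(tidy.axis_estimate(x))
  } else if (inherits(x, "deit_run")) {
    as.list(x$report)
  } else if (inherits(x, "deit_study")) {
    x$report
  } else x
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(file)
}
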