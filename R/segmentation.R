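# ---------------------------------------------------------------------------
# Segmentation of the reconstructed conductivity-difference field into
# candidate bone clusters: 15-bin partition of the sorted values around a
# fitted "flat" background band, then face-connected region growing over
# the low bins, then the small-surface-cluster discard rule.
# ---------------------------------------------------------------------------

#' Segmentation constants
#'
#' @param exclusion_radius electrode-proximal exclusion radius (m): elements
#'   with a vertex closer than this to any electrode centre are removed
#'   before binning (default two electrode diameters, 14 mm).
#' @param slope_window lag of the finite-difference slope over the sorted
#'   values (samples).
#' @param flat_factor constant factor of the flat-region slope threshold.
#' @param n0 reference sample count the threshold is calibrated to.
#' @param b_lo,b_hi number of bins below / above the flat band.
#' @param b_max highest bin considered by region growing.
#' @param min_cluster_size surface/electrode-touching clusters smaller than
#'   this are discarded.
#' @return list of segmentation options.
#' @export
segmentation_options <- function(exclusion_radius = 0.014, slope_window = 100L,
                                 flat_factor = 0.002, n0 = 230000,
                                 b_lo = 9L, b_hi = 5L, b_max = 7L,
                                 min_cluster_size = 64L) {
  list(exclusion_radius = exclusion_radius, slope_window = as.integer(slope_window),
       flat_factor = flat_factor, n0 = n0, b_lo = as.integer(b_lo),
       b_hi = as.integer(b_hi), b_max = as.integer(b_max),
       min_cluster_size = as.integer(min_cluster_size))
}

# contiguous flat sample range [i1, i2] from the lag-`window` slopes:
# slope n covers samples n .. n + window, the flat region is the union of
# samples covered between the first and the last sub-threshold slope
flat_region <- function(slopes, window, threshold) {
  w <- which(slopes < threshold)
  if (base::length(w) == 0) return(NULL)
  c(min(w), max(w) + window)
}

#' Partition the conductivity-difference field into 15 bins
#'
#' Electrode-proximal elements are removed; the remaining values are sorted
#' ascending; a lag-100 slope identifies the flat background band, to which
#' a line anchored at the band median is fitted; the RMS deviation of the
#' band from that line sets the guard offset; the interval below the band
#' is split into 9 equal half-open bins (b1-b9), the interval above into 5
#' (b11-b15), and the band itself is bin b10.  Values beyond the outermost
#' edges are clamped into b1 / b15.
#'
#' @param delta_sigma a `delta_sigma_field` or numeric per-element vector.
#' @param mesh the inverse `tet_mesh`.
#' @param electrodes electrode list (belt + ground) of the inverse mesh.
#' @param options [segmentation_options()].
#' @return a `bin_partition`: `bin_index` (per element, NA for excluded),
#'   `bin_edges` (16 boundaries), `excluded_elements`, `flat_stats`.
#' @export
compute_bin_partition <- function(delta_sigma, mesh, electrodes,
                                  options = segmentation_options()) {
  ds <- if (inherits(delta_sigma, "delta_sigma_field")) delta_sigma$delta_sigma else delta_sigma
  E <- nrow(mesh$tets)
  stopifnot(base::length(ds) == E)

  # 1. remove elements close to electrodes (any vertex within the radius
  #    of any electrode centre)
  centers <- do.call(rbind, lapply(electrodes, `[[`, "center"))
  V <- mesh$vertices
  near <- logical(nrow(V))
  r2 <- options$exclusion_radius^2
  for (k in seq_len(if (is.null(centers)) 0L else nrow(centers))) {
    d2 <- (V[, 1] - centers[k, 1])^2 + (V[, 2] - centers[k, 2])^2 +
      (V[, 3] - centers[k, 3])^2
    near <- near | (d2 < r2)
  }
  excl <- near[mesh$tets[, 1]] | near[mesh$tets[, 2]] |
    near[mesh$tets[, 3]] | near[mesh$tets[, 4]]
  retained <- which(!excl)
  N <- base::length(retained)
  win <- options$slope_window
  if (N < 2L * win) {
    stop("size error: only ", N, " retained elements; need at least ", 2L * win)
  }

  # 2-4. sort, lag slope, flat band
  vals <- ds[retained]
  svals <- sort(vals)
  sl <- svals[(win + 1L):N] - svals[1L:(N - win)]
  thr <- (sl[1] + sl[base::length(sl)]) / 2 * options$flat_factor * (options$n0 / N)
  fr <- flat_region(sl, win, thr)
  if (is.null(fr)) {
    stop("degenerate-partition error: no flat background band found")
  }
  idx <- fr[1]:min(fr[2], N)
  yflat <- svals[idx]

  # 5-6. line fit anchored at the band median; RMS deviation
  x0 <- stats::median(idx)
  y0 <- stats::median(yflat)
  dx <- idx - x0
  dy <- if (sum(dx^2) > 0) sum(dx * (yflat - y0)) / sum(dx^2) else 0
  resid <- yflat - (y0 + dx * dy)
  rms <- sqrt(mean(resid^2))
  if (rms <= 0) {
    stop("degenerate-partition error: flat band has zero RMS deviation")
  }

  # 7-8. equal half-open bins below and above the band
  lo_a <- min(svals) + rms
  lo_b <- y0 - rms
  hi_a <- y0 + rms
  hi_b <- max(svals) - rms
  lower_edges <- if (lo_a < lo_b) seq(lo_a, lo_b, length.out = options$b_lo + 1L) else NULL
  upper_edges <- if (hi_a < hi_b) seq(hi_a, hi_b, length.out = options$b_hi + 1L) else NULL

  bin <- rep(NA_integer_, E)
  v <- ds[retained]
  b <- rep(10L, N)
  below <- v < lo_b
  above <- v >= hi_a
  if (!is.null(lower_edges)) {
    k <- findInterval(v[below], lower_edges)
    b[below] <- pmin(pmax(k, 1L), options$b_lo)
  } else {
    b[below] <- 10L   # no resolvable band below: leave in the flat bin
  }
  if (!is.null(upper_edges)) {
    k <- findInterval(v[above], upper_edges)
    b[above] <- 10L + pmin(pmax(k, 1L), options$b_hi)
  } else {
    b[above] <- 10L
  }
  bin[retained] <- b

  structure(list(
    bin_index = bin,
    bin_edges = c(lower_edges, upper_edges),
    excluded_elements = which(excl),
    flat_stats = c(x0 = x0, y0 = y0, dy = dy, rms = rms),
    n_retained = N, options = options
  ), class = "bin_partition")
}

#' Grow face-connected clusters over the low bins
#'
#' Seeded flood fill over the face-adjacency graph restricted to elements
#' whose bin index is at most `b_max` (default 7; bins 8-15 and the flat
#' band are never assigned).  Seeds iterate in ascending element order, so
#' cluster numbering is deterministic.
#'
#' @param partition a `bin_partition`.
#' @param mesh the inverse `tet_mesh`.
#' @return list of `cluster` objects (`element_ids`, `size`).
#' @export
grow_clusters <- function(partition, mesh) {
  E <- nrow(mesh$tets)
  eligible <- !is.na(partition$bin_index) &
    partition$bin_index <= partition$options$b_max
  adj <- adjacency_list(face_adjacency(mesh), E)
  assigned <- integer(E)          # 0 = unassigned
  queue <- integer(E)
  clusters <- list()
  k <- 0L
  for (seed in seq_len(E)) {
    if (!eligible[seed] || assigned[seed] != 0L) next
    k <- k + 1L
    assigned[seed] <- k
    queue[1L] <- seed
    qh <- 1L; qt <- 1L
    while (qh <= qt) {
      cur <- queue[qh]; qh <- qh + 1L
      if (adj$counts[cur] > 0L) {
        nb <- adj$to[adj$starts[cur]:adj$ends[cur]]
        nb <- nb[eligible[nb] & assigned[nb] == 0L]
        for (x in nb) {
          assigned[x] <- k
          qt <- qt + 1L
          queue[qt] <- x
        }
      }
    }
    clusters[[k]] <- list(element_ids = sort(queue[seq_len(qt)]), size = qt)
  }
  clusters
}

#' Discard small surface- or electrode-touching clusters
#'
#' A cluster is discarded iff it contains fewer than `min_cluster_size`
#' elements AND touches the outer surface of the model or any electrode.
#' Survivors are returned sorted by ascending size.
#'
#' @param clusters output of [grow_clusters()].
#' @param mesh the inverse `tet_mesh`.
#' @param electrodes electrode list of the inverse mesh.
#' @param options [segmentation_options()].
#' @return filtered, size-sorted list of clusters with `touches_surface`
#'   and `touches_electrode` flags filled in.
#' @export
filter_clusters <- function(clusters, mesh, electrodes,
                            options = segmentation_options()) {
  bf <- boundary_faces(mesh)
  on_surface <- logical(nrow(mesh$tets))
  on_surface[bf$elem] <- TRUE
  el_nodes <- unique(unlist(lapply(electrodes, `[[`, "nodes")))
  node_is_el <- logical(nrow(mesh$vertices))
  node_is_el[el_nodes] <- TRUE
  tet_el <- node_is_el[mesh$tets[, 1]] | node_is_el[mesh$tets[, 2]] |
    node_is_el[mesh$tets[, 3]] | node_is_el[mesh$tets[, 4]]

  out <- list()
  for (cl in clusters) {
    cl$touches_surface <- any(on_surface[cl$element_ids])
    cl$touches_electrode <- any(tet_el[cl$element_ids])
    discard <- cl$size < options$min_cluster_size &&
      (cl$touches_surface || cl$touches_electrode)
    if (!discard) out[[base::length(out) + 1L]] <- cl
  }
  out[order(vapply(out, `[[`, 0L, "size"))]
}

#' @export
print.bin_partition <- function(x, ...) {
  tt <- table(factor(x$bin_index, levels = 1:15))
  cat(sprintf("bin_partition: %d retained, %d excluded; y0 = %.3g, rms = %.3g\n",
              x$n_retained, base::length(x$excluded_elements),
              x$flat_stats["y0"], x$flat_stats["rms"]))
  cat("  bins 1-15:", paste(tt, collapse = " "), "\n")
  invisible(x)
}
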