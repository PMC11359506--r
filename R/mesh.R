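# ---------------------------------------------------------------------------
# Structured tetrahedral mesher for (deformed) cylinder domains.
#
# Strategy: triangulate a disc with concentric node rings (ring radii snapped
# to tissue-boundary radii), extrude along z into triangular prisms on a
# graded z grid, and split every prism into 3 tetrahedra with face diagonals
# chosen from the smallest global vertex index of each quad face.  The
# min-index rule makes diagonal choices a function of the shared face alone,
# so the resulting tet mesh is conforming across prism boundaries.
# ---------------------------------------------------------------------------

#' Ring layout for a disc triangulation
#'
#' Chooses ring radii (snapping to the requested compartment boundaries,
#' filling gaps at roughly spacing `h`) and per-ring node counts.  The two
#' outermost rings carry a node count that is a multiple of `n_electrodes`
#' so electrode centres coincide with boundary nodes.
#'
#' @param boundary_radii radii (m) that must be honoured by a ring, the last
#'   one being the outer radius.
#' @param h target in-plane element size (m).
#' @param n_electrodes electrodes on the belt (node-count multiple).
#' @return list with `radius` and `n` vectors.
#' @keywords internal
ring_spec <- function(boundary_radii, h, n_electrodes = 16L,
                      outer_ring_nodes = NULL) {
  rb <- sort(unique(boundary_radii))
  stopifnot(all(rb > 0), h > 0)
  radii <- numeric(0)
  prev <- 0
  for (r in rb) {
    gap <- r - prev
    k <- max(1L, ceiling(gap / h - 1e-9))
    radii <- c(radii, prev + gap * seq_len(k) / k)
    prev <- r
  }
  radii <- sort(unique(round(radii, 12)))
  n <- pmax(8L, as.integer(ceiling(2 * pi * radii / h)))
  K <- length(radii)
  outer_rings <- unique(pmax(1L, c(K - 1L, K)))
  for (k in outer_rings) {
    n[k] <- as.integer(n_electrodes * max(3L, ceiling(n[k] / n_electrodes)))
  }
  # a fixed node count on the outer rings decouples the electrode and
  # thin-shell discretization from the interior density: meshes of the
  # same geometry then carry identical electrode patches and identical
  # shell elements, so shell discretization error cancels in voltage
  # differences while the interior meshes stay independent
  if (!is.null(outer_ring_nodes)) {
    n[K] <- as.integer(n_electrodes * max(3L, round(outer_ring_nodes / n_electrodes)))
    on_boundary <- vapply(radii, function(r) any(abs(r - rb) < 1e-9), TRUE)
    shell <- which(on_boundary & radii < radii[K] - 1e-9 &
                     radii >= rb[max(1L, length(rb) - 2L)] - 1e-9)
    n[shell] <- as.integer(n_electrodes * 3L)
  }
  list(radius = radii, n = n)
}

# Triangulate the annulus between two node rings by circular merge of the
# two angle sequences; returns index triples into the global node table.
merge_rings <- function(idxA, angA, idxB, angB) {
  nA <- length(idxA); nB <- length(idxB)
  ref <- angA[1]
  d <- (angB - ref) %% (2 * pi)
  d <- pmin(d, 2 * pi - d)
  rot <- which.min(d)
  ordB <- c(rot:nB, seq_len(rot - 1L))
  idxB <- idxB[ordB]
  ub <- (angB[ordB] - ref) %% (2 * pi)
  if (ub[1] > pi) ub[1] <- ub[1] - 2 * pi
  if (nB > 1) for (k in 2:nB) while (ub[k] < ub[k - 1]) ub[k] <- ub[k] + 2 * pi
  ua <- (angA - ref) %% (2 * pi)
  if (nA > 1) for (k in 2:nA) while (ua[k] < ua[k - 1]) ua[k] <- ua[k] + 2 * pi

  tris <- matrix(0L, nA + nB, 3L)
  ia <- 1L; ib <- 1L; ca <- 0L; cb <- 0L; nt <- 0L
  next_ang <- function(u, i, n) if (i < n) u[i + 1L] else u[1] + 2 * pi
  while (ca < nA || cb < nB) {
    advA <- if (ca >= nA) FALSE
    else if (cb >= nB) TRUE
    else next_ang(ua, ia, nA) <= next_ang(ub, ib, nB)
    if (advA) {
      ia2 <- if (ia < nA) ia + 1L else 1L
      nt <- nt + 1L
      tris[nt, ] <- c(idxA[ia], idxB[ib], idxA[ia2])
      ia <- ia2; ca <- ca + 1L
    } else {
      ib2 <- if (ib < nB) ib + 1L else 1L
      nt <- nt + 1L
      tris[nt, ] <- c(idxA[ia], idxB[ib], idxB[ib2])
      ib <- ib2; cb <- cb + 1L
    }
  }
  tris[seq_len(nt), , drop = FALSE]
}

#' Triangulate a disc from a ring specification
#'
#' @param rings output of [ring_spec()].
#' @return list with `xy` (nodes x 2), `tri` (triangles x 3),
#'   `outer_ring` (node indices of the outermost ring, in angular order).
#' @keywords internal
triangulate_disc <- function(rings) {
  K <- length(rings$radius)
  xs <- 0; ys <- 0                       # node 1 = centre
  idx <- vector("list", K)
  ang <- vector("list", K)
  nn <- 1L
  for (k in seq_len(K)) {
    m <- rings$n[k]
    a <- 2 * pi * (seq_len(m) - 1L) / m
    idx[[k]] <- nn + seq_len(m)
    ang[[k]] <- a
    xs <- c(xs, rings$radius[k] * cos(a))
    ys <- c(ys, rings$radius[k] * sin(a))
    nn <- nn + m
  }
  tris <- list()
  m1 <- rings$n[1]
  tris[[1]] <- cbind(1L, idx[[1]], idx[[1]][c(2:m1, 1L)])
  if (K > 1) {
    for (k in 2:K) {
      tris[[k]] <- merge_rings(idx[[k - 1L]], ang[[k - 1L]], idx[[k]], ang[[k]])
    }
  }
  list(xy = cbind(xs, ys), tri = do.call(rbind, tris),
       outer_ring = idx[[K]], outer_ang = ang[[K]])
}

# Graded 1D grid of layer boundaries from 0 to `dist`; spacing h0 within
# `fine_width` of the start, then geometric growth capped at hmax.
grade_steps <- function(dist, h0, hmax, fine_width, grow = 1.4) {
  if (dist <= 1e-12) return(numeric(0))
  z <- 0; out <- numeric(0); cur <- h0
  repeat {
    if (z >= fine_width - 1e-12) cur <- min(cur * grow, hmax)
    step <- if (z < fine_width - 1e-12) h0 else cur
    z2 <- min(z + step, dist)
    if (dist - z2 < 0.45 * step) z2 <- dist
    out <- c(out, z2)
    z <- z2
    if (z >= dist - 1e-12) break
  }
  out
}

# Split all prisms (triangle x layer) into 3 tets each with conforming
# diagonals (min global-vertex-index rule per quad face).
split_prisms <- function(tri, n_disc, n_layers) {
  nt <- nrow(tri)
  # rotate each triangle so its smallest disc index comes first; the
  # rotation is layer-independent because global index = offset + disc index
  amin <- max.col(-tri)                    # position of row minimum
  rot1 <- cbind(seq_len(nt), amin)
  c2 <- amin %% 3L + 1L
  c3 <- c2 %% 3L + 1L
  t1 <- tri[rot1]
  t2 <- tri[cbind(seq_len(nt), c2)]
  t3 <- tri[cbind(seq_len(nt), c3)]
  caseA <- t2 < t3
  tets <- vector("list", n_layers - 1L)
  for (l in seq_len(n_layers - 1L)) {
    off <- (l - 1L) * n_disc
    b1 <- t1 + off; b2 <- t2 + off; b3 <- t3 + off
    u1 <- b1 + n_disc; u2 <- b2 + n_disc; u3 <- b3 + n_disc
    TA <- rbind(cbind(b1, b2, b3, u3), cbind(b1, b2, u3, u2), cbind(b1, u2, u3, u1))
    TB <- rbind(cbind(b1, b2, b3, u2), cbind(b1, b3, u2, u3), cbind(b1, u1, u2, u3))
    sel <- rep(caseA, 3L)
    tets[[l]] <- rbind(TA[sel, , drop = FALSE], TB[!sel, , drop = FALSE])
  }
  do.call(rbind, tets)
}

#' Build a structured tetrahedral mesh of a cylinder
#'
#' @param boundary_radii radii (m) that rings must honour; last = outer radius.
#' @param length cylinder length (m); z runs from 0 to `length`.
#' @param z_m height (m) around which the z grid is refined (electrode plane).
#' @param h target element size (m); `hz_fine`, `hz_max`, `fine_halfwidth`
#'   control the graded z grid.
#' @param n_electrodes node-count multiple for the outer rings.
#' @return a `tet_mesh` list: `vertices` (n x 3), `tets` (E x 4),
#'   `outer_ring_nodes` (matrix layer x ring-node of global indices of the
#'   lateral-boundary nodes), `outer_ang`, `z_levels`.
#' @keywords internal
cylinder_mesh <- function(boundary_radii, length, z_m = length / 2,
                          h = 0.01, hz_fine = h / 2, hz_max = 2.2 * h,
                          fine_halfwidth = 0.025, n_electrodes = 16L,
                          outer_ring_nodes = NULL) {
  rings <- ring_spec(boundary_radii, h, n_electrodes, outer_ring_nodes)
  disc <- triangulate_disc(rings)
  lower <- grade_steps(z_m, hz_fine, hz_max, fine_halfwidth)
  upper <- grade_steps(length - z_m, hz_fine, hz_max, fine_halfwidth)
  z_levels <- sort(unique(c(z_m - lower, z_m, z_m + upper)))
  z_levels <- round(z_levels, 12)
  nl <- base::length(z_levels)
  nd <- nrow(disc$xy)
  vertices <- cbind(
    rep(disc$xy[, 1], nl),
    rep(disc$xy[, 2], nl),
    rep(z_levels, each = nd)
  )
  tets <- split_prisms(disc$tri, nd, nl)
  outer_ring_nodes <- outer(disc$outer_ring, (seq_len(nl) - 1L) * nd, `+`)
  structure(list(
    vertices = vertices, tets = tets,
    outer_ring_nodes = t(outer_ring_nodes),  # layer x ring position
    outer_ang = disc$outer_ang, z_levels = z_levels
  ), class = "tet_mesh")
}

# ---------------------------------------------------------------------------
# Tetrahedron utilities
# ---------------------------------------------------------------------------

# signed 6*volume determinant pieces, reused by volumes and gradients
tet_edge_vectors <- function(vertices, tets) {
  p1 <- vertices[tets[, 1], , drop = FALSE]
  list(
    p1 = p1,
    a = vertices[tets[, 2], , drop = FALSE] - p1,
    b = vertices[tets[, 3], , drop = FALSE] - p1,
    c = vertices[tets[, 4], , drop = FALSE] - p1
  )
}

cross3 <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

#' Tetrahedron volumes
#' @param mesh a `tet_mesh`.
#' @return numeric vector of element volumes (m^3).
#' @export
tet_volumes <- function(mesh) {
  ev <- tet_edge_vectors(mesh$vertices, mesh$tets)
  bc <- cross3(ev$b, ev$c)
  abs(rowSums(ev$a * bc)) / 6
}

#' Tetrahedron centroids
#' @param mesh a `tet_mesh`.
#' @return E x 3 matrix of element centroids.
#' @export
tet_centroids <- function(mesh) {
  (mesh$vertices[mesh$tets[, 1], , drop = FALSE] +
     mesh$vertices[mesh$tets[, 2], , drop = FALSE] +
     mesh$vertices[mesh$tets[, 3], , drop = FALSE] +
     mesh$vertices[mesh$tets[, 4], , drop = FALSE]) / 4
}

# Per-element P1 shape-function gradients: list of three E x 4 matrices
# (gx, gy, gz), plus volumes. Column j = gradient of the basis function of
# local vertex j.
tet_gradients <- function(mesh) {
  ev <- tet_edge_vectors(mesh$vertices, mesh$tets)
  bc <- cross3(ev$b, ev$c)
  ca <- cross3(ev$c, ev$a)
  ab <- cross3(ev$a, ev$b)
  det <- rowSums(ev$a * bc)                # signed 6V
  g2 <- bc / det; g3 <- ca / det; g4 <- ab / det
  g1 <- -(g2 + g3 + g4)
  list(
    gx = cbind(g1[, 1], g2[, 1], g3[, 1], g4[, 1]),
    gy = cbind(g1[, 2], g2[, 2], g3[, 2], g4[, 2]),
    gz = cbind(g1[, 3], g2[, 3], g3[, 3], g4[, 3]),
    vol = abs(det) / 6
  )
}

# Encode sorted face triples as one double key (exact for < 2^17 vertices).
face_keys <- function(f1, f2, f3, n_vert) {
  lo <- pmin(f1, f2, f3)
  hi <- pmax(f1, f2, f3)
  mid <- as.numeric(f1) + as.numeric(f2) + as.numeric(f3) -
    as.numeric(lo) - as.numeric(hi)
  M <- as.numeric(n_vert) + 1
  (as.numeric(lo) * M + mid) * M + as.numeric(hi)
}

# All 4E faces with owning element; face j of a tet omits local vertex j.
all_faces <- function(mesh) {
  T <- mesh$tets
  E <- nrow(T)
  n_vert <- nrow(mesh$vertices)
  v1 <- c(T[, 2], T[, 1], T[, 1], T[, 1])
  v2 <- c(T[, 3], T[, 3], T[, 2], T[, 2])
  v3 <- c(T[, 4], T[, 4], T[, 4], T[, 3])
  list(elem = rep(seq_len(E), 4L), v1 = v1, v2 = v2, v3 = v3,
       key = face_keys(v1, v2, v3, n_vert))
}

#' Face adjacency of a tetrahedral mesh
#'
#' @param mesh a `tet_mesh`.
#' @return two-column integer matrix; each row is a pair of elements sharing
#'   a triangular face.
#' @export
face_adjacency <- function(mesh) {
  f <- all_faces(mesh)
  o <- order(f$key)
  k <- f$key[o]; e <- f$elem[o]
  same <- which(diff(k) == 0)
  cbind(e[same], e[same + 1L])
}

#' Boundary faces of a tetrahedral mesh
#'
#' @param mesh a `tet_mesh`.
#' @return data.frame with columns `elem`, `v1`, `v2`, `v3` (one row per
#'   face belonging to exactly one element).
#' @export
boundary_faces <- function(mesh) {
  f <- all_faces(mesh)
  tab <- table(f$key)
  single <- names(tab)[tab == 1]
  keep <- f$key %in% as.numeric(single)
  data.frame(elem = f$elem[keep], v1 = f$v1[keep], v2 = f$v2[keep],
             v3 = f$v3[keep])
}

# Neighbour list (length E) from the adjacency pair matrix.
adjacency_list <- function(pairs, n_elem) {
  from <- c(pairs[, 1], pairs[, 2])
  to <- c(pairs[, 2], pairs[, 1])
  o <- order(from)
  from <- from[o]; to <- to[o]
  counts <- tabulate(from, nbins = n_elem)
  ends <- cumsum(counts)
  starts <- ends - counts + 1L
  list(to = to, starts = starts, ends = ends, counts = counts)
}

#' Check mesh conformity
#'
#' Every face must be shared by exactly one (boundary) or two (interior)
#' tetrahedra.
#'
#' @param mesh a `tet_mesh`.
#' @return TRUE invisibly; stops with a message otherwise.
#' @export
check_conforming <- function(mesh) {
  f <- all_faces(mesh)
  tab <- tabulate(match(f$key, unique(f$key)))
  if (any(tab > 2)) {
    stop("non-conforming mesh: a face is shared by more than two tets")
  }
  invisible(TRUE)
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("tet_mesh: %d vertices, %d tetrahedra, z in [%.3g, %.3g] m\n",
              nrow(x$vertices), nrow(x$tets),
              min(x$z_levels), max(x$z_levels)))
  invisible(x)
}
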