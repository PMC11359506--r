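# minimal hand-built meshes for clustering semantics
two_tet_mesh <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, 1, 1))
  structure(list(vertices = v, tets = rbind(c(1L, 2L, 3L, 4L),
                                            c(2L, 3L, 4L, 5L)),
                 z_levels = c(0, 1)), class = "tet_mesh")
}

fake_partition <- function(bins, b_max = 7L) {
  structure(list(bin_index = bins,
                 options = segmentation_options(b_max = b_max)),
            class = "bin_partition")
}

# terse independent reference of the binning steps (sorted values, lag
# slope, contiguous flat band, anchored line fit, rms guard, equal bins)
reference_bins <- function(v, opts = segmentation_options()) {
  N <- length(v)
  s <- sort(v)
  win <- opts$slope_window
  sl <- s[(win + 1):N] - s[1:(N - win)]
  thr <- (sl[1] + sl[length(sl)]) / 2 * opts$flat_factor * opts$n0 / N
  w <- which(sl < thr)
  idx <- min(w):min(max(w) + win, N)
  x0 <- median(idx); y0 <- median(s[idx])
  dy <- sum((idx - x0) * (s[idx] - y0)) / sum((idx - x0)^2)
  rms <- sqrt(mean((s[idx] - (y0 + (idx - x0) * dy))^2))
  lo <- seq(min(s) + rms, y0 - rms, length.out = 10)
  hi <- seq(y0 + rms, max(s) - rms, length.out = 6)
  b <- rep(10L, N)
  bel <- v < y0 - rms
  abv <- v >= y0 + rms
  b[bel] <- pmin(pmax(findInterval(v[bel], lo), 1L), 9L)
  b[abv] <- 10L + pmin(pmax(findInterval(v[abv], hi), 1L), 5L)
  b
}

test_that("the bin partition follows the printed construction", {
  fx <- demo_fixture()
  E <- nrow(fx$phantom$mesh$tets)
  set.seed(11)
  ds <- rnorm(E, 0, 1e-4)
  low <- sample(E, 400)
  ds[low] <- -0.3 + rnorm(400, 0, 1e-4)
  part <- compute_bin_partition(ds, fx$phantom$mesh, fx$phantom$electrodes)
  # 9 bins below the flat band, 5 above, the band itself is b10
  expect_identical(length(part$bin_edges), 16L)
  expect_true(all(diff(part$bin_edges) > 0))
  retained <- setdiff(seq_len(E), part$excluded_elements)
  lowr <- intersect(low, retained)
  expect_true(all(part$bin_index[lowr] <= 9))
  # background jitter stays out of the cluster-eligible bins and the
  # median background element sits in the flat band
  jitter <- setdiff(retained, low)
  expect_true(mean(part$bin_index[jitter] <= 8) < 0.01)
  med_el <- jitter[which.min(abs(ds[jitter] - median(ds[jitter])))]
  expect_identical(part$bin_index[med_el], 10L)
  # equal half-open bins: widths agree within each band
  expect_equal(diff(range(diff(part$bin_edges[1:10]))), 0, tolerance = 1e-12)
  expect_equal(diff(range(diff(part$bin_edges[11:16]))), 0, tolerance = 1e-12)
  # independent step-by-step reference gives the identical assignment
  expect_identical(unname(part$bin_index[retained]),
                   reference_bins(ds[retained]))
})

test_that("the chosen study cluster concentrates on the true bone region", {
  st <- study_run()
  run <- st$runs[[1]]                # cylinder, homogeneous reference
  inv <- run$shared$inverse
  ctr <- tet_centroids(inv$mesh)
  ids <- run$chosen$element_ids
  db <- sqrt(ctr[ids, 1]^2 + ctr[ids, 2]^2)   # concentric bone at r = 15 mm
  h <- mean_edge_length(inv$mesh)
  # the truncated one-step reconstruction smears the bone dip, so the
  # cluster carries a halo: it concentrates on the bone region (its
  # bone-overlap fraction is several times the region's share of the
  # thigh cross-section) without being confined to it
  frac <- mean(db <= 0.015 + h)
  area_share <- ((0.015 + h) / 0.06)^2       # dilated bone vs muscle area
  expect_gt(frac, 0.25)
  expect_gt(frac, 1.5 * area_share)
  expect_lt(median(db), 0.03)
})

test_that("uniform partition arithmetic matches the closed form", {
  edges <- seq(-0.9, -0.1, length.out = 10)
  expect_equal(unique(round(diff(edges), 10)), round(0.8 / 9, 10))
  expect_equal(edges[1], -0.9)
})

test_that("degenerate and undersized fields are rejected", {
  fx <- demo_fixture()
  E <- nrow(fx$phantom$mesh$tets)
  expect_error(compute_bin_partition(rep(1, E), fx$phantom$mesh,
                                     fx$phantom$electrodes),
               "degenerate|size")
  tiny <- two_tet_mesh()
  expect_error(compute_bin_partition(c(0, 1), tiny, list()), "size error")
})

test_that("region growing honours adjacency and the b_max gap", {
  mesh <- two_tet_mesh()
  cl <- grow_clusters(fake_partition(c(5L, 7L)), mesh)
  expect_length(cl, 1L)
  expect_identical(cl[[1]]$element_ids, c(1L, 2L))
  cl <- grow_clusters(fake_partition(c(7L, 8L)), mesh)
  expect_length(cl, 1L)
  expect_identical(cl[[1]]$element_ids, 1L)
  cl <- grow_clusters(fake_partition(c(8L, 9L)), mesh)
  expect_length(cl, 0L)
})

test_that("clusters equal the connected components of the low-bin subgraph", {
  skip_if_not_installed("igraph")
  set.seed(99)
  for (case in 1:50) {
    h <- sample(c(0.04, 0.05), 1)
    mesh <- cylinder_mesh(boundary_radii = c(0.04, 0.07), length = 0.1,
                          h = h, hz_fine = 0.03, hz_max = 0.05,
                          fine_halfwidth = 0.03)
    E <- nrow(mesh$tets)
    bins <- sample(1:15, E, replace = TRUE)
    cl <- grow_clusters(fake_partition(bins), mesh)
    # oracle: igraph components of the subgraph on bin <= 7 elements
    keep <- which(bins <= 7)
    adj <- face_adjacency(mesh)
    sub <- adj[bins[adj[, 1]] <= 7 & bins[adj[, 2]] <= 7, , drop = FALSE]
    g <- igraph::graph_from_edgelist(
      matrix(match(as.vector(sub), keep), ncol = 2), directed = FALSE)
    g <- igraph::add_vertices(g, max(0, length(keep) - igraph::vcount(g)))
    comp <- igraph::components(g)
    oracle <- lapply(split(keep, comp$membership), sort)
    mine <- lapply(cl, `[[`, "element_ids")
    expect_setequal(vapply(oracle, paste, "", collapse = ","),
                    vapply(mine, paste, "", collapse = ","))
  }
})

test_that("cluster filtering applies the size AND contact rule", {
  fx <- demo_fixture()
  mesh <- fx$phantom$mesh
  E <- nrow(mesh$tets)
  adj <- face_adjacency(mesh)
  nb <- adjacency_list(adj, E)
  grow_from <- function(seed, n) {
    sel <- seed
    repeat {
      front <- unique(unlist(lapply(sel, function(e)
        if (nb$counts[e] > 0) nb$to[nb$starts[e]:nb$ends[e]] else integer(0))))
      sel2 <- unique(c(sel, front))
      if (length(sel2) >= n || length(sel2) == length(sel)) {
        return(sel2[seq_len(min(n, length(sel2)))])
      }
      sel <- sel2
    }
  }
  bf <- boundary_faces(mesh)
  ctr <- tet_centroids(mesh)
  rr <- sqrt(ctr[, 1]^2 + ctr[, 2]^2)
  surf_seed <- bf$elem[which.max(abs(ctr[bf$elem, 3] - fx$phantom$z_m))]
  core_seed <- which.min(rr + abs(ctr[, 3] - fx$phantom$z_m))
  sets <- list(small_surface = grow_from(surf_seed, 40),
               big_surface = grow_from(surf_seed, 80),
               small_interior = grow_from(core_seed, 10))
  for (nm in names(sets)) {
    bins <- rep(10L, E)
    bins[sets[[nm]]] <- 1L
    cl <- grow_clusters(fake_partition(bins), mesh)
    kept <- filter_clusters(cl, mesh, fx$phantom$electrodes)
    if (nm == "small_surface") expect_length(kept, 0L)
    else expect_gte(length(kept), 1L)
  }
})

test_that("segmentation is a pure function of its inputs", {
  fx <- demo_fixture()
  E <- nrow(fx$phantom$mesh$tets)
  set.seed(5)
  ds <- rnorm(E, 0, 1e-4)
  ds[sample(E, 300)] <- -0.2
  p1 <- compute_bin_partition(ds, fx$phantom$mesh, fx$phantom$electrodes)
  p2 <- compute_bin_partition(ds, fx$phantom$mesh, fx$phantom$electrodes)
  expect_identical(p1$bin_index, p2$bin_index)
  c1 <- grow_clusters(p1, fx$phantom$mesh)
  c2 <- grow_clusters(p2, fx$phantom$mesh)
  expect_identical(c1, c2)
  # disjoint, face-connected, all in bins <= 7
  ids <- unlist(lapply(c1, `[[`, "element_ids"))
  expect_identical(length(ids), length(unique(ids)))
  expect_true(all(p1$bin_index[ids] <= 7))
})
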