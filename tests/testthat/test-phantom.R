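test_that("concentric cylinder phantom records the trivial axis", {
  ph <- tiny_phantom()
  expect_equal(ph$true_axis$n, c(0, 0, 1))
  expect_equal(ph$true_axis$o[1:2], c(0, 0))
  expect_equal(ph$true_axis$o[3], ph$z_m)
})

test_that("electrode belt matches the configured geometry", {
  ph <- tiny_phantom()
  belt <- Filter(function(e) e$role == "belt", ph$electrodes)
  expect_length(belt, 16L)
  expect_true(all(vapply(belt, function(e) e$diameter, 0) == 0.007))
  nodes <- lapply(ph$electrodes, `[[`, "nodes")
  expect_identical(length(unlist(nodes)), length(unique(unlist(nodes))))
  centz <- vapply(belt, function(e) mean(ph$mesh$vertices[e$nodes, 3]), 0)
  expect_true(all(abs(centz - ph$z_m) < mean_edge_length(ph$mesh)))
})

test_that("reference conductivities follow the tissue table", {
  # fine enough for every compartment, including the 7 mm marrow core,
  # to contain elements
  ph <- build_phantom("cylinder", mesh_density = 0.012, length = 0.06,
                      outer_ring_nodes = 48L, belt_hz = 0.008,
                      belt_halfwidth = 0.012, hz_max = 0.02)
  expect_setequal(unique(ph$tissue), c("skin", "fat_subcut", "muscle",
                                       "bone", "marrow"))
  f <- assign_conductivities(ph, "cfg1")
  expect_equal(unique(f$sigma[ph$tissue == "muscle"]), 0.37)
  expect_equal(unique(f$sigma[ph$tissue == "marrow"]), 0.002)
  expect_equal(unique(f$sigma[ph$tissue == "bone"]), 0.02)
  expect_equal(unique(f$sigma[ph$tissue == "skin"]), 0.065)
  expect_error(assign_conductivities(ph, "cfg1", frequency = 5e4),
               "frequency")
  bad <- tiny_phantom()
  bad$tissue[1] <- "cartilage"
  expect_error(assign_conductivities(bad, "cfg1"), "unknown tissue")
})

test_that("boneless fields replace bone and marrow by muscle", {
  ph <- tiny_phantom()
  for (cfgn in c("cfg1_homogeneous", "cfg2_skin_fat", "cfg3_skin_fat_intra")) {
    b <- make_boneless(ph, cfgn)
    expect_length(b$sigma, nrow(ph$mesh$tets))
    expect_false(any(b$sigma %in% c(0.02, 0.002)))
    # idempotence: the boneless map only depends on labels
    expect_identical(b$sigma, make_boneless(ph, cfgn)$sigma)
  }
  expect_equal(unique(make_boneless(ph, "cfg1")$sigma), 0.37)
  b2 <- make_boneless(ph, "cfg2")
  expect_equal(unique(b2$sigma[ph$tissue == "skin"]), 0.065)
  expect_equal(unique(b2$sigma[ph$tissue == "fat_subcut"]), 0.03)
  expect_equal(unique(b2$sigma[ph$tissue == "bone"]), 0.37)
})

test_that("identity deformation reproduces the cylinder boundary", {
  dp0 <- deform_params(scale = c(1, 1), amp = c(0, 0), shift = c(0, 0))
  cyl <- build_phantom("cylinder", mesh_density = 0.035, length = 0.12,
                       outer_ring_nodes = 48L, belt_hz = 0.01,
                       belt_halfwidth = 0.02, hz_max = 0.03)
  real <- build_phantom("realistic", mesh_density = 0.035, length = 0.12,
                        deform_params = dp0, bone_tilt_deg = 0,
                        intra_fat = FALSE, outer_ring_nodes = 48L,
                        belt_hz = 0.01, belt_halfwidth = 0.02, hz_max = 0.03)
  expect_equal(real$mesh$vertices, cyl$mesh$vertices, tolerance = 1e-12)
})

test_that("marrow centroids recover the ground-truth axis", {
  ph <- build_phantom("realistic", mesh_density = 0.018, length = 0.2,
                      seed = 3)
  ctr <- tet_centroids(ph$mesh)
  marrow <- ctr[ph$tissue == "marrow", , drop = FALSE]
  fit <- initial_axis_svd(marrow)
  h <- mean_edge_length(ph$mesh)
  # centre of the fitted line at the electrode plane vs truth
  pb <- fit$p_b + (ph$z_m - fit$p_b[3]) / fit$n_b[3] * fit$n_b
  expect_lt(sqrt(sum((pb[1:2] - ph$true_axis$o[1:2])^2)), h)
})

test_that("infeasible bone placement is rejected", {
  expect_error(build_phantom("cylinder", bone_offset = c(0.05, 0),
                             mesh_density = 0.03),
               "geometry")
})
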