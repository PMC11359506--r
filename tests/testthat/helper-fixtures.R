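# Session-cached fixtures so expensive objects are built once per test run.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# small cylinder phantom for forward-solver tests (~3k tets)
tiny_phantom <- function() {
  cached("tiny_phantom", function() {
    build_phantom("cylinder", mesh_density = 0.035, length = 0.12,
                  outer_ring_nodes = 48L, belt_hz = 0.01,
                  belt_halfwidth = 0.02, hz_max = 0.03)
  })
}

tiny_system <- function() {
  cached("tiny_system", function() {
    ph <- tiny_phantom()
    cem_system(ph$mesh, make_boneless(ph, "cfg1"), ph$electrodes)
  })
}

demo_fixture <- function() {
  cached("demo_fixture", function() suppressWarnings(make_demo_fixture()))
}

# same fixture with the skin+fat reference: its voltage difference carries
# the bone signal only, giving a clean reconstruction for localization tests
demo_fixture_cfg2 <- function() {
  cached("demo_fixture_cfg2", function() {
    suppressWarnings(make_demo_fixture(config = "cfg2_skin_fat"))
  })
}

# the five-model study at the package's reduced scale, shared by the
# acceptance tests
study_run <- function() {
  cached("study", function() suppressWarnings(run_study(seed = 1L)))
}

angle_deg <- function(u, v) {
  acos(pmin(1, abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2)))) * 180 / pi
}

# deterministic point cloud filling a cylinder of radius r about an axis
cylinder_cloud <- function(n, radius, length, axis, seed = 1) {
  set.seed(seed)
  u <- axis / sqrt(sum(axis^2))
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * u) * u; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2], u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  t <- runif(n, -length / 2, length / 2)
  r <- radius * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  outer(t, u) + outer(r * cos(th), e1) + outer(r * sin(th), e2)
}
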