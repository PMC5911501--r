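# Derived quantities: orifice area, rotation angle, lambda2, stress field,
# and the output writers.

test_that("orifice area: full disc with no leaflets, half coverage, closed = 0", {
  # closure line across a plain channel with no solid cells: full width
  m <- rectangle_mesh(8, 6, 0.04, 0.02)
  m$metadata$axis <- c(1, 0)
  # tag an interior vertical line as closure
  xs <- sort(unique(m$vertices[, 1]))
  xmid <- xs[4]
  vids <- which(abs(m$vertices[, 1] - xmid) < 1e-12)
  vids <- vids[order(m$vertices[vids, 2])]
  cl <- cbind(vids[-length(vids)], vids[-1])
  m$facets <- rbind(m$facets, cl)
  m$facet_tags <- c(m$facet_tags, rep(5L, nrow(cl)))
  m$facet_names <- c(m$facet_names, closure = 5L)
  th <- initial_phase(m)
  expect_equal(geometric_orifice_area(m, th, n_samples = 2000), 0.02,
               tolerance = 1e-6)
  # constructed occlusion: mark cells covering the lower half as solid
  m2 <- m
  cent <- (m2$vertices[m2$cells[, 1], ] + m2$vertices[m2$cells[, 2], ] +
           m2$vertices[m2$cells[, 3], ]) / 3
  occl <- cent[, 2] < 0.01 & cent[, 1] > xmid + 0.004
  m2$region_tags[occl] <- 2L
  m2$region_names <- c(fluid = 1L, leaflet1 = 2L)
  th2 <- initial_phase(m2)
  expect_equal(geometric_orifice_area(m2, th2, n_samples = 4000), 0.01,
               tolerance = 5e-4)
  # closed valve: GOA exactly zero
  ch <- small_channel()
  thc <- initial_phase(ch)
  cc <- check_and_close(ch, thc, contact_state(1e-3), d_min = 1e-4)
  expect_identical(geometric_orifice_area(ch, cc$theta), 0)
})

test_that("GOA stays within [0, closure area] and is 0 iff closed on the fixture", {
  ch <- small_channel()
  th <- initial_phase(ch)
  area <- sum(valvefsi:::facet_measures(ch$vertices, facet_set(ch, "closure")))
  g <- geometric_orifice_area(ch, th, n_samples = 2000)
  expect_gte(g, 0); expect_lte(g, area)
  expect_gt(g, 0)  # open valve
})

test_that("rotation angle recovers synthetic rigid rotations exactly", {
  set.seed(41)
  pts0 <- cbind(runif(40, 0, 0.01), runif(40, -0.008, 0.008), 0)
  axis <- list(point = c(0, 0, 0), direction = c(0, 1, 0))
  ref <- c(1, 0, 0)
  expect_equal(rotation_angle(pts0, axis, ref), 0, tolerance = 1e-9)
  for (ang in c(15, 30, 45, 80)) {
    a <- ang * pi / 180
    R <- matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
    expect_equal(rotation_angle(pts0 %*% t(R), axis, ref), ang,
                 tolerance = 1e-6)
  }
  # degenerate: all vertices on the axis
  expect_error(rotation_angle(cbind(0, 1:5, 0), axis, ref), "degenerate")
  # constant angle series -> zero angular velocity
  om <- angular_velocity(rep(12, 6), seq(0, 1, length.out = 6))
  expect_true(all(om == 0))
  # linear series -> constant rate
  om2 <- angular_velocity(2 * (0:5), 0:5)
  expect_true(all(abs(om2 - 2) < 1e-12))
})

test_that("lambda2: rigid rotation gives -|omega|^2, uniform flow 0, pure strain >= 0", {
  b <- generate_bmhv(bmhv_params(mesh_size = 4))
  co <- b$vertices
  omega <- c(0.3, -0.2, 0.9)
  U <- t(apply(co, 1, function(x) c(omega[2] * x[3] - omega[3] * x[2],
                                    omega[3] * x[1] - omega[1] * x[3],
                                    omega[1] * x[2] - omega[2] * x[1])))
  l2 <- lambda2_field(U, b)
  expect_equal(max(abs(l2$cell + sum(omega^2))), 0, tolerance = 1e-9)
  # uniform flow
  U0 <- matrix(rep(c(1, 2, 3), each = nrow(co)), nrow(co))
  expect_equal(max(abs(lambda2_field(U0, b)$cell)), 0, tolerance = 1e-12)
  # irrotational pure strain: lambda2 >= 0 (no vortex)
  Us <- cbind(0.5 * co[, 1], 0.2 * co[, 2], -0.7 * co[, 3])
  expect_true(all(lambda2_field(Us, b)$cell >= -1e-12))
  # Galilean invariance
  expect_equal(lambda2_field(U + U0, b)$cell, l2$cell, tolerance = 1e-9)
  # 2D unsupported
  expect_error(lambda2_field(matrix(0, 4, 2), rectangle_mesh(2, 2)), "3D")
})

test_that("von Mises field: quiescent uniform pressure is 0; analytic shear matches", {
  ch <- small_channel()
  th <- initial_phase(ch)
  st <- initial_state(ch)
  st$P[] <- 7.3
  vm <- von_mises_field(st, ch, th, material_constants())
  expect_equal(max(abs(vm)), 0, tolerance = 1e-12)
  # linear shear flow u = (gamma * y, 0): fluid cells see sqrt(2) mu gamma
  gam <- 4
  st$U <- cbind(gam * ch$vertices[, 2], 0)
  st$P[] <- 0
  vm <- von_mises_field(st, ch, th, material_constants())
  fl <- which(th == 1L)
  expect_equal(vm[fl], rep(sqrt(2) * 0.0027 * gam / 2 * 2, length(fl)),
               tolerance = 1e-9)
  # log-scale output inverts back to the linear values
  vml <- von_mises_field(st, ch, th, material_constants(), log_scale = TRUE)
  expect_equal(10^vml[fl], vm[fl], tolerance = 1e-9)
})

test_that("output writers emit a consistent VTU/PVD/XDMF/CSV set", {
  ch <- small_channel()
  cfg <- utils::modifyList(default_config(), list(
    cycle = list(U_peak = 0),
    solver = list(t_end = 0.02, dt_max = 0.005),
    output = list(save_every = 2L)))
  tr <- run_simulation(cfg, ch)
  out <- withr::local_tempdir()
  files <- write_outputs(tr, out)
  expect_true(file.exists(file.path(out, "series.pvd")))
  expect_true(file.exists(file.path(out, "timeseries.csv")))
  expect_true(file.exists(file.path(out, "final.xdmf")))
  csv <- utils::read.csv(file.path(out, "timeseries.csv"))
  expect_equal(nrow(csv), nrow(tr$timeseries))
  expect_true(all(c("t", "dt", "goa", "d_min", "Q_max") %in% names(csv)))
  # round trip of the final snapshot mesh
  mm <- read_mesh(file.path(out, "final.xdmf"))
  expect_equal(nrow(mm$vertices), nrow(ch$vertices))
  # empty trajectory warns and writes nothing
  expect_warning(write_outputs(list(snapshots = list()), withr::local_tempdir()),
                 "empty")
})
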