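# Inflow waveform, cycle events, boundary data, radial pre-stress.

test_that("waveform is periodic with the 1.124 s cycle and has the right phases", {
  cfg <- cycle_config()
  expect_equal(cfg$T_cycle, 1.124)
  # diastole: zero inflow
  expect_equal(inflow_magnitude(cfg$T_systole + cfg$T_reversal + 1e-6, cfg), 0)
  expect_equal(inflow_magnitude(1.0, cfg), 0)
  # exact periodicity
  ts <- seq(0, 1.1, by = 0.013)
  expect_equal(inflow_magnitude(ts, cfg), inflow_magnitude(ts + 1.124, cfg))
  # forward pulse positive, reversal lobe negative
  expect_gt(inflow_magnitude(0.2, cfg), 0)
  expect_lt(inflow_magnitude(cfg$T_systole + cfg$T_reversal / 2, cfg), 0)
  # integral over the reversal window is negative
  tt <- seq(cfg$T_systole, cfg$T_systole + cfg$T_reversal, length.out = 200)
  expect_lt(sum(inflow_magnitude(tt, cfg)) * diff(tt[1:2]), 0)
  # continuity of the pulse except at the documented reversal onset
  expect_equal(inflow_magnitude(cfg$T_systole - 1e-9, cfg), 0, tolerance = 1e-6)
})

test_that("cycle events fire exactly once per boundary, in order", {
  cfg <- cycle_config()
  expect_identical(cycle_events(1.12, 1.13, cfg), c("cycle_start", "systole_start"))
  expect_identical(cycle_events(0.6, 0.7, cfg), character(0))
  # step spanning two boundaries emits both, ordered
  ev <- cycle_events(0.39, 0.46, cfg)
  expect_identical(ev, c("reversal_start", "diastole_start"))
  # over N cycles each event appears exactly N times
  tgrid <- seq(0, 3 * 1.124, length.out = 300)  # events at T, 2T, 3T crossed
  all_ev <- unlist(lapply(seq_len(length(tgrid) - 1L), function(i)
    cycle_events(tgrid[i], tgrid[i + 1L], cfg)))
  expect_equal(unname(table(all_ev)["cycle_start"]), 3L)
  expect_equal(unname(table(all_ev)["diastole_start"]), 3L)
  expect_equal(unname(table(all_ev)["reversal_start"]), 3L)
})

test_that("boundary data: flat inlet profile, no-slip walls, weak outlet", {
  m <- rectangle_mesh(6, 4, 0.06, 0.02)
  m$metadata$axis <- c(1, 0)
  cfg <- cycle_config(U_peak = 0.8)
  bcs <- apply_bcs(m, t = 0.2, cfg)
  inlet <- facet_set_vertices(m, "inlet")
  sp <- inflow_magnitude(0.2, cfg)
  vin <- bcs$velocity$values[match(inlet, bcs$velocity$idx), ]
  expect_true(all(vin[, 1] == sp))          # identical normal speed: flat
  expect_true(all(vin[, 2] == 0))
  # diastole: inlet velocity zero
  bcs0 <- apply_bcs(m, t = 1.0, cfg)
  vin0 <- bcs0$velocity$values[match(inlet, bcs0$velocity$idx), ]
  expect_true(all(vin0 == 0))
  # walls no-slip
  wall <- setdiff(facet_set_vertices(m, "wall"), inlet)
  vw <- bcs$velocity$values[match(wall, bcs$velocity$idx), ]
  expect_true(all(vw == 0))
  # no strong pressure constraint: the outlet condition is weak
  expect_null(bcs$pressure)
  expect_error(apply_bcs(rectangle_mesh(2, 2, tag_boundary = FALSE), 0, cfg),
               "facet set")
})

test_that("pre-stress pulls the leaflet free edges radially inward, monotonically in sigma_r", {
  root <- coarse_root()
  # sigma_r = 0: identity
  p0 <- prestress_initialize(root, config = prestress_config(sigma_r = 0))
  expect_identical(p0$coords, root$vertices)
  ps <- prestress_initialize(root, config = prestress_config(sigma_r = 4))
  expect_gt(max(abs(ps$displacement)), 0)
  # free-edge vertices: leaflet vertices on the local free-edge rim
  lv <- unique(as.vector(root$cells[root$region_tags > 1L, ]))
  prm <- root$metadata$params
  phi <- atan2(root$vertices[lv, 2], root$vertices[lv, 1])
  zfree <- valvefsi:::root_free_edge_height(phi, structure(prm, class = "root_params"))
  rim <- lv[root$vertices[lv, 3] * 1000 > zfree - prm$mesh_size / 2]
  r0 <- sqrt(rowSums(root$vertices[rim, 1:2]^2))
  r1 <- sqrt(rowSums(ps$coords[rim, 1:2]^2))
  expect_lt(mean(r1 - r0), 0)     # free edge moves inward on average
  # doubling sigma_r doubles the (linear-response) displacement
  ps2 <- prestress_initialize(root, config = prestress_config(sigma_r = 8))
  d1 <- mean(sqrt(rowSums(ps$displacement[rim, ]^2)))
  d2 <- mean(sqrt(rowSums(ps2$displacement[rim, ]^2)))
  expect_gt(d2, d1)
})

test_that("pre-stress relaxation step size is non-increasing after warm-up", {
  root <- coarse_root()
  ps <- prestress_initialize(root, config = prestress_config(sigma_r = 4))
  sn <- ps$step_norms
  expect_gt(length(sn), 10)
  tail_part <- sn[-(1:10)]
  expect_true(all(diff(tail_part) <= 1e-12))
})
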