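# Collision detection, phase-switch closure/release, hinge locking,
# mean pressure probes.

test_that("geometric distance equals the brute-force vertex/facet minimum", {
  ch <- small_channel()
  d <- leaflet_distance(ch, "leaflet1", "leaflet2", method = "geometric")
  expect_equal(d, ch$metadata$gap, tolerance = 1e-12)
  # brute force over all vertex-facet pairs
  s1 <- valvefsi:::region_surface(ch, "leaflet1")
  s2 <- valvefsi:::region_surface(ch, "leaflet2")
  bf <- Inf
  for (f in seq_len(nrow(s2))) for (v in unique(as.vector(s1)))
    bf <- min(bf, valvefsi:::point_facet_distance(ch$vertices[v, ],
              ch$vertices[s2[f, ], , drop = FALSE]))
  for (f in seq_len(nrow(s1))) for (v in unique(as.vector(s2)))
    bf <- min(bf, valvefsi:::point_facet_distance(ch$vertices[v, ],
              ch$vertices[s1[f, ], , drop = FALSE]))
  expect_equal(d, bf)
  # random leaflet displacement: still matches brute force
  set.seed(31)
  co <- ch$vertices
  l2v <- unique(as.vector(ch$cells[ch$region_tags == 3L, ]))
  co[l2v, 2] <- co[l2v, 2] - 5e-4   # top leaflet moved toward the bottom one
  d2 <- leaflet_distance(ch, "leaflet1", "leaflet2", coords = co)
  expect_lt(abs(d2 - (ch$metadata$gap - 5e-4)), 1e-12)
})

test_that("touching surfaces report zero distance (shared vertices)", {
  # two triangles sharing an edge, tagged as distinct regions
  verts <- rbind(c(0, 0), c(1, 0), c(0.5, 1), c(0.5, -1))
  cells <- rbind(c(1, 2, 3), c(1, 4, 2))
  m <- fsi_mesh(verts, cells, region_tags = c(2L, 3L),
                region_names = c(fluid = 1L, leaflet1 = 2L, leaflet2 = 3L))
  expect_equal(leaflet_distance(m, "leaflet1", "leaflet2"), 0)
})

test_that("Eikonal distance brackets the geometric distance within 2h", {
  # parallel-strip fixture: distance from the left edge across a rectangle
  m <- rectangle_mesh(12, 6, Lx = 1, Ly = 0.5)
  src <- facet_set(m, "inlet")
  phi <- eikonal_distance(m, src)
  h <- max(cell_diameters(m))
  exact <- m$vertices[, 1]
  expect_true(all(phi - exact >= -1e-9))        # lower bound: true distance
  expect_true(all(phi - exact <= 2 * h + 1e-9)) # consistency band
  # surface-to-surface: inlet to outlet across the rectangle
  d_geo <- 1
  tgt <- facet_set_vertices(m, "outlet")
  d_eik <- min(phi[tgt])
  expect_gte(d_eik, d_geo - 1e-9)
  expect_lte(d_eik, d_geo + 2 * h)
  # and through leaflet_distance on the channel fixture
  ch <- small_channel()
  dg <- leaflet_distance(ch, "leaflet1", "leaflet2", method = "geometric")
  de <- leaflet_distance(ch, "leaflet1", "leaflet2", method = "eikonal")
  h2 <- 2 * max(cell_diameters(ch))
  expect_gte(de, dg - 1e-9)
  expect_lte(de, dg + h2)
})

test_that("closure switches exactly the upstream layer and is idempotent", {
  ch <- small_channel()
  th <- initial_phase(ch)
  cs <- contact_state(1e-3)
  # far apart: no change
  cc <- check_and_close(ch, th, cs, d_min = 1e-2)
  expect_identical(cc$theta, th)
  expect_false(cc$contact$closed)
  # below threshold: the upstream cells attached under the closure line flip
  cc <- check_and_close(ch, th, cs, d_min = 5e-4)
  expect_true(cc$contact$closed)
  layer <- valvefsi:::closure_layer_cells(ch)
  expect_setequal(cc$contact$closed_cells, layer[th[layer] == 1L])
  expect_true(all(cc$theta[cc$contact$closed_cells] == 0L))
  expect_equal(length(cc$theta), nrow(ch$cells)) # cell count conserved
  # idempotent
  cc2 <- check_and_close(ch, cc$theta, cc$contact, d_min = 5e-4)
  expect_identical(cc2$theta, cc$theta)
  expect_identical(cc2$contact$closed_cells, cc$contact$closed_cells)
})

test_that("release restores the phase field exactly and zeroes switched stress", {
  ch <- small_channel()
  th <- initial_phase(ch)
  cc <- check_and_close(ch, th, contact_state(1e-3), d_min = 1e-4)
  tau <- zero_cell_tensors(nrow(ch$cells), 2L)
  tau[cc$contact$closed_cells, 1] <- 99
  # diastole event: no release
  rl <- release_contact(cc$theta, cc$contact, tau, "diastole_start")
  expect_identical(rl$theta, cc$theta)
  # systole start: exact round trip
  rl <- release_contact(cc$theta, cc$contact, tau, "systole_start")
  expect_identical(rl$theta, th)
  expect_true(all(rl$tau_s[cc$contact$closed_cells, ] == 0))
  expect_false(rl$contact$closed)
})

test_that("close/release is reproducible over repeated cycles on a rigid fixture", {
  ch <- small_channel()
  th <- initial_phase(ch)
  tau <- zero_cell_tensors(nrow(ch$cells), 2L)
  cs <- contact_state(1e-3)
  first <- NULL
  for (cycle in 1:3) {
    cc <- check_and_close(ch, th, cs, d_min = 1e-4)
    if (is.null(first)) first <- cc$contact$closed_cells
    expect_identical(cc$contact$closed_cells, first)
    rl <- release_contact(cc$theta, cc$contact, tau, "systole_start")
    th <- rl$theta; cs <- rl$contact; tau <- rl$tau_s
  }
})

test_that("hinge locking follows the release-before-lock state machine", {
  hs <- hinge_state(2, alpha_max = 45, alpha_closed = 0)
  # drive past 45 degrees: locks open, reported angle clamped at 45
  hs <- update_hinge(hs, c(50, 30), dt = 0.01, p_above = 0, p_below = 1)
  expect_true(hs$locked_open[1]); expect_false(hs$locked_open[2])
  expect_equal(hs$alpha[1], 45)
  # pressure above exceeds below: released (and not re-locked in the same step)
  hs <- update_hinge(hs, c(44, 30), dt = 0.01, p_above = 2, p_below = 1)
  expect_false(hs$locked_open[1])
  # closing: alpha <= 0 locks closed
  hs <- update_hinge(hs, c(-1, 30), dt = 0.01, p_above = 0, p_below = 1)
  expect_true(hs$locked_closed[1])
  expect_equal(hs$alpha[1], 0)
  # stays locked through diastole ...
  hs <- update_hinge(hs, c(5, 30), dt = 0.01, p_above = 0, p_below = 1)
  expect_true(hs$locked_closed[1])
  # ... and releases when a new cycle starts
  hs <- update_hinge(hs, c(5, 30), dt = 0.01, p_above = 0, p_below = 1,
                     new_cycle = TRUE)
  expect_false(hs$locked_closed[1])
})

test_that("mean pressure is the exact area-weighted integral for P1 fields", {
  m <- rectangle_mesh(4, 4)
  P <- rep(3.5, nrow(m$vertices))
  expect_equal(mean_pressure(P, m, "inlet"), 3.5)
  # linear field: mean over the inlet (x = 0) equals the value at its centroid
  P <- 2 * m$vertices[, 1] + 5 * m$vertices[, 2] + 1
  expect_equal(mean_pressure(P, m, "inlet"), 5 * 0.5 + 1, tolerance = 1e-12)
  # two equal-length facets with facet means a, b -> (a + b) / 2
  inlet <- facet_set(m, "inlet")
  ord <- order(m$vertices[inlet[, 1], 2])
  probe <- inlet[ord[1:2], , drop = FALSE]
  shared <- intersect(probe[1, ], probe[2, ])
  Pv <- numeric(nrow(m$vertices))
  Pv[probe[1, ]] <- 2                       # facet 1 mean: 2
  Pv[setdiff(probe[2, ], shared)] <- 10     # facet 2 mean: (2 + 10)/2 = 6
  expect_equal(mean_pressure(Pv, m, probe), 4)
  expect_error(mean_pressure(P, m, matrix(integer(0), 0, 2)), "empty probe")
})
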