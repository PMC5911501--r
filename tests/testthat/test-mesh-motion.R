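# Linear (Poisson) and nonlinear (quality-weighted) mesh smoothers.

test_that("linear smoother reproduces harmonic extensions", {
  m <- rectangle_mesh(8, 4)
  th <- initial_phase(m)
  n <- nrow(m$vertices)
  # zero interface data -> zero mesh velocity
  iv <- facet_set_vertices(m, "inlet")
  M0 <- linear_smooth(m, th, list(idx = iv, values = matrix(0, length(iv), 2)),
                      fixed_boundary_tags = c("outlet", "wall"))
  expect_equal(max(abs(M0)), 0)
  # uniform Dirichlet data c everywhere -> M == c (discrete maximum principle)
  bidx <- sort(unique(as.vector(m$facets)))
  cvec <- c(0.3, -0.1)
  Mc <- linear_smooth(m, th, list(idx = bidx,
                                  values = matrix(rep(cvec, each = length(bidx)),
                                                  length(bidx))),
                      fixed_boundary_tags = character(0))
  expect_equal(Mc, matrix(rep(cvec, each = n), n), tolerance = 1e-10)
  # strip with M = 1 on the left, 0 on the right: harmonic solution is the
  # linear interpolant in x
  lv <- facet_set_vertices(m, "inlet")
  Ml <- linear_smooth(m, th, list(idx = lv, values = cbind(1, 0)[rep(1, length(lv)), ]),
                      fixed_boundary_tags = c("outlet"))
  expect_equal(Ml[, 1], 1 - m$vertices[, 1], tolerance = 1e-9)
  # no Dirichlet data at all -> singular
  expect_error(linear_smooth(m, th, list(idx = integer(0),
                                         values = matrix(0, 0, 2)),
                             fixed_boundary_tags = character(0)),
               "no Dirichlet data")
})

test_that("nonlinear smoother is the identity on an optimal patch and with zero budget", {
  # a patch of equilateral triangles: hexagon around a centre vertex
  ang <- 2 * pi * (0:5) / 6
  verts <- rbind(c(0, 0), cbind(cos(ang), sin(ang)))
  cells <- cbind(1, 2:7, c(3:7, 2))
  m <- fsi_mesh(verts, cells, facets = cbind(2:7, c(3:7, 2)),
                facet_tags = rep(3L, 6), facet_names = c(wall = 3L))
  out <- nonlinear_smooth(m, smoothing_config(pseudo_steps = 10), free_vertices = 1L)
  expect_lt(max(abs(out$coords - verts)), 1e-9)
  expect_equal(out$Q_max, 1, tolerance = 1e-12)
  # zero pseudo steps: identity
  out0 <- nonlinear_smooth(m, smoothing_config(pseudo_steps = 0), free_vertices = 1L)
  expect_identical(out0$coords, verts)
  expect_identical(out0$steps, 0L)
})

test_that("nonlinear smoother relaxes a displaced vertex and decreases Q_max", {
  ang <- 2 * pi * (0:5) / 6
  verts <- rbind(c(0.55, 0.3), cbind(cos(ang), sin(ang)))  # centre pushed out
  cells <- cbind(1, 2:7, c(3:7, 2))
  m <- fsi_mesh(verts, cells, facets = cbind(2:7, c(3:7, 2)),
                facet_tags = rep(3L, 6), facet_names = c(wall = 3L))
  q0 <- quality_report(m)$Q_max
  out <- nonlinear_smooth(m, smoothing_config(pseudo_steps = 40, pseudo_dt = 0.3),
                          free_vertices = 1L)
  expect_lt(out$Q_max, q0)
  # the centre moved back toward the origin
  expect_lt(sqrt(sum(out$coords[1, ]^2)), sqrt(sum(verts[1, ]^2)))
})

test_that("pseudo steps never invert cells and never increase Q_max", {
  set.seed(21)
  m <- rectangle_mesh(6, 6)
  coords <- m$vertices
  inner <- setdiff(seq_len(nrow(coords)), unique(as.vector(m$facets)))
  coords[inner, ] <- coords[inner, ] +
    matrix(runif(2 * length(inner), -0.05, 0.05), ncol = 2)
  q0 <- max(mesh_cell_quality(coords, m$cells, 2L))
  qprev <- q0
  cur <- coords
  for (k in 1:5) {
    out <- nonlinear_smooth(m, smoothing_config(pseudo_steps = 1, pseudo_dt = 0.5),
                            free_vertices = inner, coords = cur)
    expect_true(all(simplex_signed_measures(out$coords, m$cells) > 0))
    expect_lte(out$Q_max, qprev + 1e-9)
    qprev <- out$Q_max
    cur <- out$coords
  }
  expect_lt(qprev, q0)
})

test_that("smoothed coordinate updates keep an oscillating-boundary mesh untangled", {
  m <- rectangle_mesh(10, 5)
  th <- initial_phase(m)
  iv <- facet_set_vertices(m, "inlet")
  coords <- m$vertices
  dt <- 0.02
  for (k in 1:25) {
    vel <- 0.5 * sin(2 * pi * k / 25)
    Mv <- linear_smooth(m, th, list(idx = iv,
                                    values = cbind(vel, 0)[rep(1, length(iv)), ]),
                        fixed_boundary_tags = c("outlet", "wall"), coords = coords)
    Mv[iv, ] <- cbind(vel, 0)
    coords <- coords + dt * Mv
    expect_true(all(simplex_signed_measures(coords, m$cells) > 0))
  }
})
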