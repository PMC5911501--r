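# Parametric geometry generators: aortic root, BMHV, 2D valve channel.

test_that("parameter invariants are enforced", {
  expect_error(root_params(t_l = 10, h_l = 20, h_c = 25),
               class = "valvefsi_geometry_error")   # h_c > h_l
  expect_error(root_params(beta = 150), class = "valvefsi_geometry_error")
  expect_error(root_params(R_A = -1), class = "valvefsi_geometry_error")
  expect_error(bmhv_params(initial_angle = 60), class = "valvefsi_geometry_error")
  expect_error(bmhv_params(leaflet_chord = 40, aorta_radius = 12),
               class = "valvefsi_geometry_error")
  expect_error(bmhv_params(hinge_offset = 0), class = "valvefsi_geometry_error")
})

test_that("aortic root: measured radii equal the Table-1 inputs", {
  root <- coarse_root()
  rr <- root_rim_radii(root)
  expect_equal(unname(rr["annulus"]), 20, tolerance = 0.01)
  expect_equal(unname(rr["sinotubular"]), 22, tolerance = 0.01)
  # leaflet height reaches h_l at the commissures
  lv <- unique(as.vector(root$cells[root$region_tags > 1L, ]))
  expect_equal(max(root$vertices[lv, 3]) * 1000, 20, tolerance = 0.01 * 20)
  expect_equal(min(root$vertices[lv, 3]), 0)
})

test_that("aortic root is a valid tagged mesh with a closure surface", {
  root <- coarse_root()
  expect_true(all(cell_volumes(root) > 0))
  expect_setequal(names(root$region_names),
                  c("fluid", "leaflet1", "leaflet2", "leaflet3"))
  expect_true(all(table(root$region_tags[root$region_tags > 1L]) > 0))
  # closure facets are interior: shared by exactly two cells
  cf <- facet_set(root, "closure")
  expect_gt(nrow(cf), 0)
  adj <- facet_adjacency(root, cf)
  expect_true(all(!is.na(adj)))
  # tag partition: every cell has exactly one region tag (by construction);
  # boundary facets are fully covered by inlet/outlet/wall
  bf <- boundary_facets(root)
  expect_equal(nrow(bf), sum(root$facet_tags != root$facet_names[["closure"]]))
})

test_that("aortic root has threefold symmetry under 120-degree rotation", {
  root <- coarse_root()
  R <- matrix(c(cos(2 * pi / 3), sin(2 * pi / 3), 0,
                -sin(2 * pi / 3), cos(2 * pi / 3), 0,
                0, 0, 1), 3, 3)
  h <- min_diameter(root)
  for (k in 1:3) {
    a <- unique(as.vector(root$cells[root$region_tags == 1L + k, ]))
    b <- unique(as.vector(root$cells[root$region_tags == 1L + (k %% 3) + 1L, ]))
    va <- root$vertices[a, ] %*% t(R)
    vb <- root$vertices[b, ]
    haus <- max(apply(va, 1, function(p) min(sqrt(colSums((t(vb) - p)^2)))))
    expect_lt(haus, h / 2)
  }
})

test_that("BMHV: hinge metadata, angles, and initial configuration", {
  p <- bmhv_params(initial_angle = 45, mesh_size = 3)
  b <- generate_bmhv(p)
  expect_equal(b$metadata$alpha_max, 45)
  expect_true(all(cell_volumes(b) > 0))
  # two disjoint leaflets, no shared vertices at the initial angle
  l1 <- unique(as.vector(b$cells[b$region_tags == 2L, ]))
  l2 <- unique(as.vector(b$cells[b$region_tags == 3L, ]))
  expect_length(intersect(l1, l2), 0)
  # measured rotation angle of the generated leaflet matches initial_angle
  h1 <- b$metadata$hinges[[1]]
  a <- rotation_angle(b$vertices[l1, ], h1, h1$closed_ref)
  expect_equal(a, 45, tolerance = 3)
  # closed valve: leaflets lie in the hinge plane
  b0 <- generate_bmhv(bmhv_params(initial_angle = 0, mesh_size = 3))
  l1 <- unique(as.vector(b0$cells[b0$region_tags == 2L, ]))
  h1 <- b0$metadata$hinges[[1]]
  expect_lt(abs(rotation_angle(b0$vertices[l1, ], h1, h1$closed_ref)), 4)
  zs <- b0$vertices[l1, 3]
  expect_lt(diff(range(zs)) * 1000, 3 * 3)  # thin slab around the hinge plane
})

test_that("2D valve channel: tags partition the cells and errors are caught", {
  ch <- small_channel()
  expect_gt(sum(ch$region_tags == 1L), 0)
  expect_gt(sum(ch$region_tags == 2L), 0)
  expect_gt(sum(ch$region_tags == 3L), 0)
  expect_equal(length(ch$region_tags), nrow(ch$cells))
  # closure facets are interior and span the channel height
  cf <- facet_set(ch, "closure")
  expect_true(all(!is.na(facet_adjacency(ch, cf))))
  ys <- range(ch$vertices[unique(as.vector(cf)), 2])
  expect_equal(ys, c(0, 0.02))
  expect_error(generate_2d_valve_channel(0.06, 0.02, 0.025, 0.002, 0.0025),
               class = "valvefsi_geometry_error")  # leaflet taller than channel
  expect_error(generate_2d_valve_channel(0.06, 0.02, 0.008, 0, 0.0025),
               class = "valvefsi_geometry_error")  # zero thickness
})

test_that("halving the mesh size quadruples the 2D cell count (approximately)", {
  c1 <- generate_2d_valve_channel(0.06, 0.02, 0.0085, 0.0022, 0.0030, 1L, 0.02)
  c2 <- generate_2d_valve_channel(0.06, 0.02, 0.0085, 0.0022, 0.0015, 1L, 0.02)
  ratio <- nrow(c2$cells) / nrow(c1$cells)
  expect_gt(ratio, 3)
  expect_lt(ratio, 5.5)
})
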