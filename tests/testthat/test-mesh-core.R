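# Mesh container, per-cell geometry, quality measure, and mesh I/O.

test_that("quality measure is 1 on equilateral simplices and matches direct evaluation", {
  # equilateral triangles of several sizes/positions
  for (s in c(1, 0.01, 37)) {
    tri <- rbind(c(0, 0), c(s, 0), c(s / 2, s * sqrt(3) / 2)) + 3.2
    expect_equal(cell_quality(tri), 1, tolerance = 1e-12)
  }
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  expect_equal(cell_quality(tet), 1, tolerance = 1e-12)

  # right isoceles triangle: build F explicitly against the equilateral
  # reference and evaluate the formula independently
  rt <- rbind(c(0, 0), c(1, 0), c(0, 1))
  S <- matrix(c(1, 0, 0.5, sqrt(3) / 2), 2, 2)
  F <- diag(2) %*% solve(S)
  q_oracle <- sum(F^2) / (2 * det(F))
  expect_equal(cell_quality(rt), q_oracle, tolerance = 1e-12)
  expect_equal(q_oracle, 2 / sqrt(3), tolerance = 1e-12)
})

test_that("quality is >= 1 and scale/rotation invariant on random simplices", {
  set.seed(11)
  for (d in 2:3) {
    for (k in 1:300) {
      x <- random_simplex(d)
      q <- cell_quality(x)
      expect_gte(q, 1 - 1e-12)
      R <- random_rotation(d)
      s <- stats::runif(1, 0.1, 10)
      expect_equal(cell_quality(s * x %*% R), q, tolerance = 1e-8)
    }
  }
})

test_that("degenerate simplices are rejected", {
  expect_error(cell_quality(rbind(c(0, 0), c(1, 1), c(2, 2))), "degenerate")
  expect_error(fsi_mesh(rbind(c(0, 0), c(1, 0), c(2, 0)),
                        matrix(1:3, 1)), "degenerate")
})

test_that("cell diameters equal brute-force max pairwise distances", {
  tri <- rbind(c(0, 0), c(1, 0), c(0, 1))
  m <- fsi_mesh(tri, matrix(1:3, 1))
  expect_equal(cell_diameters(m), sqrt(2))
  # uniform refinement halves diameters
  m1 <- rectangle_mesh(4, 4); m2 <- rectangle_mesh(8, 8)
  expect_equal(min_diameter(m1) / 2, min_diameter(m2))
  # random tets vs brute force
  set.seed(7)
  for (k in 1:20) {
    x <- random_simplex(3)
    mt <- fsi_mesh(x, matrix(1:4, 1))
    bf <- max(stats::dist(x))
    expect_equal(cell_diameters(mt), bf, tolerance = 1e-12)
  }
})

test_that("cell volumes are positive and sum to the domain measure", {
  m <- rectangle_mesh(5, 7, Lx = 2, Ly = 0.5)
  v <- cell_volumes(m)
  expect_true(all(v > 0))
  expect_equal(sum(v), 1, tolerance = 1e-12)
  root <- coarse_root()
  expect_true(all(cell_volumes(root) > 0))
})

test_that("msh v4.1 ASCII round trip is bit-exact", {
  m <- rectangle_mesh(3, 2, Lx = pi / 3, Ly = exp(1) / 10)
  tf <- withr::local_tempfile(fileext = ".msh")
  write_mesh(m, tf)
  m2 <- read_mesh(tf)
  expect_identical(m$vertices, m2$vertices)
  expect_identical(unname(m$cells), unname(m2$cells))
  expect_identical(m$region_tags, m2$region_tags)
  keys <- function(x) sort(paste(apply(x$facets, 1, function(r)
    paste(sort(r), collapse = "-")), x$facet_tags))
  expect_identical(keys(m), keys(m2))
})

test_that("a tagged valve fixture survives the msh round trip", {
  ch <- small_channel()
  tf <- withr::local_tempfile(fileext = ".msh")
  write_mesh(ch, tf)
  ch2 <- read_mesh(tf)
  expect_identical(ch$vertices, ch2$vertices)
  expect_identical(sort(names(ch2$region_names)),
                   sort(names(ch$region_names)))
  expect_equal(sum(ch2$region_tags != ch2$region_names[["fluid"]]),
               sum(ch$region_tags != 1L))
})

test_that("unsupported cell types raise a format error", {
  tf <- withr::local_tempfile(fileext = ".msh")
  writeLines(c("$MeshFormat", "4.1 0 8", "$EndMeshFormat",
               "$Nodes", "1 4 1 4", "2 1 0 4", "1", "2", "3", "4",
               "0 0 0", "1 0 0", "1 1 0", "0 1 0", "$EndNodes",
               "$Elements", "1 1 1 1", "2 1 3 1", "1 1 2 3 4",
               "$EndElements"), tf)
  expect_error(read_mesh(tf), "unsupported element type")
  expect_error(read_mesh(tempfile(), format = "msh"), "does not exist")
})

test_that("xdmf writer/reader and vtu writer produce consistent files", {
  m <- rectangle_mesh(3, 3)
  tf <- withr::local_tempfile(fileext = ".xdmf")
  write_xdmf(m, tf, point_data = list(P = matrix(seq_len(nrow(m$vertices)), ncol = 1)))
  m2 <- read_mesh(tf)
  expect_equal(m2$vertices, m$vertices)
  expect_equal(unname(m2$cells), unname(m$cells))
  tv <- withr::local_tempfile(fileext = ".vtu")
  write_vtu(m, tv, point_data = list(U = matrix(1, nrow(m$vertices), 2)))
  expect_gt(file.size(tv), 200)
})

test_that("facet adjacency distinguishes boundary and interior facets", {
  m <- rectangle_mesh(2, 2)
  bf <- boundary_facets(m)
  expect_equal(nrow(bf), 8)
  adj <- facet_adjacency(m, bf)
  expect_true(all(is.na(adj[, 2])))
  # an interior edge belongs to exactly two cells
  inner <- matrix(c(m$cells[1, 1], m$cells[1, 3]), 1)
  expect_error(facet_adjacency(m, matrix(c(1L, 9999L), 1)), "not part")
})
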