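# Stabilized P1-P1 slab solver: stabilization parameters, CFL control,
# linear solver contract, Couette exactness, free-stream preservation,
# Picard behaviour.

test_that("stabilization parameters follow the per-cell formulas", {
  # pure Lagrangian cell: relative velocity vanishes, delta1 = kappa1 k / rho
  st <- stabilization_params(matrix(c(2, 1), 1), matrix(c(2, 1), 1),
                             rho = 1060, h_cell = 0.01, k = 0.002)
  expect_equal(st$delta1, 0.002 / 1060)
  # U = 0 -> delta2 = 0
  st0 <- stabilization_params(matrix(0, 1, 2), matrix(0, 1, 2),
                              1060, 0.01, 0.002)
  expect_equal(st0$delta2, 0)
  # direct arithmetic oracle
  rho <- 1060; h <- 0.01; k <- 0.001; rel <- 1
  st1 <- stabilization_params(matrix(c(1, 0), 1), matrix(0, 1, 2), rho, h, k)
  expect_equal(st1$delta1, 1 / rho / sqrt(k^-2 + rel^2 / h^2))
  expect_equal(st1$delta2, rho * h * 1)
})

test_that("CFL controller hits the target exactly on a uniform field", {
  m <- rectangle_mesh(10, 10)
  n <- nrow(m$vertices)
  U <- matrix(rep(c(1, 0), each = n), n)
  M <- matrix(0, n, 2)
  h <- cell_diameters(m)
  dt <- cfl_timestep(U, M, m$cells, h, cfl_target = 0.5, dt_max = 10)
  # recompute the attained Courant number per cell
  cfl <- max(1 * dt / h)
  expect_equal(cfl, 0.5, tolerance = 1e-14)
  # quiescent flow caps at dt_max
  expect_equal(cfl_timestep(0 * U, M, m$cells, h, 0.5, dt_max = 0.05), 0.05)
})

test_that("linear solver meets the residual contract and reports failure", {
  set.seed(1)
  n <- 60
  A <- Matrix::Diagonal(n, 2) +
    Matrix::sparseMatrix(i = seq_len(n - 1), j = 2:n, x = rep(-1, n - 1), dims = c(n, n))
  A <- A + Matrix::t(A) # SPD tridiagonal (Poisson-like)
  xref <- rnorm(n)
  b <- as.vector(A %*% xref)
  x <- solve_linear(A, b, tol = 1e-10, method = "bicgstab")
  expect_lt(sqrt(sum((x - xref)^2)) / sqrt(sum(xref^2)), 1e-8)
  # identity
  expect_equal(as.numeric(solve_linear(Matrix::Diagonal(5), 1:5, method = "direct")),
               as.numeric(1:5))
  # singular matrix signals
  S <- Matrix::sparseMatrix(i = c(1, 2), j = c(1, 2), x = c(1, 0), dims = c(2, 2))
  expect_error(solve_linear(S, c(1, 1), method = "direct"),
               class = "valvefsi_solver_error")
})

test_that("zero data yields the zero solution", {
  m <- rectangle_mesh(4, 4)
  st <- initial_state(m)
  bidx <- sort(unique(as.vector(m$facets)))
  bcs <- list(velocity = list(idx = bidx, values = matrix(0, length(bidx), 2)),
              pressure = list(idx = 1L, values = 0))
  out <- picard_step(m, st, initial_phase(m), material_constants(), bcs, 0.01)
  expect_equal(max(abs(out$U)), 0)
  expect_equal(max(abs(out$P)), 0)
})

test_that("Couette flow is reproduced exactly (P1-representable steady state)", {
  cc <- make_couette(8, 6, mu_f = 1)
  bcs <- cc$bcs(cc$mesh$vertices)
  # the exact profile is a discrete fixed point
  st <- initial_state(cc$mesh)
  st$U <- cc$exact(cc$mesh$vertices)
  st2 <- picard_step(cc$mesh, st, initial_phase(cc$mesh), cc$materials, bcs, 0.1)
  expect_lt(max(abs(st2$U - st$U)), 1e-11)
  # and the solver converges to it from rest
  stz <- solve_to_steady(cc$mesh, cc$materials, bcs, dt = 0.2, cap = 300,
                         tol = 1e-12)
  expect_lt(max(abs(stz$U - cc$exact(cc$mesh$vertices))), 1e-8)
})

test_that("free-stream preservation: uniform U = M is an exact steady state", {
  ua <- make_uniform_advection(6)
  r <- slab_residual(ua$mesh, ua$state, initial_phase(ua$mesh), ua$materials,
                     ua$bcs, dt = 0.01, U_new = ua$state$U,
                     P_new = numeric(nrow(ua$mesh$vertices)))
  expect_lt(r, 1e-10)
})

test_that("Galilean invariance: translating box keeps its uniform velocity", {
  ua <- make_uniform_advection(5, c(0.4, 0.25))
  m <- ua$mesh
  st <- ua$state
  # all boundaries move with c; the mesh moves too (M = c everywhere)
  for (k in 1:3) {
    st2 <- picard_step(m, st, initial_phase(m), ua$materials, ua$bcs, 0.02)
    expect_lt(max(abs(st2$U - st$U)), 1e-10)
    st2$coords <- st$coords + 0.02 * st$M
    st2$M <- st$M
    st <- st2
  }
})

test_that("a diverging step signals rejection for the caller to halve dt", {
  m <- rectangle_mesh(6, 6)
  st <- initial_state(m)
  set.seed(9)
  st$U <- matrix(rnorm(2 * nrow(m$vertices), sd = 50), ncol = 2)
  bidx <- sort(unique(as.vector(m$facets)))
  bcs <- list(velocity = list(idx = bidx, values = st$U[bidx, ]),
              pressure = list(idx = 1L, values = 0))
  expect_error(
    picard_step(m, st, initial_phase(m), material_constants(mu_f = 1e-6),
                bcs, dt = 50, control = list(picard_max = 3L)),
    class = "valvefsi_picard_nonconvergence")
})

test_that("dt -> 0 limit is consistent: the state changes continuously", {
  cc <- make_couette(6, 6, mu_f = 0.5)
  m <- cc$mesh
  st <- initial_state(m)
  st$U <- cc$exact(m$vertices)
  inner <- setdiff(seq_len(nrow(m$vertices)), unique(as.vector(m$facets)))
  st$U[inner, ] <- 0.5 * st$U[inner, , drop = FALSE]  # interior perturbation
  bcs <- cc$bcs(m$vertices)
  d1 <- picard_step(m, st, initial_phase(m), cc$materials, bcs, 1e-3)
  d2 <- picard_step(m, st, initial_phase(m), cc$materials, bcs, 1e-5)
  expect_lt(max(abs(d2$U - st$U)), max(abs(d1$U - st$U)))
  expect_lt(max(abs(d2$U - st$U)), 1e-3)
})

test_that("Stokes-like regime converges in very few Picard sweeps", {
  cc <- make_couette(6, 6, mu_f = 10)
  m <- cc$mesh
  st <- initial_state(m)
  bcs <- cc$bcs(m$vertices)
  out <- picard_step(m, st, initial_phase(m),
                     material_constants(rho_fluid = 1, mu_f = 10), bcs, 0.05)
  expect_lte(attr(out, "picard_iters"), 3L)
})
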