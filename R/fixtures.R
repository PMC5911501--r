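# Programmatic verification fixtures: analytic and manufactured flow cases
# on which every solver property is testable without external data.

#' Structured triangulation of a rectangle
#'
#' @param nx,ny subdivisions per direction.
#' @param Lx,Ly side lengths (m).
#' @param tag_boundary add `inlet` (x=0), `outlet` (x=Lx), `wall` (y=0,Ly)
#'   facet sets.
#' @return a 2D `fsi_mesh` (all cells fluid).
#' @export
rectangle_mesh <- function(nx, ny, Lx = 1, Ly = 1, tag_boundary = TRUE) {
  xs <- seq(0, Lx, length.out = nx + 1L)
  ys <- seq(0, Ly, length.out = ny + 1L)
  nxx <- length(xs)
  verts <- cbind(rep(xs, times = length(ys)), rep(ys, each = nxx))
  vid <- function(i, j) (j - 1L) * nxx + i
  cells <- NULL
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    a <- vid(i, j); b <- vid(i + 1L, j); c <- vid(i + 1L, j + 1L); d <- vid(i, j + 1L)
    if ((i + j) %% 2L == 0L) cells <- rbind(cells, c(a, b, c), c(a, c, d))
    else cells <- rbind(cells, c(a, b, d), c(b, c, d))
  }
  facets <- NULL; tags <- NULL
  if (tag_boundary) {
    mesh0 <- structure(list(vertices = verts, cells = cells, dim = 2L),
                       class = "fsi_mesh")
    bf <- boundary_facets(mesh0)
    fx <- matrix(verts[bf, 1L], nrow(bf))
    tags <- rep(3L, nrow(bf))
    tags[apply(abs(fx) < 1e-14, 1L, all)] <- 1L
    tags[apply(abs(fx - Lx) < 1e-12 * max(1, Lx), 1L, all)] <- 2L
    facets <- bf
  }
  fsi_mesh(verts, cells, facets = facets, facet_tags = tags,
           facet_names = if (tag_boundary) c(inlet = 1L, outlet = 2L, wall = 3L)
                         else integer(0),
           metadata = list(kind = "rectangle", axis = c(1, 0),
                           L = c(Lx, Ly)))
}

#' Couette-flow verification case
#'
#' Plane Couette flow between a fixed bottom wall and a lid moving at
#' `U_lid`: the steady solution u = (U_lid * y / H, 0), p = 0 is linear and
#' therefore representable exactly in P1; the discrete solver must reproduce
#' it to linear-solver tolerance.
#'
#' @param nx,ny resolution.
#' @param U_lid lid speed (m/s).
#' @param H channel height (m).
#' @param mu_f viscosity (Pa s).
#' @return list with `mesh`, `materials`, `exact(coords)` returning the
#'   analytic velocity, and `bcs(coords)` returning Dirichlet data (exact
#'   values on the whole boundary).
#' @export
make_couette <- function(nx = 8L, ny = 8L, U_lid = 1, H = 1, mu_f = 0.01) {
  mesh <- rectangle_mesh(nx, ny, Lx = 1, Ly = H)
  exact <- function(coords) cbind(U_lid * coords[, 2L] / H, 0)
  bidx <- sort(unique(as.vector(mesh$facets)))
  out_v <- facet_set_vertices(mesh, "outlet")
  bcs <- function(coords) list(
    velocity = list(idx = bidx, values = exact(coords)[bidx, , drop = FALSE]),
    pressure = list(idx = out_v, values = 0))
  list(mesh = mesh, materials = material_constants(mu_f = mu_f),
       exact = exact, bcs = bcs)
}

#' Steady Taylor-Green manufactured solution with forcing
#'
#' u = (sin(pi x) cos(pi y), -cos(pi x) sin(pi y)),
#' p = rho/4 (cos(2 pi x) + cos(2 pi y)), divergence-free; the body force
#' f = rho (u . grad) u - mu lap(u) + grad p makes the pair an exact steady
#' solution of the momentum equation, so the spatial convergence order of
#' the stabilized scheme can be measured on uniform refinements.
#'
#' @param n resolution (n x n).
#' @param mu_f viscosity (Pa s); the default puts the cell Peclet number in
#'   the advection-dominated regime the stabilized scheme is designed for.
#' @param rho density (kg/m^3).
#' @return list with `mesh`, `materials`, `exact`, `exact_p`, `force`,
#'   `bcs`.
#' @export
make_taylor_green <- function(n = 8L, mu_f = 0.01, rho = 1) {
  mesh <- rectangle_mesh(n, n)
  exact <- function(coords) cbind(sin(pi * coords[, 1L]) * cos(pi * coords[, 2L]),
                                  -cos(pi * coords[, 1L]) * sin(pi * coords[, 2L]))
  exact_p <- function(coords) rho / 4 * (cos(2 * pi * coords[, 1L]) +
                                         cos(2 * pi * coords[, 2L]))
  force <- function(coords, t) {
    x <- coords[, 1L]; y <- coords[, 2L]
    sx <- sin(pi * x); cx <- cos(pi * x); sy <- sin(pi * y); cy <- cos(pi * y)
    # (u.grad)u = (pi sx cx, pi sy cy); lap u = -2 pi^2 u;
    # grad p = -pi rho/2 (sin 2pi x, sin 2pi y) = -pi rho (sx cx, sy cy)
    adv <- cbind(pi * sx * cx, pi * sy * cy)
    lap <- -2 * pi^2 * cbind(sx * cy, -cx * sy)
    gp <- cbind(-pi * rho * sx * cx, -pi * rho * sy * cy)
    rho * adv - mu_f * lap + gp
  }
  bidx <- sort(unique(as.vector(mesh$facets)))
  # all-Dirichlet velocity leaves the pressure defined up to a constant;
  # pin one vertex at its exact value
  bcs <- function(coords) list(
    velocity = list(idx = bidx, values = exact(coords)[bidx, , drop = FALSE]),
    pressure = list(idx = 1L, values = exact_p(coords[1L, , drop = FALSE])))
  list(mesh = mesh,
       materials = material_constants(rho_fluid = rho, mu_f = mu_f),
       exact = exact, exact_p = exact_p, force = force, bcs = bcs)
}

#' Uniform-advection (free-stream preservation) case
#'
#' Uniform velocity c with mesh velocity M = c is an exact steady state of
#' the discrete slab equations: every term of the variational form vanishes
#' and the assembled residual must be zero to rounding.
#'
#' @param n resolution.
#' @param c_vec the uniform velocity (m/s).
#' @return list with `mesh`, `materials`, `state` (uniform), `bcs`.
#' @export
make_uniform_advection <- function(n = 6L, c_vec = c(0.7, -0.3)) {
  mesh <- rectangle_mesh(n, n)
  nv <- nrow(mesh$vertices)
  U <- matrix(rep(c_vec, each = nv), nv)
  st <- fsi_state(U, numeric(nv), U, zero_cell_tensors(nrow(mesh$cells), 2L),
                  0, mesh$vertices)
  bidx <- sort(unique(as.vector(mesh$facets)))
  bcs <- list(velocity = list(idx = bidx, values = U[bidx, , drop = FALSE]),
              pressure = list(idx = facet_set_vertices(mesh, "outlet"),
                              values = 0))
  list(mesh = mesh, materials = material_constants(rho_fluid = 1, mu_f = 0.01),
       state = st, bcs = bcs)
}

#' Iterate the slab solver to a steady state on a fixed mesh
#'
#' Repeated Crank-Nicolson steps with the mesh frozen (M = 0) until the
#' velocity update stalls; used by the analytic and manufactured-solution
#' verification cases.
#'
#' @param mesh an `fsi_mesh` (all fluid).
#' @param materials a [material_constants()].
#' @param bcs Dirichlet data.
#' @param dt pseudo-time step (s).
#' @param U0 initial velocity (default zero).
#' @param body_force optional forcing hook.
#' @param cap maximum steps.
#' @param tol stall tolerance on the max velocity update.
#' @return the steady `fsi_state` with attribute `steady_steps`.
#' @export
solve_to_steady <- function(mesh, materials, bcs, dt, U0 = NULL,
                            body_force = NULL, cap = 400L, tol = 1e-10) {
  th <- initial_phase(mesh)
  st <- initial_state(mesh)
  if (!is.null(U0)) st$U <- U0
  for (k in seq_len(cap)) {
    st2 <- picard_step(mesh, st, th, materials, bcs, dt,
                       control = list(picard_tol = 1e-8),
                       body_force = body_force)
    st2$coords <- st$coords
    dU <- max(abs(st2$U - st$U))
    st <- st2
    st$M[] <- 0
    if (dU < tol) break
  }
  attr(st, "steady_steps") <- k
  st
}

#' L2 norm of a vertex field over a mesh
#' @param field `n x k` vertex values.
#' @param mesh the mesh.
#' @return sqrt of the integral of |field|^2 (midpoint-type quadrature).
#' @export
field_l2 <- function(field, mesh) {
  geo <- p1_geometry(mesh)
  ec <- cell_average(as.matrix(field)^2, mesh$cells)
  sqrt(sum(geo$vol * rowSums(ec)))
}

#' 2D flapping-leaflet demonstration case
#'
#' The desk-scale valve analogue used by the end-to-end demonstration: a
#' short channel with two flexible leaflet strips, pulsatile flat inflow
#' over one cardiac cycle (1.124 s), contact by phase switching across the
#' closure line, and a soft leaflet modulus so the strips flex visibly at
#' channel scale.
#'
#' The channel is 60 x 20 mm with two 9 mm strips resting 30 degrees open
#' (the analogue of the pre-stressed native starting configuration); the
#' contact threshold sits just below the resting tip gap so that the
#' reversal-driven back-swing, and nothing earlier, closes the valve.
#'
#' @param mesh_size cell size (m).
#' @param mu_s leaflet shear modulus (Pa).
#' @param U_peak peak inflow (m/s).
#' @return list with `mesh` and a ready `config` for [run_simulation()].
#' @export
make_flapping_leaflet_2d <- function(mesh_size = 0.0016, mu_s = 8000,
                                     U_peak = 0.32) {
  mesh <- generate_2d_valve_channel(
    channel_length = 0.06, channel_height = 0.02,
    leaflet_length = 0.009, leaflet_thickness = 0.0014,
    mesh_size = mesh_size, n_leaflets = 2L, leaflet_x = 0.018,
    tilt_deg = 30)
  config <- utils::modifyList(default_config(), list(
    materials = list(mu_s = mu_s),
    cycle = list(U_peak = U_peak, U_reversal = 0.6 * U_peak),
    solver = list(t_end = 1.124, dt_max = 0.004),
    smoothing = list(pseudo_steps = 25L, quality_trigger = 5,
                     max_quality = 60),
    contact = list(enabled = TRUE, threshold = 0.0042),
    output = list(save_every = 40L)))
  list(mesh = mesh, config = config)
}
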