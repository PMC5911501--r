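# Cardiac-cycle boundary conditions: a flat-profile inflow waveform with an
# end-systolic reversal lobe, homogeneous pressure Dirichlet data at the
# outlet, phase events (systole / reversal / diastole / cycle start), and the
# radial pre-stress initialization that pushes the native leaflets from the
# fully open CAD position into a physiologic starting configuration.

#' Cycle timing and inflow amplitudes
#'
#' One heart cycle lasts 1.124 s and splits into systole followed by a short
#' reversed-flow lobe and a quiescent diastole (the valve is closed and the
#' inflow is zero).  The forward pulse is a half sine of peak `U_peak` over
#' `T_systole`; the reversal is a negative half sine of magnitude
#' `U_reversal` over `T_reversal` (about 0.05 s of backflow completes the
#' closure).  The waveform amplitudes are configurable interpretations of a
#' left-ventricle outflow history that is not tabulated anywhere.
#'
#' @param T_cycle cycle duration (s, default 1.124).
#' @param T_systole forward-flow duration (s, default 0.4).
#' @param T_reversal backflow duration (s, default 0.05).
#' @param U_peak peak forward inflow speed (m/s, default 1.0).
#' @param U_reversal peak reversed speed (m/s, default 0.2).
#' @return list of class `cycle_config`.
#' @export
cycle_config <- function(T_cycle = 1.124, T_systole = 0.4, T_reversal = 0.05,
                         U_peak = 1.0, U_reversal = 0.2) {
  stopifnot(T_cycle > 0, T_systole > 0, T_reversal > 0,
            T_systole + T_reversal < T_cycle)
  structure(list(T_cycle = T_cycle, T_systole = T_systole,
                 T_reversal = T_reversal, U_peak = U_peak,
                 U_reversal = U_reversal), class = "cycle_config")
}

#' Inflow speed at time t
#'
#' Periodic with period `T_cycle`; positive half-sine during systole,
#' negative lobe during the reversal window, zero in diastole.
#'
#' @param t time (s), vectorized.
#' @param config a [cycle_config()].
#' @return signed inflow speed (m/s); positive = forward (into the domain).
#' @export
inflow_magnitude <- function(t, config = cycle_config()) {
  tm <- t %% config$T_cycle
  out <- numeric(length(tm))
  sys <- tm <= config$T_systole
  rev <- !sys & tm <= config$T_systole + config$T_reversal
  out[sys] <- config$U_peak * sin(pi * tm[sys] / config$T_systole)
  out[rev] <- -config$U_reversal *
    sin(pi * (tm[rev] - config$T_systole) / config$T_reversal)
  out
}

#' Cycle events crossed in a time interval
#'
#' Emits, in chronological order and exactly once each, every phase boundary
#' crossed in `(t_prev, t_new]`: `cycle_start` and `systole_start` at
#' multiples of the period, `reversal_start` at end of systole,
#' `diastole_start` at end of the reversal lobe.
#'
#' @param t_prev,t_new interval bounds (s), `t_new > t_prev`.
#' @param config a [cycle_config()].
#' @return character vector of event names (possibly empty).
#' @export
cycle_events <- function(t_prev, t_new, config = cycle_config()) {
  stopifnot(t_new > t_prev)
  Tc <- config$T_cycle
  marks <- list(cycle_start = 0, systole_start = 0,
                reversal_start = config$T_systole,
                diastole_start = config$T_systole + config$T_reversal)
  ev <- character(0); tv <- numeric(0)
  k0 <- floor(t_prev / Tc); k1 <- floor(t_new / Tc) + 1
  for (k in k0:k1) for (nm in names(marks)) {
    tk <- k * Tc + marks[[nm]]
    if (tk > t_prev && tk <= t_new) { ev <- c(ev, nm); tv <- c(tv, tk) }
  }
  ord <- order(tv, match(ev, names(marks)))
  ev[ord]
}

#' Time-dependent Dirichlet data
#'
#' Inlet: uniform ("flat") velocity of magnitude `inflow_magnitude(t)` along
#' the inward valve axis on all inlet vertices.  Walls: no-slip against the
#' (fixed) wall.  Outlet: the homogeneous pressure condition is carried by
#' the weak form -- the boundary stress term is dropped after integration by
#' parts, which imposes zero traction (hence zero outlet pressure) without
#' nodal pressure constraints; pair with [outflow_data()] for backflow
#' stabilization during the reversal phase.
#'
#' @param mesh an `fsi_mesh` with `inlet`, `outlet`, `wall` facet sets and an
#'   `axis` entry in its metadata (unit vector, flow direction).
#' @param t evaluation time (s).
#' @param config a [cycle_config()].
#' @param extra_velocity optional additional velocity constraints
#'   `list(idx, values)` (e.g. locked hinge leaflets), appended last so they
#'   override.
#' @return Dirichlet data list: `velocity = list(idx, values)`,
#'   `pressure = list(idx, values)`.
#' @export
apply_bcs <- function(mesh, t, config = cycle_config(), extra_velocity = NULL) {
  for (nm in c("inlet", "outlet", "wall"))
    if (!nm %in% names(mesh$facet_names))
      stop(sprintf("apply_bcs: mesh lacks facet set '%s'", nm), call. = FALSE)
  axis <- mesh$metadata$axis
  if (is.null(axis)) stop("apply_bcs: mesh metadata lacks the valve axis", call. = FALSE)
  d <- mesh$dim
  inlet <- facet_set_vertices(mesh, "inlet")
  wall <- setdiff(facet_set_vertices(mesh, "wall"), inlet)
  outlet <- facet_set_vertices(mesh, "outlet")
  if (!length(inlet) || !length(outlet))
    stop("apply_bcs: inlet/outlet facet sets are empty", call. = FALSE)
  speed <- inflow_magnitude(t, config)
  vel_idx <- c(inlet, wall)
  vel_val <- rbind(matrix(rep(axis * speed, each = length(inlet)), ncol = d),
                   matrix(0, length(wall), d))
  if (!is.null(extra_velocity) && length(extra_velocity$idx)) {
    keep <- !(vel_idx %in% extra_velocity$idx)
    vel_idx <- c(vel_idx[keep], extra_velocity$idx)
    vel_val <- rbind(vel_val[keep, , drop = FALSE],
                     as.matrix(extra_velocity$values))
  }
  list(velocity = list(idx = vel_idx, values = vel_val),
       pressure = NULL, outlet_vertices = outlet)
}

#' Radial pre-stress configuration
#' @param sigma_r radial stress magnitude (Pa, default 4).
#' @param max_steps pseudo-dynamic relaxation step cap.
#' @param tol per-step displacement tolerance (m).
#' @param mu_relax elastic modulus of the relaxation operator (Pa); sets the
#'   magnitude, not the direction, of the response.
#' @return list of class `prestress_config`.
#' @export
prestress_config <- function(sigma_r = 4, max_steps = 2000L, tol = 1e-10,
                             mu_relax = 200) {
  stopifnot(sigma_r >= 0)
  structure(list(sigma_r = sigma_r, max_steps = as.integer(max_steps),
                 tol = tol, mu_relax = mu_relax), class = "prestress_config")
}

#' Pre-stress initialization of the native leaflets
#'
#' Prescribes a constant radial stress sigma_r (e_r x e_r) in the leaflet
#' cells -- the leaflets behave like a contracting balloon that was stretched
#' -- and relaxes the leaflet vertices pseudo-dynamically (damped Jacobi
#' iteration of the linear elastic balance against the prescribed stress,
#' attachment vertices fixed) until the per-step displacement falls below
#' tolerance.  The deformed coordinates become the simulation's starting
#' configuration and the stress is reset to zero afterwards.
#'
#' @param mesh a native-root `fsi_mesh` (leaflet regions tagged; valve axis =
#'   z in metadata).
#' @param theta per-cell phase.
#' @param config a [prestress_config()].
#' @return list with `coords` (deformed), `displacement` (n x d), and
#'   `steps` taken.
#' @export
prestress_initialize <- function(mesh, theta = initial_phase(mesh),
                                 config = prestress_config()) {
  coords <- mesh$vertices
  d <- mesh$dim; n <- nrow(coords)
  if (config$sigma_r == 0)
    return(list(coords = coords, displacement = matrix(0, n, d), steps = 0L))
  sol <- which(theta == 0L)
  if (!length(sol)) stop("prestress_initialize: no leaflet cells", call. = FALSE)
  cl <- mesh$cells[sol, , drop = FALSE]
  geo <- p1_geometry(list(vertices = coords, cells = cl))
  nv <- d + 1L

  # radial stress per leaflet cell: sigma_r * (e_r x e_r), e_r from the z-axis
  cent <- cell_average(coords, cl)
  er <- cent[, 1:2, drop = FALSE]
  er <- er / pmax(sqrt(rowSums(er^2)), 1e-12)

  # nodal force: rhs_i = -(tau_pre : grad v_i).  The prescribed stress is
  # compressive in the radial direction (tau_pre = -sigma_r e_r x e_r): a
  # stretched balloon contracts, so the resulting body force in the curved
  # shell points inward and drives the free edges toward the valve axis.
  f <- matrix(0, n, d)
  for (i in seq_len(nv)) for (al in 1:2) {
    acc <- 0
    for (be in 1:2)
      acc <- acc - config$sigma_r * er[, al] * er[, be] * geo$grads[, i, be]
    contrib <- -geo$vol * acc
    tb <- rowsum(contrib, cl[, i])
    f[as.integer(rownames(tb)), al] <- f[as.integer(rownames(tb)), al] + tb[, 1L]
  }

  # elastic restoring operator: vector Laplacian with modulus mu_relax
  ti <- list(); tj <- list(); tx <- list()
  for (i in seq_len(nv)) for (j in seq_len(nv)) {
    acc <- 0
    for (g in seq_len(d)) acc <- acc + geo$grads[, i, g] * geo$grads[, j, g]
    k <- length(ti) + 1L
    ti[[k]] <- cl[, i]; tj[[k]] <- cl[, j]; tx[[k]] <- config$mu_relax * geo$vol * acc
  }
  K <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(n, n))

  # attachment = leaflet vertices on the vessel wall (or other outer
  # boundaries); free-edge vertices carry no wall tag and may move
  lverts <- sort(unique(as.vector(cl)))
  fixed_sets <- intersect(c("wall", "inlet", "outlet"), names(mesh$facet_names))
  attach <- intersect(lverts, unique(unlist(
    lapply(fixed_sets, function(nm) facet_set_vertices(mesh, nm)))))
  free <- setdiff(lverts, attach)
  if (!length(free))
    stop("prestress_initialize: leaflets have no free vertices", call. = FALSE)

  dia <- Matrix::diag(K)[free]
  dia[dia <= 0] <- 1
  disp <- matrix(0, n, d)
  omega <- 0.8
  steps <- 0L
  step_norms <- numeric(0)
  for (s in seq_len(config$max_steps)) {
    r <- f[free, , drop = FALSE] - as.matrix(K[free, , drop = FALSE] %*% disp)
    upd <- omega * r / dia
    disp[free, ] <- disp[free, ] + upd
    steps <- s
    step_norms[s] <- max(abs(upd))
    if (step_norms[s] < config$tol) break
  }
  if (steps == config$max_steps && step_norms[steps] >= config$tol)
    stop(structure(class = c("valvefsi_prestress_error", "error", "condition"),
                   list(message = "prestress relaxation did not converge",
                        call = NULL, displacement = disp)))
  list(coords = coords + disp, displacement = disp, steps = steps,
       step_norms = step_norms)
}
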