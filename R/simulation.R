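# End-to-end driver.  Per time step: (1) cycle events and contact handling
# (collision detection, closure by phase switching, release at systole
# start, hinge locking for mechanical valves), (2) the monolithic
# momentum/continuity solve, (3) mesh-velocity smoothing, (4) coordinate
# update x <- x + dt * M with quality surveillance and nonlinear smoothing,
# (5) post-processing (orifice area, fluxes, series logging).

#' Run a valve FSI simulation
#'
#' @param config configuration list (see [default_config()] /
#'   [load_config()]).
#' @param mesh an `fsi_mesh` with `inlet`, `outlet`, `wall` facet sets (and a
#'   `closure` set when contact is enabled).
#' @param init optional initial `fsi_state` (default: quiescent).
#' @param quiet suppress progress output.
#' @return an `fsi_trajectory`: list with `mesh`, `snapshots` (stored states
#'   with their phase), `timeseries` (data frame: t, dt, cfl, goa, d_min,
#'   Q_max, picard iterations, inflow speed), `materials`, `config`, and
#'   `events` log.
#' @export
run_simulation <- function(config, mesh, init = NULL, quiet = TRUE) {
  validate_config(config, mesh)
  mat <- do.call(material_constants, config$materials)
  cyc <- do.call(cycle_config, config$cycle)
  sol <- config$solver
  smo <- do.call(smoothing_config, config$smoothing[c("pseudo_steps", "pseudo_dt",
                                                      "quality_trigger", "max_quality")])
  n <- nrow(mesh$vertices); d <- mesh$dim
  cl <- mesh$cells
  theta <- initial_phase(mesh)
  state <- if (is.null(init)) initial_state(mesh) else init

  leaf_regions <- grep("^leaflet", names(mesh$region_names), value = TRUE)
  contact_on <- isTRUE(config$contact$enabled) && length(leaf_regions) >= 1L &&
    "closure" %in% names(mesh$facet_names)
  contact <- NULL
  if (contact_on) {
    thr <- config$contact$threshold
    if (is.null(thr)) {
      # default: twice the smallest cell diameter adjacent to a leaflet
      lv <- unique(as.vector(cl[mesh$region_tags != mesh$region_names[["fluid"]], ,
                                drop = FALSE]))
      near <- rowSums(matrix(cl %in% lv, nrow(cl))) > 0
      thr <- 2 * min(mesh_diameters(state$coords, cl[near, , drop = FALSE]))
    }
    contact <- contact_state(thr)
  }
  pairs <- NULL
  if (contact_on) {
    pairs <- if (length(leaf_regions) >= 2L) utils::combn(leaf_regions, 2L)
             else matrix(c(leaf_regions, "wall"), 2L)
  }

  hinges <- mesh$metadata$hinges
  hs <- if (!is.null(hinges))
    hinge_state(length(hinges), mesh$metadata$alpha_max, mesh$metadata$alpha_closed)
  else NULL

  ctl <- list(picard_tol = sol$picard_tol, picard_max = sol$picard_max,
              krylov = sol$krylov, lin_tol = sol$lin_tol,
              kappa1 = sol$kappa1, kappa2 = sol$kappa2)

  fluid_tag <- mesh$region_names[["fluid"]]
  outflow <- outflow_data(mesh, "outlet")
  tagged_vertices <- unique(as.vector(mesh$facets))
  rows <- list(); snaps <- list(); evlog <- list()
  cfl <- sol$cfl_target
  accepted <- 0L
  step <- 0L
  t_end <- sol$t_end

  while (state$t < t_end - 1e-12) {
    step <- step + 1L
    diam <- mesh_diameters(state$coords, cl)
    dt <- cfl_timestep(state$U, state$M, cl, diam, cfl, sol$dt_max)
    dt <- min(dt, t_end - state$t)
    events <- cycle_events(state$t, state$t + dt, cyc)
    if (length(events)) evlog[[length(evlog) + 1L]] <-
      data.frame(t = state$t + dt, event = events)

    # contact handling
    d_min <- NA_real_
    if (contact_on) {
      if ("systole_start" %in% events && contact$closed) {
        rel <- release_contact(theta, contact, state$tau_s, "systole_start")
        theta <- rel$theta; contact <- rel$contact; state$tau_s <- rel$tau_s
      }
      if (step %% max(1L, config$contact$check_every) == 0L || contact$closed) {
        d_min <- min(apply(pairs, 2L, function(pr)
          leaflet_distance(mesh, pr[1L], pr[2L], method = config$contact$method,
                           coords = state$coords)))
        if (!contact$closed) {
          cc <- check_and_close(mesh, theta, contact, d_min, state$coords)
          theta <- cc$theta; contact <- cc$contact
        } else contact$d_min <- d_min
      }
    }

    # hinge locking (mechanical valves)
    extra <- NULL
    if (!is.null(hs)) {
      alpha_now <- vapply(seq_along(hinges), function(k) {
        lv <- unique(as.vector(cl[region_cells(mesh, hinges[[k]]$region), ,
                                  drop = FALSE]))
        rotation_angle(state$coords[lv, , drop = FALSE], hinges[[k]],
                       hinges[[k]]$closed_ref)
      }, 0)
      p_above <- mean_pressure(state$P, mesh, "outlet", state$coords)
      p_below <- mean_pressure(state$P, mesh, "inlet", state$coords)
      hs <- update_hinge(hs, alpha_now, dt, p_above, p_below,
                         new_cycle = "cycle_start" %in% events)
      locked <- which(hs$locked_open | hs$locked_closed)
      if (length(locked)) {
        lv <- unique(unlist(lapply(locked, function(k)
          as.vector(cl[region_cells(mesh, hinges[[k]]$region), , drop = FALSE]))))
        extra <- list(idx = lv, values = matrix(0, length(lv), d))
      }
    }

    bcs <- apply_bcs(mesh, state$t + dt, cyc, extra_velocity = extra)

    state_new <- tryCatch(
      picard_step(mesh, state, theta, mat, bcs, dt, control = ctl,
                  outflow = outflow),
      valvefsi_picard_nonconvergence = function(e) e,
      valvefsi_solver_error = function(e) e)
    if (inherits(state_new, "condition")) {
      if (cfl <= sol$cfl_floor + 1e-15)
        stop(structure(class = c("valvefsi_step_failure", "error", "condition"),
                       list(message = sprintf(
                         "step rejected at t=%.4f with CFL already at floor: %s",
                         state$t, conditionMessage(state_new)), call = NULL)))
      cfl <- max(cfl / 2, sol$cfl_floor)
      accepted <- 0L
      next
    }
    accepted <- accepted + 1L
    if (accepted %% sol$recover_after == 0L) cfl <- min(2 * cfl, sol$cfl_target)

    # mesh velocity: material velocity in the solid, harmonic extension in
    # the fluid, zero on the fixed outer boundaries
    sv <- solid_vertices(mesh, theta)
    iv <- interface_vertices(mesh, theta)
    Mnew <- matrix(0, n, d)
    if (length(sv)) {
      Mf <- linear_smooth(mesh, theta,
                          list(idx = iv, values = state_new$U[iv, , drop = FALSE]),
                          coords = state$coords)
      Mnew <- Mf
      Mnew[sv, ] <- state_new$U[sv, , drop = FALSE]
    }
    coords_new <- state$coords + dt * Mnew

    vols <- simplex_signed_measures(coords_new, cl)
    if (any(vols <= 0)) {
      # attempt local repair; otherwise reject the step and advance with a
      # reduced Courant number through the sensitive phase of large and
      # fast deformation
      ns <- try(nonlinear_smooth(mesh, smo,
                                 free_vertices = setdiff(seq_len(n),
                                                         c(tagged_vertices, sv, iv)),
                                 coords = coords_new), silent = TRUE)
      if (inherits(ns, "try-error") || any(simplex_signed_measures(ns$coords, cl) <= 0)) {
        if (cfl > sol$cfl_floor + 1e-15) {
          cfl <- max(cfl / 2, sol$cfl_floor)
          accepted <- 0L
          step <- step - 1L
          next
        }
        bad <- which(simplex_signed_measures(coords_new, cl) <= 0)
        stop(structure(class = c("valvefsi_mesh_error", "error", "condition"),
                       list(message = sprintf(
                         "unrecoverable mesh degeneration at t=%.4f (inverted cell)",
                         state$t + dt), call = NULL, state = state_new,
                         bad_cells = bad,
                         timeseries = do.call(rbind, rows[!vapply(rows, is.null, TRUE)]))))
      }
      coords_new <- ns$coords
    }
    q <- mesh_cell_quality(coords_new, cl, d)
    if (max(q) > smo$quality_trigger && smo$pseudo_steps > 0L) {
      ns <- nonlinear_smooth(mesh, smo,
                             free_vertices = setdiff(seq_len(n),
                                                     c(tagged_vertices, sv, iv)),
                             coords = coords_new)
      coords_new <- ns$coords
      q <- mesh_cell_quality(coords_new, cl, d)
    }
    if (max(q) > smo$max_quality) {
      if (cfl > sol$cfl_floor + 1e-15) {
        cfl <- max(cfl / 2, sol$cfl_floor)
        accepted <- 0L
        step <- step - 1L
        next
      }
      stop(structure(class = c("valvefsi_mesh_error", "error", "condition"),
                     list(message = sprintf(
                       "mesh quality %.1f beyond abort threshold at t=%.4f",
                       max(q), state$t + dt), call = NULL, state = state_new,
                       bad_cells = which(q > smo$max_quality),
                       timeseries = do.call(rbind, rows[!vapply(rows, is.null, TRUE)]))))
    }

    state_new$M <- Mnew
    state_new$coords <- coords_new
    state <- state_new

    goa <- if (contact_on)
      geometric_orifice_area(mesh, theta, coords = state$coords,
                             n_samples = 2000L) else NA_real_
    rows[[step]] <- data.frame(
      t = state$t, dt = dt, cfl = cfl, goa = goa, d_min = d_min,
      Q_max = max(q), picard = attr(state, "picard_iters"),
      inflow = inflow_magnitude(state$t, cyc),
      alpha1 = if (!is.null(hs)) hs$alpha[1L] else NA_real_,
      alpha2 = if (!is.null(hs) && length(hs$alpha) > 1L) hs$alpha[2L] else NA_real_,
      closed = if (contact_on) contact$closed else NA)
    if (step %% max(1L, config$output$save_every) == 0L)
      snaps[[length(snaps) + 1L]] <- list(state = state, theta = theta)
    if (!quiet && step %% 50L == 0L)
      message(sprintf("t=%.4f dt=%.2e cfl=%.3f goa=%.3g Qmax=%.2f",
                      state$t, dt, cfl, goa, max(q)))
  }
  snaps[[length(snaps) + 1L]] <- list(state = state, theta = theta)
  ts <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  structure(list(mesh = mesh, snapshots = snaps, timeseries = ts,
                 materials = mat, config = config,
                 events = if (length(evlog)) do.call(rbind, evlog) else NULL,
                 contact = contact, hinge = hs),
            class = "fsi_trajectory")
}

#' @export
print.fsi_trajectory <- function(x, ...) {
  cat(sprintf("<fsi_trajectory> %d steps to t=%.4f s, %d snapshots\n",
              nrow(x$timeseries), max(x$timeseries$t), length(x$snapshots)))
  invisible(x)
}
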