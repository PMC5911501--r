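# Stabilized equal-order P1-P1 discretization of the unified continuum
# momentum/continuity system in ALE form, advanced with Crank-Nicolson in time
# (midpoint quadrature over each space-time slab) and Picard iteration on the
# advective velocity and on the rotational part of the solid stress rate.
#
# Per slab, with Ubar = (U^n + U^{n-1})/2 and mesh velocity M:
#   (rho/k (U^n - U^{n-1}) + rho ((Ubar - M) . grad) Ubar, v)
#     + (T(Ubar, P^n) : grad v) + (div Ubar, q) + SD_delta = 0
# where T = tauD - P I, and the simplified Galerkin/least-squares term
#   SD = (delta1 rho ((a . grad)Ubar + grad P - f), rho (a . grad)v + grad q)
#      + (delta2 div Ubar, div v)
# drops the time-derivative and diffusion from the strong residual.  The
# boundary stress term from integration by parts is dropped (weak dynamic
# interface condition and zero-traction outlet).
#
# Unknown ordering: velocity component a of vertex i at (a-1)*n + i, pressure
# of vertex i at d*n + i.

#' Simulation state
#'
#' @param U vertex velocity field (n x d, m/s); fluid velocity in the fluid
#'   phase, material velocity in the solid phase.
#' @param P vertex pressure (n, Pa).
#' @param M vertex mesh velocity (n x d, m/s).
#' @param tau_s per-cell solid stress, `m x d^2` row-major tensor entries (Pa).
#' @param t current time (s).
#' @param coords current vertex positions (n x d, m).
#' @return object of class `fsi_state`.
#' @export
fsi_state <- function(U, P, M, tau_s, t, coords) {
  structure(list(U = U, P = P, M = M, tau_s = tau_s, t = t, coords = coords),
            class = "fsi_state")
}

#' Fresh quiescent state for a mesh
#' @param mesh an `fsi_mesh`.
#' @return an `fsi_state` with zero fields at t = 0.
#' @export
initial_state <- function(mesh) {
  n <- nrow(mesh$vertices); d <- mesh$dim
  fsi_state(matrix(0, n, d), numeric(n), matrix(0, n, d),
            zero_cell_tensors(nrow(mesh$cells), d), 0, mesh$vertices)
}

#' Streamline-diffusion / GLS stabilization parameters
#'
#' Per cell:
#'   delta1 = kappa1 / rho * (k^-2 + |U - M|^2 / h^2)^(-1/2)
#'   delta2 = kappa2 * rho * h * |U|
#' with |.| the cell-averaged Euclidean magnitude of the previous-step
#' velocity fields, h the cell diameter and k the time step.  kappa1, kappa2
#' are problem-independent constants of order one.
#'
#' @param U_cell,M_cell per-cell averaged velocity and mesh velocity
#'   (`m x d` matrices, m/s).
#' @param rho density per cell (kg/m^3), recycled.
#' @param h_cell per-cell diameters (m).
#' @param k time step (s).
#' @param kappa1,kappa2 dimensionless constants (default 1).
#' @return list with per-cell vectors `delta1`, `delta2`.
#' @export
stabilization_params <- function(U_cell, M_cell, rho, h_cell, k,
                                 kappa1 = 1, kappa2 = 1) {
  stopifnot(all(h_cell > 0), k > 0)
  U_cell <- as.matrix(U_cell); M_cell <- as.matrix(M_cell)
  speedU <- sqrt(rowSums(U_cell^2))
  rel <- sqrt(rowSums((U_cell - M_cell)^2))
  delta1 <- kappa1 / rho / sqrt(k^-2 + (rel / h_cell)^2)
  delta2 <- kappa2 * rho * h_cell * speedU
  list(delta1 = delta1, delta2 = delta2)
}

#' CFL-driven time-step selection
#'
#' dt = cfl_target * min_K h_K / max(|U - M| over the cell, floor); the floor
#' guards against division by zero in quiescent regions, where the step is
#' capped at `dt_max` instead.
#'
#' @param U,M vertex velocity and mesh velocity (`n x d`).
#' @param cells cell connectivity (`m x (d+1)`).
#' @param diameters per-cell diameters (m).
#' @param cfl_target target Courant number (default 0.5).
#' @param dt_max cap for quiescent flow (s).
#' @param speed_floor smallest speed considered (m/s).
#' @return time step dt (s).
#' @export
cfl_timestep <- function(U, M, cells, diameters, cfl_target = 0.5,
                         dt_max = 0.05, speed_floor = 1e-12) {
  stopifnot(cfl_target > 0)
  rel <- as.matrix(U) - as.matrix(M)
  vmag <- sqrt(rowSums(rel^2))
  cellmax <- matrix(vmag[cells], nrow(cells), ncol(cells))
  speed <- pmax(apply(cellmax, 1L, max), speed_floor)
  min(cfl_target * min(diameters / speed), dt_max)
}

# cell averages of a vertex field
cell_average <- function(field, cells) {
  field <- as.matrix(field)
  out <- 0
  for (j in seq_len(ncol(cells))) out <- out + field[cells[, j], , drop = FALSE]
  out / ncol(cells)
}

#' Assemble the linearized slab system
#'
#' Builds the sparse matrix and right-hand side for the unknowns (U^n, P^n),
#' with the advective velocity and the rotational solid-stress terms frozen at
#' the supplied Picard iterate so the system is linear.
#'
#' @param mesh an `fsi_mesh`; geometry is taken from `state$coords`.
#' @param state previous-step `fsi_state` (supplies U^{n-1}, M, tau_s, coords).
#' @param theta per-cell phase (1 fluid, 0 solid).
#' @param materials a [material_constants()] object.
#' @param dt time step (s).
#' @param picard_U current Picard iterate of U^n (defaults to U^{n-1}).
#' @param stab optional list(delta1, delta2); computed from `state` if `NULL`.
#' @param body_force optional `function(coords, t)` returning an `n x d` force
#'   density (N/m^3); a testing hook, zero in the physical model.
#' @param kappa1,kappa2 stabilization constants.
#' @param outflow optional open-boundary data from [outflow_data()]; adds the
#'   backflow-stabilization boundary term
#'   `rho * (u.n)_- (Ubar, v)` on facets where the flow re-enters, which keeps
#'   the zero-traction outlet well-posed during the end-systolic reversal.
#' @return list with `A` (sparse matrix), `b`, `n`, `d`.
#' @export
assemble_system <- function(mesh, state, theta, materials, dt,
                            picard_U = state$U, stab = NULL,
                            body_force = NULL, kappa1 = 1, kappa2 = 1,
                            outflow = NULL) {
  stopifnot(dt > 0)
  cl <- mesh$cells
  coords <- state$coords
  n <- nrow(coords); d <- ncol(coords); m <- nrow(cl); nv <- d + 1L
  geo <- p1_geometry(list(vertices = coords, cells = cl))
  vol <- geo$vol; G <- geo$grads
  if (any(vol <= 0)) stop("assemble_system: inverted cell in mesh", call. = FALSE)

  rho_c <- ifelse(theta == 1L, materials$rho_fluid, materials$rho_solid)
  mu_eff <- ifelse(theta == 1L, materials$mu_f, dt * materials$mu_s / 2)

  if (is.null(stab)) {
    hK <- mesh_diameters(coords, cl)
    st <- stabilization_params(cell_average(state$U, cl), cell_average(state$M, cl),
                               rho_c, hK, dt, kappa1, kappa2)
  } else st <- stab
  s1 <- st$delta1 * vol
  d2v <- st$delta2 * vol

  Ubar <- (picard_U + state$U) / 2
  arel <- cell_average(Ubar, cl) - cell_average(state$M, cl)
  # adv[, j] = (a . grad lambda_j) per cell
  adv <- matrix(0, m, nv)
  for (j in seq_len(nv)) for (al in seq_len(d))
    adv[, j] <- adv[, j] + arel[, al] * G[, j, al]

  # cell gradient of the Picard midpoint velocity, gU[[al]][[be]] = d(Ubar_al)/dx_be
  gU <- vector("list", d)
  for (al in seq_len(d)) {
    gU[[al]] <- vector("list", d)
    for (be in seq_len(d)) {
      acc <- 0
      for (j in seq_len(nv)) acc <- acc + G[, j, be] * Ubar[cl[, j], al]
      gU[[al]][[be]] <- acc
    }
  }

  # explicit part of the midpoint solid stress:
  # tau_expl = tau_s + (dt/2) (g tau_s + tau_s g^T), zero on fluid cells
  tau_expl <- zero_cell_tensors(m, d)
  sol <- theta == 0L
  if (any(sol)) {
    ts <- state$tau_s
    for (i in seq_len(d)) for (j in seq_len(d)) {
      rot <- 0
      for (q in seq_len(d))
        rot <- rot + gU[[i]][[q]][sol] * ts[sol, (q - 1L) * d + j] +
                     ts[sol, (i - 1L) * d + q] * gU[[j]][[q]][sol]
      tau_expl[sol, (i - 1L) * d + j] <- ts[sol, (i - 1L) * d + j] + dt / 2 * rot
    }
  }

  fv <- NULL; fc <- NULL
  if (!is.null(body_force)) {
    fv <- as.matrix(body_force(coords, state$t + dt / 2))
    fc <- cell_average(fv, cl)
  }

  wphi <- vol / nv
  mass_c <- rho_c * vol / (nv * (nv + 1L)) / dt  # off-diagonal entry; diag x2
  Uprev <- state$U

  N <- (d + 1L) * n
  ti <- list(); tj <- list(); tx <- list()
  ri <- list(); rx <- list()
  push <- function(rows, cols, vals) {
    k <- length(ti) + 1L
    ti[[k]] <<- rows; tj[[k]] <<- cols; tx[[k]] <<- vals
  }
  rpush <- function(rows, vals) {
    k <- length(ri) + 1L
    ri[[k]] <<- rows; rx[[k]] <<- vals
  }
  vdof <- function(al, i) (al - 1L) * n + cl[, i]
  pdof <- function(i) d * n + cl[, i]

  GiGj <- function(i, j) {
    acc <- 0
    for (g in seq_len(d)) acc <- acc + G[, i, g] * G[, j, g]
    acc
  }

  for (i in seq_len(nv)) for (j in seq_len(nv)) {
    gij <- GiGj(i, j)
    for (al in seq_len(d)) {
      rowsa <- vdof(al, i)
      # mass + advection + SD velocity-velocity (component-diagonal)
      mv <- mass_c * (1 + (i == j))
      av <- 0.5 * rho_c * wphi * adv[, j]
      sv <- 0.5 * s1 * rho_c^2 * adv[, i] * adv[, j]
      push(rowsa, vdof(al, j), mv + av + sv)
      rpush(rowsa, mv * Uprev[cl[, j], al] - (av + sv) * Uprev[cl[, j], al])
      # viscous/elastic + grad-div stabilization (couples components)
      for (be in seq_len(d)) {
        visc <- mu_eff * vol * ((al == be) * gij + G[, j, al] * G[, i, be])
        dd2 <- d2v * G[, i, al] * G[, j, be]
        coeff <- 0.5 * (visc + dd2)
        push(rowsa, vdof(be, j), coeff)
        rpush(rowsa, -coeff * Uprev[cl[, j], be])
      }
      # pressure gradient on momentum + SD pressure-in-residual vs adv test
      push(rowsa, pdof(j), -wphi * G[, i, al] + s1 * rho_c^2 * adv[, i] * G[, j, al])
      # continuity + SD advection-in-residual vs grad q test
      cc <- 0.5 * (wphi * G[, j, al] + s1 * rho_c * adv[, j] * G[, i, al])
      push(pdof(i), vdof(al, j), cc)
      rpush(pdof(i), -cc * Uprev[cl[, j], al])
      # body force, consistent mass
      if (!is.null(fv))
        rpush(rowsa, vol * (1 + (i == j)) / (nv * (nv + 1L)) * fv[cl[, j], al])
    }
    # pressure-pressure (PSPG-like) block
    push(pdof(i), pdof(j), s1 * rho_c * gij)
  }
  # cell-constant contributions (independent of trial index j)
  for (i in seq_len(nv)) {
    for (al in seq_len(d)) {
      rowsa <- vdof(al, i)
      # explicit solid stress: -(tau_expl : grad v)
      acc <- 0
      for (be in seq_len(d)) acc <- acc + tau_expl[, (al - 1L) * d + be] * G[, i, be]
      rpush(rowsa, -vol * acc)
      if (!is.null(fc)) {
        rpush(rowsa, s1 * rho_c^2 * adv[, i] * fc[, al])
      }
    }
    if (!is.null(fc)) {
      acc <- 0
      for (al in seq_len(d)) acc <- acc + G[, i, al] * fc[, al]
      rpush(pdof(i), s1 * rho_c * acc)
    }
  }

  # backflow stabilization on open boundaries: where (u - m).n < 0 the
  # entering momentum flux is penalized with a facet mass matrix
  if (!is.null(outflow) && nrow(outflow$facets)) {
    fb <- outflow$facets
    nor <- outflow_normals(coords, fb, outflow$inward)
    len <- facet_measures(coords, fb)
    ubar_f <- 0; m_f <- 0
    for (k in seq_len(d)) {
      ubar_f <- ubar_f + rowMeans(matrix(Ubar[fb, k], nrow(fb))) * nor[, k]
      m_f <- m_f + rowMeans(matrix(state$M[fb, k], nrow(fb))) * nor[, k]
    }
    wbf <- materials$rho_fluid * pmax(-(ubar_f - m_f), 0) * len
    if (any(wbf > 0)) {
      mfac <- if (d == 2L) 6 else 12
      for (i in seq_len(ncol(fb))) for (j in seq_len(ncol(fb))) {
        coef <- 0.5 * wbf * (1 + (i == j)) / mfac
        for (al in seq_len(d)) {
          rows <- (al - 1L) * n + fb[, i]
          push(rows, (al - 1L) * n + fb[, j], coef)
          rpush(rows, -coef * Uprev[fb[, j], al])
        }
      }
    }
  }

  A <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(N, N))
  b <- numeric(N)
  agg <- rowsum(unlist(rx), unlist(ri))
  b[as.integer(rownames(agg))] <- agg[, 1L]
  list(A = A, b = b, n = n, d = d)
}

#' Open-boundary (outflow) data for backflow stabilization
#'
#' Collects the facets of a tagged open boundary together with the inward
#' reference points needed to orient their outward normals at any later
#' coordinate state.
#'
#' @param mesh an `fsi_mesh`.
#' @param name facet set name (default `"outlet"`).
#' @return list with `facets` and `inward` (adjacent-cell vertex index used
#'   to orient the normal), or `NULL` when the set is absent/empty.
#' @export
outflow_data <- function(mesh, name = "outlet") {
  if (!name %in% names(mesh$facet_names)) return(NULL)
  fb <- facet_set(mesh, name)
  if (!nrow(fb)) return(NULL)
  adj <- facet_adjacency(mesh, fb)
  own <- adj[, 1L]
  # opposite vertex of the owning cell: any cell vertex not on the facet
  inward <- integer(nrow(fb))
  for (f in seq_len(nrow(fb)))
    inward[f] <- setdiff(mesh$cells[own[f], ], fb[f, ])[1L]
  list(facets = fb, inward = inward)
}

# outward unit normals of facets, oriented away from the inward vertex
outflow_normals <- function(coords, facets, inward) {
  d <- ncol(coords)
  if (d == 2L) {
    e <- coords[facets[, 2L], , drop = FALSE] - coords[facets[, 1L], , drop = FALSE]
    nor <- cbind(e[, 2L], -e[, 1L])
  } else {
    e1 <- coords[facets[, 2L], , drop = FALSE] - coords[facets[, 1L], , drop = FALSE]
    e2 <- coords[facets[, 3L], , drop = FALSE] - coords[facets[, 1L], , drop = FALSE]
    nor <- cbind(e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L],
                 e1[, 3L] * e2[, 1L] - e1[, 1L] * e2[, 3L],
                 e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L])
  }
  nor <- nor / sqrt(rowSums(nor^2))
  tocell <- coords[inward, , drop = FALSE] - coords[facets[, 1L], , drop = FALSE]
  flip <- rowSums(nor * tocell) > 0
  nor[flip, ] <- -nor[flip, , drop = FALSE]
  nor
}

# per-cell diameters from raw arrays (used during stepping on moving coords)
mesh_diameters <- function(coords, cells) {
  nv <- ncol(cells)
  dmax <- rep(0, nrow(cells))
  for (i in seq_len(nv - 1L)) for (j in seq.int(i + 1L, nv)) {
    e <- coords[cells[, j], , drop = FALSE] - coords[cells[, i], , drop = FALSE]
    dmax <- pmax(dmax, sqrt(rowSums(e * e)))
  }
  dmax
}

#' Impose strong Dirichlet constraints on an assembled system
#'
#' @param A,b assembled matrix and right-hand side.
#' @param dofs integer vector of constrained global dofs.
#' @param values constraint values (recycled).
#' @return list(A, b) with rows/columns eliminated and unit diagonal.
#' @export
apply_dirichlet <- function(A, b, dofs, values) {
  if (!length(dofs)) return(list(A = A, b = b))
  N <- length(b)
  g <- numeric(N); g[dofs] <- values
  b <- b - as.vector(A %*% g)
  A[dofs, ] <- 0
  A[, dofs] <- 0
  A <- A + Matrix::sparseMatrix(i = dofs, j = dofs, x = 1, dims = c(N, N))
  b[dofs] <- g[dofs]
  list(A = A, b = b)
}

# velocity/pressure Dirichlet data -> global dof lists
bc_dofs <- function(bcs, n, d) {
  dofs <- integer(0); vals <- numeric(0)
  if (!is.null(bcs$velocity) && length(bcs$velocity$idx)) {
    V <- as.matrix(bcs$velocity$values)
    if (nrow(V) == 1L) V <- V[rep(1L, length(bcs$velocity$idx)), , drop = FALSE]
    for (al in seq_len(d)) {
      dofs <- c(dofs, (al - 1L) * n + bcs$velocity$idx)
      vals <- c(vals, V[, al])
    }
  }
  if (!is.null(bcs$pressure) && length(bcs$pressure$idx)) {
    dofs <- c(dofs, d * n + bcs$pressure$idx)
    vals <- c(vals, rep_len(bcs$pressure$values, length(bcs$pressure$idx)))
  }
  list(dofs = dofs, vals = vals)
}

#' Solve a sparse linear system
#'
#' Default is Bi-CGStab with Jacobi (diagonal) preconditioning; `"direct"`
#' uses a sparse LU factorization.  Any method must deliver
#' `||b - A x|| <= tol * ||b||`; non-convergence raises a condition of class
#' `valvefsi_solver_error` carrying iteration diagnostics, unless
#' `fallback = TRUE`, in which case the direct solver finishes the job.
#'
#' @param A sparse matrix.
#' @param b right-hand side.
#' @param tol relative residual tolerance.
#' @param method `"bicgstab"` or `"direct"`.
#' @param maxit iteration cap for the Krylov method.
#' @param fallback fall back to the direct solver on Krylov failure.
#' @return solution vector with attributes `iterations` and `residual`.
#' @export
solve_linear <- function(A, b, tol = 1e-8, method = c("bicgstab", "direct"),
                         maxit = 500L, fallback = FALSE) {
  method <- match.arg(method)
  nb <- sqrt(sum(b^2))
  if (nb == 0) return(structure(numeric(length(b)), iterations = 0L, residual = 0))
  if (method == "direct") {
    x <- tryCatch(as.vector(Matrix::solve(A, b)),
                  error = function(e) stop(solver_error(conditionMessage(e), 0L, NA)))
    r <- nb_rel(A, b, x, nb)
    if (!is.finite(r) || r > max(tol, 1e-7))
      stop(solver_error("direct solve residual too large (singular system?)", 0L, r))
    return(structure(x, iterations = 1L, residual = r))
  }
  di <- Matrix::diag(A)
  di[di == 0 | !is.finite(di)] <- 1
  prec <- function(v) v / di
  x <- numeric(length(b))
  r <- b
  rhat <- r
  rho0 <- alpha <- omega <- 1
  v <- p <- numeric(length(b))
  it <- 0L
  ok <- FALSE
  repeat {
    it <- it + 1L
    rho1 <- sum(rhat * r)
    if (abs(rho1) < 1e-300) break
    beta <- (rho1 / rho0) * (alpha / omega)
    p <- r + beta * (p - omega * v)
    ph <- prec(p)
    v <- as.vector(A %*% ph)
    den <- sum(rhat * v)
    if (abs(den) < 1e-300) break
    alpha <- rho1 / den
    s <- r - alpha * v
    if (sqrt(sum(s^2)) <= tol * nb) { x <- x + alpha * ph; ok <- TRUE; break }
    sh <- prec(s)
    tv <- as.vector(A %*% sh)
    tt <- sum(tv * tv)
    if (tt < 1e-300) break
    omega <- sum(tv * s) / tt
    x <- x + alpha * ph + omega * sh
    r <- s - omega * tv
    rho0 <- rho1
    if (sqrt(sum(r^2)) <= tol * nb) { ok <- TRUE; break }
    if (it >= maxit) break
  }
  res <- nb_rel(A, b, x, nb)
  if (!ok && res > tol) {
    if (fallback) return(solve_linear(A, b, tol, "direct"))
    stop(solver_error("Bi-CGStab did not converge", it, res))
  }
  structure(x, iterations = it, residual = res)
}

nb_rel <- function(A, b, x, nb) sqrt(sum((b - as.vector(A %*% x))^2)) / nb

solver_error <- function(msg, iterations, residual) {
  structure(class = c("valvefsi_solver_error", "error", "condition"),
            list(message = sprintf("%s (iterations=%d, residual=%.3e)",
                                   msg, iterations, residual),
                 call = NULL, iterations = iterations, residual = residual))
}

picard_error <- function(msg, iterations, residual) {
  structure(class = c("valvefsi_picard_nonconvergence", "error", "condition"),
            list(message = sprintf("%s (iterations=%d, residual=%.3e)",
                                   msg, iterations, residual),
                 call = NULL, iterations = iterations, residual = residual))
}

#' One Crank-Nicolson step with Picard linearization
#'
#' Fixed-point iteration on the advective velocity and the rotational solid
#' stress terms until the relative update of the solution drops below
#' `picard_tol`; on convergence the solid stress is advanced with the
#' converged midpoint velocity gradient and the mesh velocity on solid
#' vertices is set to the material velocity (U = M in the solid).  If the
#' iteration does not converge within `picard_max` sweeps a condition of
#' class `valvefsi_picard_nonconvergence` is raised: the caller is expected to
#' reject the step and halve dt.
#'
#' @param mesh an `fsi_mesh`.
#' @param state previous `fsi_state`.
#' @param theta per-cell phase.
#' @param materials a [material_constants()].
#' @param bcs Dirichlet data, list(velocity = list(idx, values),
#'   pressure = list(idx, values)).
#' @param dt time step (s).
#' @param control list of solver knobs: `picard_tol`, `picard_max`, `krylov`,
#'   `lin_tol`, `kappa1`, `kappa2`.
#' @param body_force optional manufactured-solution forcing hook.
#' @return the new `fsi_state` (time advanced, coordinates not yet moved),
#'   with attributes `picard_iters` and `picard_res`.
#' @export
picard_step <- function(mesh, state, theta, materials, bcs, dt,
                        control = list(), body_force = NULL, outflow = NULL) {
  ctl <- utils::modifyList(list(picard_tol = 1e-6, picard_max = 50L,
                                krylov = "direct", lin_tol = 1e-9,
                                kappa1 = 1, kappa2 = 1), control)
  n <- nrow(state$coords); d <- ncol(state$coords)
  cl <- mesh$cells
  hK <- mesh_diameters(state$coords, cl)
  rho_c <- ifelse(theta == 1L, materials$rho_fluid, materials$rho_solid)
  stab <- stabilization_params(cell_average(state$U, cl), cell_average(state$M, cl),
                               rho_c, hK, dt, ctl$kappa1, ctl$kappa2)
  bc <- bc_dofs(bcs, n, d)
  Uk <- state$U; Pk <- state$P
  res <- Inf; it <- 0L
  while (it < ctl$picard_max) {
    it <- it + 1L
    sys <- assemble_system(mesh, state, theta, materials, dt, picard_U = Uk,
                           stab = stab, body_force = body_force,
                           kappa1 = ctl$kappa1, kappa2 = ctl$kappa2,
                           outflow = outflow)
    sys <- apply_dirichlet(sys$A, sys$b, bc$dofs, bc$vals)
    z <- solve_linear(sys$A, sys$b, tol = ctl$lin_tol, method = ctl$krylov,
                      fallback = TRUE)
    Un <- matrix(z[seq_len(d * n)], n, d)
    Pn <- z[d * n + seq_len(n)]
    num <- sqrt(sum((Un - Uk)^2))
    den <- max(sqrt(sum(Un^2)), 1e-14)
    res <- num / den
    Uk <- Un; Pk <- Pn
    if (!is.finite(res)) stop(picard_error("diverging Picard residual", it, res))
    if (res < ctl$picard_tol) break
  }
  if (res >= ctl$picard_tol)
    stop(picard_error("Picard iteration did not converge", it, res))

  # advance solid stress with the converged midpoint gradient
  Ubar <- (Uk + state$U) / 2
  geo <- p1_geometry(list(vertices = state$coords, cells = cl))
  grad_cells <- cell_gradients(Ubar, cl, geo, d)
  tau_new <- advance_solid_stress_cells(state$tau_s, grad_cells, materials$mu_s,
                                        dt, which(theta == 0L), d)
  Mn <- state$M
  sv <- solid_vertices(mesh, theta)
  Mn[sv, ] <- Uk[sv, ]
  out <- fsi_state(Uk, Pk, Mn, tau_new, state$t + dt, state$coords)
  attr(out, "picard_iters") <- it
  attr(out, "picard_res") <- res
  out
}

# per-cell velocity gradient, m x (d*d) row-major
cell_gradients <- function(field, cells, geo, d) {
  m <- nrow(cells); nv <- d + 1L
  out <- matrix(0, m, d * d)
  for (i in seq_len(d)) for (j in seq_len(d)) {
    acc <- 0
    for (k in seq_len(nv)) acc <- acc + geo$grads[, k, j] * field[cells[, k], i]
    out[, (i - 1L) * d + j] <- acc
  }
  out
}

#' Residual of the assembled slab system at a given candidate solution
#'
#' Convenience for verification (free-stream preservation and similar
#' checks): assembles the system linearized at `U_new` and returns the
#' relative residual of `(U_new, P_new)`.
#'
#' @inheritParams picard_step
#' @param U_new,P_new candidate end-of-slab solution.
#' @param body_force optional forcing hook.
#' @return relative algebraic residual (scaled by matrix and solution norms).
#' @export
slab_residual <- function(mesh, state, theta, materials, bcs, dt,
                          U_new, P_new, body_force = NULL, outflow = NULL) {
  n <- nrow(state$coords); d <- ncol(state$coords)
  sys <- assemble_system(mesh, state, theta, materials, dt, picard_U = U_new,
                         body_force = body_force, outflow = outflow)
  bc <- bc_dofs(bcs, n, d)
  sys <- apply_dirichlet(sys$A, sys$b, bc$dofs, bc$vals)
  z <- c(as.vector(U_new), P_new)
  r <- as.vector(sys$A %*% z) - sys$b
  sqrt(sum(r^2)) / max(sqrt(sum(sys$b^2)), max(abs(sys$A)) * max(sqrt(sum(z^2)), 1))
}
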