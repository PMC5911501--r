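# ALE mesh motion.  The linear smoother diffuses the structure velocity from
# the fluid-structure interface over the fluid region (a componentwise Poisson
# problem with Dirichlet data), giving the mesh velocity M cheaply every step.
# When cells nevertheless degrade, the nonlinear smoother relaxes interior
# vertex positions down the gradient of a quality-weighted elastic energy,
# with the per-cell quality measure Q(K) concentrating stiffness on the worst
# cells.

#' Smoothing schedule
#' @param pseudo_steps cap on nonlinear pseudo time steps per call.
#' @param pseudo_dt initial pseudo step scale (dimensionless fraction of the
#'   local cell size per unit gradient).
#' @param quality_trigger run the nonlinear smoother only when
#'   `Q_max` exceeds this (default 8).
#' @param max_quality abort threshold for unrecoverable distortion.
#' @return list of class `smoothing_config`.
#' @export
smoothing_config <- function(pseudo_steps = 5L, pseudo_dt = 0.2,
                             quality_trigger = 8, max_quality = 50) {
  stopifnot(pseudo_steps >= 0, quality_trigger > 1, max_quality > 1)
  structure(list(pseudo_steps = as.integer(pseudo_steps), pseudo_dt = pseudo_dt,
                 quality_trigger = quality_trigger, max_quality = max_quality),
            class = "smoothing_config")
}

#' Linear (Poisson) mesh-velocity smoother
#'
#' Solves, componentwise on the fluid region, a Poisson equation for the mesh
#' velocity with Dirichlet data: the structure velocity on the fluid-structure
#' interface vertices and zero on the fixed outer boundaries.  On solid cells
#' the mesh velocity is the material velocity and is not touched here.
#'
#' @param mesh an `fsi_mesh`.
#' @param theta per-cell phase (1 = fluid).
#' @param interface_velocity list(idx, values): interface vertex indices and
#'   their prescribed velocities (`length(idx) x d`).
#' @param fixed_boundary_tags names of facet sets held fixed (M = 0), e.g.
#'   `c("inlet", "outlet", "wall")`.
#' @param coords current coordinates (default: mesh vertices).
#' @return `n x d` matrix of mesh velocities on fluid vertices (zero rows for
#'   vertices not in the fluid region).
#' @export
linear_smooth <- function(mesh, theta, interface_velocity,
                          fixed_boundary_tags = c("inlet", "outlet", "wall"),
                          coords = mesh$vertices) {
  d <- mesh$dim; n <- nrow(coords)
  fl <- which(theta == 1L)
  if (!length(fl)) stop("linear_smooth: empty fluid region", call. = FALSE)
  cl <- mesh$cells[fl, , drop = FALSE]
  fverts <- sort(unique(as.vector(cl)))
  geo <- p1_geometry(list(vertices = coords, cells = cl))

  # P1 stiffness on the fluid subdomain
  nv <- d + 1L
  ti <- list(); tj <- list(); tx <- list()
  for (i in seq_len(nv)) for (j in seq_len(nv)) {
    acc <- 0
    for (g in seq_len(d)) acc <- acc + geo$grads[, i, g] * geo$grads[, j, g]
    k <- length(ti) + 1L
    ti[[k]] <- cl[, i]; tj[[k]] <- cl[, j]; tx[[k]] <- geo$vol * acc
  }
  K <- Matrix::sparseMatrix(i = unlist(ti), j = unlist(tj), x = unlist(tx),
                            dims = c(n, n))

  fixed_idx <- interface_velocity$idx
  fixed_val <- as.matrix(interface_velocity$values)
  for (nm in fixed_boundary_tags) {
    if (!nm %in% names(mesh$facet_names)) next
    bidx <- setdiff(facet_set_vertices(mesh, nm), fixed_idx)
    if (length(bidx)) {
      fixed_idx <- c(fixed_idx, bidx)
      fixed_val <- rbind(fixed_val, matrix(0, length(bidx), d))
    }
  }
  keep <- fixed_idx %in% fverts
  fixed_idx <- fixed_idx[keep]; fixed_val <- fixed_val[keep, , drop = FALSE]
  free <- setdiff(fverts, fixed_idx)
  if (!length(fixed_idx))
    stop("linear_smooth: no Dirichlet data reaches the fluid region", call. = FALSE)

  M <- matrix(0, n, d)
  M[fixed_idx, ] <- fixed_val
  if (length(free)) {
    Kff <- K[free, free, drop = FALSE]
    Kfc <- K[free, fixed_idx, drop = FALSE]
    rhs <- -as.matrix(Kfc %*% fixed_val)
    sol <- tryCatch(as.matrix(Matrix::solve(Kff, rhs)),
                    error = function(e)
                      stop("linear_smooth: singular system (disconnected fluid region?)",
                           call. = FALSE))
    M[free, ] <- sol
  }
  M
}

# quality-weighted elastic energy and its gradient for one configuration.
# Per cell: E_K = Q(F) * W(F), with W(F) = (||F||_F^2/d - 1)/2 + (det F - 1)^2/2
# and F the deformation gradient against an equilateral reference scaled to
# the cell's measure at entry (pinned per smoothing call).
smoother_energy <- function(coords, cells, Sinv_list, d) {
  m <- nrow(cells)
  E <- numeric(m)
  grad <- matrix(0, nrow(coords), d)
  nv <- d + 1L
  Qmax <- 0
  for (c in seq_len(m)) {
    vi <- cells[c, ]
    D <- t(coords[vi[-1L], , drop = FALSE]) - coords[vi[1L], ]
    F <- D %*% Sinv_list[[c]]
    dtF <- det(F)
    if (dtF <= 0) return(list(inverted = TRUE))
    f2 <- sum(F * F)
    Q <- f2 / (d * dtF^(2 / d))
    W <- (f2 / d - 1) / 2 + (dtF - 1)^2 / 2
    E[c] <- Q * W
    Qmax <- max(Qmax, Q)
    Finv_t <- t(solve(F))
    dQ <- (2 / (d * dtF^(2 / d))) * (F - (f2 / d) * Finv_t)
    dW <- F / d + (dtF - 1) * dtF * Finv_t
    dE <- dQ * W + Q * dW            # dE/dF
    dD <- dE %*% t(Sinv_list[[c]])   # dE/dD (chain rule, F = D Sinv)
    for (k in 2:nv) {
      grad[vi[k], ] <- grad[vi[k], ] + dD[, k - 1L]
      grad[vi[1L], ] <- grad[vi[1L], ] - dD[, k - 1L]
    }
  }
  list(inverted = FALSE, E = sum(E), grad = grad, Qmax = Qmax)
}

#' Nonlinear quality-weighted mesh smoother
#'
#' Relaxes interior vertex coordinates by gradient descent on the
#' quality-weighted elastic energy sum_K Q(K) W(F_K), for at most
#' `config$pseudo_steps` pseudo time steps.  Boundary and interface vertices
#' are held fixed.  A pseudo step that would invert a cell or increase the
#' worst quality Q_max is rejected and retried with a halved pseudo step; the
#' committed configuration therefore never contains an inverted cell and
#' Q_max is non-increasing.
#'
#' @param mesh an `fsi_mesh`.
#' @param config a [smoothing_config()].
#' @param free_vertices indices of vertices allowed to move (default: all
#'   vertices not on a tagged facet).
#' @param coords current coordinates (default: mesh vertices).
#' @param cells optional cell subset to smooth over (default: all cells).
#' @return list with `coords` (updated), `Q_max`, `steps` taken, and
#'   `improved` flag (`FALSE` with a warning attribute when the budget was
#'   exhausted without reaching equilibrium).
#' @export
nonlinear_smooth <- function(mesh, config = smoothing_config(),
                             free_vertices = NULL, coords = mesh$vertices,
                             cells = mesh$cells) {
  d <- mesh$dim
  if (is.null(free_vertices)) {
    tagged <- unique(as.vector(mesh$facets))
    free_vertices <- setdiff(sort(unique(as.vector(cells))), tagged)
  }
  if (config$pseudo_steps == 0L || !length(free_vertices)) {
    q <- mesh_cell_quality(coords, cells, d)
    return(list(coords = coords, Q_max = max(q), steps = 0L, improved = TRUE))
  }
  # restrict to cells touching a free vertex
  touch <- rowSums(matrix(cells %in% free_vertices, nrow(cells))) > 0
  cl <- cells[touch, , drop = FALSE]
  # pin reference simplices to the entry measures
  Sref <- reference_edge_matrix(d)
  vol0 <- simplex_signed_measures(coords, cl)
  vref <- abs(det(Sref)) / factorial(d)
  Sinv_list <- lapply(seq_len(nrow(cl)), function(c) {
    s <- (vol0[c] / vref)^(1 / d)
    solve(Sref * s)
  })
  hloc <- min(mesh_diameters(coords, cl))

  st <- smoother_energy(coords, cl, Sinv_list, d)
  if (st$inverted) stop("nonlinear_smooth: mesh already inverted", call. = FALSE)
  eta <- config$pseudo_dt
  steps <- 0L
  for (k in seq_len(config$pseudo_steps)) {
    g <- st$grad
    g[-free_vertices, ] <- 0
    gmax <- max(abs(g))
    if (gmax < 1e-12) break
    accepted <- FALSE
    etak <- eta
    for (try in 1:20) {
      cand <- coords
      cand[free_vertices, ] <- coords[free_vertices, ] -
        etak * hloc * g[free_vertices, ] / gmax
      stc <- smoother_energy(cand, cl, Sinv_list, d)
      if (!stc$inverted && stc$Qmax <= st$Qmax + 1e-12 && stc$E <= st$E) {
        coords <- cand; st <- stc; accepted <- TRUE; break
      }
      etak <- etak / 2
    }
    if (!accepted) break
    steps <- steps + 1L
  }
  # improved = FALSE flags that the pseudo-step budget was exhausted without
  # progress; the caller may respond by reducing the physical time step
  improved <- st$Qmax <= config$quality_trigger || max(abs(st$grad)) < 1e-10 ||
    steps > 0L
  list(coords = coords, Q_max = st$Qmax, steps = steps, improved = improved)
}
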