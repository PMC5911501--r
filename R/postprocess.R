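# Valve-dynamics post-processing: geometric orifice area (GOA), leaflet
# rotation angle and angular velocity, von Mises stress fields, the lambda2
# vortex criterion, and series writers (VTU/PVD, XDMF, CSV).

#' Geometric orifice area
#'
#' The GOA is the area of the closure surface available to flow: the part of
#' the pre-embedded closure surface not occluded by the projection of the
#' leaflet cells along the valve axis.  Computed by dense deterministic
#' sampling of the closure facets (area-weighted) and point-in-projection
#' tests against the leaflet cells.  A closed valve (any closure-attached
#' cell switched to solid) has GOA = 0 exactly.
#'
#' @param mesh an `fsi_mesh` with a `closure` facet set and `axis` metadata.
#' @param theta per-cell phase.
#' @param coords current coordinates.
#' @param n_samples sampling density target over the whole surface.
#' @return the orifice area (m^2 in 3D; an orifice width in m in 2D).
#' @export
geometric_orifice_area <- function(mesh, theta, coords = mesh$vertices,
                                   n_samples = 10000L) {
  cf <- facet_set(mesh, "closure")
  if (!nrow(cf)) stop("geometric_orifice_area: closure surface untagged", call. = FALSE)
  adj <- facet_adjacency(mesh, cf)
  attached <- unique(as.vector(adj[!is.na(adj)]))
  # closed state: a closure-attached cell of the fluid region has been
  # phase-switched to solid (leaflet cells natively border the closure line)
  fl <- mesh$region_names[["fluid"]]
  if (any(theta[attached] == 0L & mesh$region_tags[attached] == fl)) return(0)

  d <- mesh$dim
  axis <- mesh$metadata$axis
  leaf <- which(mesh$region_tags != mesh$region_names[["fluid"]] & theta == 0L)
  areas <- facet_measures(coords, cf)
  total <- sum(areas)
  if (!length(leaf)) return(total)

  # orthonormal frame transverse to the valve axis
  if (d == 2L) {
    t1 <- c(-axis[2L], axis[1L])
    proj <- function(x) as.matrix(x) %*% t1
  } else {
    ref <- if (abs(axis[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    t1 <- ref - sum(ref * axis) * axis; t1 <- t1 / sqrt(sum(t1^2))
    t2 <- c(axis[2L] * t1[3L] - axis[3L] * t1[2L],
            axis[3L] * t1[1L] - axis[1L] * t1[3L],
            axis[1L] * t1[2L] - axis[2L] * t1[1L])
    proj <- function(x) cbind(as.matrix(x) %*% t1, as.matrix(x) %*% t2)
  }

  # deterministic area-weighted samples on the closure facets
  per <- pmax(1L, round(n_samples * areas / total))
  pts <- NULL
  for (f in seq_len(nrow(cf))) {
    fv <- coords[cf[f, ], , drop = FALSE]
    k <- per[f]
    if (d == 2L) {
      s <- (seq_len(k) - 0.5) / k
      pts <- rbind(pts, outer(1 - s, fv[1L, ]) + outer(s, fv[2L, ]))
    } else {
      # triangular lattice of barycentric samples
      nlev <- max(1L, ceiling((sqrt(8 * k + 1) - 1) / 2))
      bc <- NULL
      for (a in seq_len(nlev)) for (b in seq_len(nlev + 1L - a))
        bc <- rbind(bc, c(a - 1/3, b - 1/3, nlev + 1 - a - b + 1/3) / nlev)
      pts <- rbind(pts, bc %*% fv)
    }
  }
  sp <- proj(pts)

  # occlusion: sample covered by the axis-projection of any leaflet cell
  covered <- rep(FALSE, nrow(sp))
  lcl <- mesh$cells[leaf, , drop = FALSE]
  if (d == 2L) {
    for (c in seq_len(nrow(lcl))) {
      y <- proj(coords[lcl[c, ], , drop = FALSE])
      rng <- range(y)
      covered <- covered | (sp[, 1L] >= rng[1L] & sp[, 1L] <= rng[2L])
      if (all(covered)) break
    }
  } else {
    for (c in seq_len(nrow(lcl))) {
      tv <- proj(coords[lcl[c, ], , drop = FALSE])  # 4 projected points
      # a projected tet is covered by its 4 faces' projected triangles
      combs <- utils::combn(4L, 3L)
      for (k in seq_len(ncol(combs))) {
        tri <- tv[combs[, k], , drop = FALSE]
        covered <- covered | point_in_triangle(sp, tri)
      }
      if (all(covered)) break
    }
  }
  total * (1 - sum(covered) / length(covered))
}

point_in_triangle <- function(p, tri) {
  v0 <- tri[3L, ] - tri[1L, ]; v1 <- tri[2L, ] - tri[1L, ]
  den <- v0[1L] * v1[2L] - v1[1L] * v0[2L]
  if (abs(den) < 1e-30) return(rep(FALSE, nrow(p)))
  wx <- p[, 1L] - tri[1L, 1L]; wy <- p[, 2L] - tri[1L, 2L]
  u <- (wx * v1[2L] - wy * v1[1L]) / den
  v <- (wy * v0[1L] - wx * v0[2L]) / den
  u >= -1e-12 & v >= -1e-12 & (u + v) <= 1 + 1e-12
}

#' Leaflet rotation angle about a hinge axis
#'
#' The angle of the leaflet about the hinge axis relative to a closed-position
#' reference direction: each vertex is projected into the plane transverse to
#' the axis and its angular position measured; the leaflet angle is the
#' radius-weighted circular mean.  For a rigid rotation of the leaflet this
#' recovers the rotation angle exactly.
#'
#' @param leaflet_coords vertex coordinates of the leaflet (`k x d`).
#' @param hinge_axis list(point, direction): a point on the axis and the unit
#'   axis direction (in 2D the "axis" is the hinge point and direction is
#'   ignored).
#' @param closed_ref unit vector (transverse to the axis) of the leaflet
#'   direction in the closed position.
#' @return angle alpha in degrees.
#' @export
rotation_angle <- function(leaflet_coords, hinge_axis, closed_ref) {
  x <- as.matrix(leaflet_coords)
  d <- ncol(x)
  p0 <- hinge_axis$point
  if (d == 3L) {
    ax <- hinge_axis$direction / sqrt(sum(hinge_axis$direction^2))
    rel <- sweep(x, 2L, p0)
    rel <- rel - outer(as.vector(rel %*% ax), ax)
    e1 <- closed_ref - sum(closed_ref * ax) * ax
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(ax[2L] * e1[3L] - ax[3L] * e1[2L],
            ax[3L] * e1[1L] - ax[1L] * e1[3L],
            ax[1L] * e1[2L] - ax[2L] * e1[1L])
  } else {
    rel <- sweep(x, 2L, p0)
    e1 <- closed_ref / sqrt(sum(closed_ref^2))
    e2 <- c(-e1[2L], e1[1L])
  }
  c1 <- as.vector(rel %*% e1); c2 <- as.vector(rel %*% e2)
  r <- sqrt(c1^2 + c2^2)
  keep <- r > max(r) * 1e-8
  if (sum(keep) < 1L || max(r) == 0)
    stop("rotation_angle: degenerate leaflet (all vertices on the axis)",
         call. = FALSE)
  ang <- atan2(sum(c2[keep] * r[keep]), sum(c1[keep] * r[keep]))
  ang * 180 / pi
}

#' Angular velocity from an angle series
#' @param alpha angle series (degrees).
#' @param t matching times (s).
#' @return centered-difference angular velocity (degrees/s), one per sample.
#' @export
angular_velocity <- function(alpha, t) {
  n <- length(alpha)
  if (n < 2L) return(rep(0, n))
  om <- numeric(n)
  om[1L] <- (alpha[2L] - alpha[1L]) / (t[2L] - t[1L])
  om[n] <- (alpha[n] - alpha[n - 1L]) / (t[n] - t[n - 1L])
  if (n > 2L)
    om[2:(n - 1L)] <- (alpha[3:n] - alpha[1:(n - 2L)]) / (t[3:n] - t[1:(n - 2L)])
  om
}

#' Lambda2 vortex-criterion field
#'
#' Per cell, with S and Omega the symmetric and antisymmetric parts of the
#' velocity gradient, lambda2 is the middle eigenvalue of S^2 + Omega^2
#' (eigenvalues sorted ascending); vertex values are volume-weighted cell
#' averages.  A vortex core is where lambda2 is below a user-chosen negative
#' threshold (applied at visualization, not here).  Defined for 3D fields
#' only.
#'
#' @param U vertex velocity field (`n x 3`).
#' @param mesh a 3D `fsi_mesh`.
#' @param coords current coordinates.
#' @return list with `cell` (per-cell lambda2) and `vertex` (averaged).
#' @export
lambda2_field <- function(U, mesh, coords = mesh$vertices) {
  if (mesh$dim != 3L)
    stop("lambda2_field: defined for 3D meshes only", call. = FALSE)
  cl <- mesh$cells
  geo <- p1_geometry(list(vertices = coords, cells = cl))
  g <- cell_gradients(as.matrix(U), cl, geo, 3L)
  m <- nrow(cl)
  lam <- numeric(m)
  for (c in seq_len(m)) {
    Gm <- matrix(g[c, ], 3L, 3L, byrow = TRUE)
    S <- (Gm + t(Gm)) / 2; W <- (Gm - t(Gm)) / 2
    B <- S %*% S + W %*% W
    lam[c] <- sort(eigen((B + t(B)) / 2, symmetric = TRUE,
                         only.values = TRUE)$values)[2L]
  }
  vert <- numeric(nrow(coords)); wsum <- numeric(nrow(coords))
  for (k in seq_len(ncol(cl))) {
    tb <- rowsum(lam * geo$vol, cl[, k]); ids <- as.integer(rownames(tb))
    vert[ids] <- vert[ids] + tb[, 1L]
    tb2 <- rowsum(geo$vol, cl[, k])
    wsum[ids] <- wsum[ids] + tb2[, 1L]
  }
  list(cell = lam, vertex = vert / pmax(wsum, 1e-300))
}

#' Von Mises stress field of the composite stress
#'
#' Evaluates tau = tauD - p I per cell (fluid viscous stress or solid stress
#' selected by the phase) and reduces it with [von_mises()].  Optionally on a
#' log10 scale for visualization.
#'
#' @param state an `fsi_state`.
#' @param mesh an `fsi_mesh`.
#' @param theta per-cell phase.
#' @param materials a [material_constants()].
#' @param log_scale return log10(tau_v) (with floor 1e-12).
#' @return per-cell von Mises stress (Pa).
#' @export
von_mises_field <- function(state, mesh, theta, materials, log_scale = FALSE) {
  cl <- mesh$cells; d <- mesh$dim
  geo <- p1_geometry(list(vertices = state$coords, cells = cl))
  g <- cell_gradients(state$U, cl, geo, d)
  pcell <- rowMeans(matrix(state$P[cl], nrow(cl)))
  m <- nrow(cl)
  out <- numeric(m)
  for (c in seq_len(m)) {
    if (theta[c] == 1L) {
      tauD <- fluid_stress(matrix(g[c, ], d, d, byrow = TRUE), materials$mu_f)
    } else {
      tauD <- matrix(state$tau_s[c, ], d, d, byrow = TRUE)
    }
    # the pressure is isotropic in all three directions; a 2D deviatoric
    # stress embeds with zero out-of-plane components
    T3 <- diag(-pcell[c], 3)
    T3[seq_len(d), seq_len(d)] <- T3[seq_len(d), seq_len(d)] + tauD
    out[c] <- von_mises(T3)
  }
  if (log_scale) log10(pmax(out, 1e-12)) else out
}

#' Write a trajectory to disk
#'
#' Emits one VTU per stored snapshot (point fields U, P; cell fields theta,
#' von Mises stress, quality), a PVD index, an XDMF copy of the final state,
#' and the scalar time series as CSV.
#'
#' @param trajectory result of [run_simulation()].
#' @param outdir output directory (created if missing).
#' @param materials a [material_constants()] (for the stress field); taken
#'   from the trajectory if absent.
#' @return character vector of the files written, invisibly; warns and writes
#'   nothing for an empty trajectory.
#' @export
write_outputs <- function(trajectory, outdir, materials = trajectory$materials) {
  if (!length(trajectory$snapshots)) {
    warning("write_outputs: empty trajectory, nothing written", call. = FALSE)
    return(invisible(character(0)))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  mesh <- trajectory$mesh
  files <- character(0)
  vtus <- character(0); times <- numeric(0)
  for (k in seq_along(trajectory$snapshots)) {
    snap <- trajectory$snapshots[[k]]
    st <- snap$state
    mk <- mesh; mk$vertices <- st$coords
    q <- mesh_cell_quality(st$coords, mesh$cells, mesh$dim)
    vm <- von_mises_field(st, mesh, snap$theta, materials)
    fn <- sprintf("step_%04d.vtu", k)
    write_vtu(mk, file.path(outdir, fn),
              point_data = list(U = st$U, P = matrix(st$P, ncol = 1L)),
              cell_data = list(theta = as.numeric(snap$theta), tau_vm = vm, Q = q))
    vtus <- c(vtus, fn); times <- c(times, st$t)
    files <- c(files, file.path(outdir, fn))
  }
  pvd <- file.path(outdir, "series.pvd")
  write_pvd(vtus, times, pvd)
  last <- trajectory$snapshots[[length(trajectory$snapshots)]]
  mk <- mesh; mk$vertices <- last$state$coords
  xd <- file.path(outdir, "final.xdmf")
  write_xdmf(mk, xd, point_data = list(U = last$state$U,
                                       P = matrix(last$state$P, ncol = 1L)),
             cell_data = list(theta = matrix(as.numeric(last$theta), ncol = 1L)))
  csv <- file.path(outdir, "timeseries.csv")
  utils::write.csv(trajectory$timeseries, csv, row.names = FALSE)
  invisible(c(files, pvd, xd, csv))
}

#' Segment a GOA trace into the four valve phases
#'
#' Classifies a geometric-orifice-area series into rapid opening, quasi-steady
#' open, gradual closure, and rapid closure, by locating the first time the
#' trace reaches a high fraction of its maximum, the last time it leaves it,
#' and the closing instant (first zero after the plateau).
#'
#' @param t times (s).
#' @param goa GOA series.
#' @param plateau_frac fraction of max defining "widely open" (default 0.9).
#' @return list with the four phase durations (s) and the boundary times, or
#'   `NULL` when the trace never opens or never closes.
#' @export
goa_phases <- function(t, goa, plateau_frac = 0.9) {
  gmax <- max(goa)
  if (gmax <= 0) return(NULL)
  hi <- goa >= plateau_frac * gmax
  if (!any(hi)) return(NULL)
  i_open <- which(hi)[1L]
  i_leave <- which(hi)[length(which(hi))]
  closed <- which(goa <= 0 & seq_along(goa) > i_leave)
  if (!length(closed)) return(NULL)
  i_closed <- closed[1L]
  # rapid closure onset: last time above a low fraction before full closure
  low <- which(goa[seq_len(i_closed)] >= 0.25 * gmax)
  i_rapid <- if (length(low)) low[length(low)] else i_leave
  list(rvot = t[i_open] - t[1L],
       open = t[i_leave] - t[i_open],
       gradual = t[i_rapid] - t[i_leave],
       rvct = t[i_closed] - t[i_rapid],
       t_open = t[i_open], t_leave = t[i_leave],
       t_rapid = t[i_rapid], t_closed = t[i_closed])
}
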