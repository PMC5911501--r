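# Valve contact: collision detection between leaflet surfaces (exact
# geometric distance, or an Eikonal distance field solved on the mesh),
# closure by phase switching of the cells attached under the pre-embedded
# closure surface, contact release at the start of systole, and hinge-angle
# locking for bileaflet mechanical valves.

#' Contact bookkeeping
#' @param threshold closing distance threshold (m).
#' @return list of class `contact_state` with `d_min`, `closed`, `threshold`
#'   and the index set `closed_cells` of phase-switched cells.
#' @export
contact_state <- function(threshold) {
  stopifnot(threshold > 0)
  structure(list(d_min = Inf, closed = FALSE, threshold = threshold,
                 closed_cells = integer(0)), class = "contact_state")
}

# facets of a region's cells shared with cells of any other region
region_surface <- function(mesh, region_name) {
  cidx <- region_cells(mesh, region_name)
  af <- cell_facets_all(mesh$cells, mesh$dim)
  keys <- facet_key(af$sorted)
  inreg <- af$cell %in% cidx
  # facets appearing once within the region are its surface (either mesh
  # boundary or shared with a different region)
  cnt <- table(keys[inreg])
  surf <- names(cnt)[cnt == 1L]
  af$facets[inreg, , drop = FALSE][match(surf, keys[inreg]), , drop = FALSE]
}

point_facet_distance <- function(p, fv) {
  # fv: facet vertex coordinates (d x d matrix, rows = vertices)
  d <- length(p)
  if (d == 2L) {
    a <- fv[1L, ]; b <- fv[2L, ]
    u <- b - a; w <- p - a
    t <- if (sum(u * u) > 0) max(0, min(1, sum(w * u) / sum(u * u))) else 0
    sqrt(sum((w - t * u)^2))
  } else {
    a <- fv[1L, ]; b <- fv[2L, ]; c <- fv[3L, ]
    # project onto the triangle plane, clamp to the triangle
    u <- b - a; v <- c - a; w <- p - a
    uu <- sum(u * u); vv <- sum(v * v); uv <- sum(u * v)
    det <- uu * vv - uv^2
    if (det <= 0) return(min(sqrt(sum((p - a)^2)), sqrt(sum((p - b)^2)),
                             sqrt(sum((p - c)^2))))
    s <- (vv * sum(w * u) - uv * sum(w * v)) / det
    t <- (uu * sum(w * v) - uv * sum(w * u)) / det
    if (s >= 0 && t >= 0 && s + t <= 1) {
      sqrt(sum((w - s * u - t * v)^2))
    } else {
      # closest point is on an edge
      min(point_facet_distance(p, fv[c(1L, 2L), ]),
          point_facet_distance(p, fv[c(1L, 3L), ]),
          point_facet_distance(p, fv[c(2L, 3L), ]))
    }
  }
}

surface_pair_distance <- function(coords, surfA, surfB) {
  dmin <- Inf
  va <- sort(unique(as.vector(surfA)))
  vb <- sort(unique(as.vector(surfB)))
  for (f in seq_len(nrow(surfB))) {
    fv <- coords[surfB[f, ], , drop = FALSE]
    for (p in va) dmin <- min(dmin, point_facet_distance(coords[p, ], fv))
  }
  for (f in seq_len(nrow(surfA))) {
    fv <- coords[surfA[f, ], , drop = FALSE]
    for (p in vb) dmin <- min(dmin, point_facet_distance(coords[p, ], fv))
  }
  dmin
}

#' Distance between two leaflet surfaces
#'
#' `method = "geometric"` returns the exact minimum point-to-facet distance
#' between the two surfaces.  `method = "eikonal"` solves the distance
#' equation |grad(phi)| = 1 from surface i on the mesh by a Hopf-Lax
#' fixed-point iteration (edge and two-point facet updates, iterated to
#' convergence) and evaluates the field on surface j; it bounds the geometric
#' distance from above and agrees with it within about two cell diameters.
#'
#' @param mesh an `fsi_mesh`.
#' @param leaflet_i,leaflet_j region names of the two leaflets (a wall facet
#'   set name may stand in for a rigid counterpart in fixtures).
#' @param method `"geometric"` or `"eikonal"`.
#' @param coords current coordinates.
#' @return the surface-to-surface distance `d_ij` (m); 0 when the surfaces
#'   share vertices.
#' @export
leaflet_distance <- function(mesh, leaflet_i, leaflet_j,
                             method = c("geometric", "eikonal"),
                             coords = mesh$vertices) {
  method <- match.arg(method)
  getsurf <- function(nm) {
    if (nm %in% names(mesh$region_names)) region_surface(mesh, nm)
    else facet_set(mesh, nm)
  }
  sA <- getsurf(leaflet_i); sB <- getsurf(leaflet_j)
  if (!nrow(sA) || !nrow(sB))
    stop("leaflet_distance: empty leaflet surface", call. = FALSE)
  if (length(intersect(as.vector(sA), as.vector(sB)))) return(0)
  if (method == "geometric") {
    surface_pair_distance(coords, sA, sB)
  } else {
    phi <- eikonal_distance(mesh, sA, coords)
    min(phi[sort(unique(as.vector(sB)))])
  }
}

# two-point Hopf-Lax update: min over the segment [a, b] of
# lambda*pa + (1-lambda)*pb + |c - (lambda a + (1-lambda) b)|
hl_two_point <- function(pa, pb, a, b, cpt) {
  u <- a - b; w <- cpt - b
  A <- sum(u * u); B <- sum(u * w); C <- sum(w * w)
  s <- pa - pb
  cand <- c(0, 1)
  den <- A - s^2
  if (abs(den) > 1e-30 && A > 0) {
    disc <- B^2 - A * (B^2 - s^2 * C) / den
    if (disc >= 0) {
      r <- sqrt(disc)
      cand <- c(cand, (B + r) / A, (B - r) / A)
    }
  }
  best <- Inf
  for (lam in cand) {
    if (lam < 0 || lam > 1 || !is.finite(lam)) next
    g2 <- C - 2 * lam * B + lam^2 * A
    val <- pb + lam * s + sqrt(max(g2, 0))
    best <- min(best, val)
  }
  best
}

#' Eikonal distance field from a surface
#'
#' Vertex distances to `source_facets`, by exact initialization near the
#' source followed by Hopf-Lax fixed-point sweeps (edge updates plus
#' two-point updates within every cell) until stationary.  The result is an
#' upper bound on the true Euclidean distance, consistent to O(h).
#'
#' @param mesh an `fsi_mesh`.
#' @param source_facets facet matrix of the source surface.
#' @param coords current coordinates.
#' @param max_sweeps iteration cap.
#' @return numeric vector of per-vertex distances.
#' @export
eikonal_distance <- function(mesh, source_facets, coords = mesh$vertices,
                             max_sweeps = 200L) {
  n <- nrow(coords); d <- mesh$dim
  phi <- rep(Inf, n)
  src <- sort(unique(as.vector(source_facets)))
  phi[src] <- 0
  # exact distances for vertices of cells touching the source
  touch <- which(rowSums(matrix(mesh$cells %in% src, nrow(mesh$cells))) > 0)
  near <- setdiff(sort(unique(as.vector(mesh$cells[touch, , drop = FALSE]))), src)
  for (p in near) {
    best <- Inf
    for (f in seq_len(nrow(source_facets)))
      best <- min(best, point_facet_distance(coords[p, ],
                  coords[source_facets[f, ], , drop = FALSE]))
    phi[p] <- best
  }
  cl <- mesh$cells; nv <- d + 1L
  pairs <- utils::combn(nv, 2L)
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (c in seq_len(nrow(cl))) {
      vi <- cl[c, ]
      for (k in seq_len(ncol(pairs))) {
        i <- vi[pairs[1L, k]]; j <- vi[pairs[2L, k]]
        others <- setdiff(vi, c(i, j))
        if (is.finite(phi[i]) && is.finite(phi[j])) {
          for (t in others) {
            val <- hl_two_point(phi[i], phi[j], coords[i, ], coords[j, ], coords[t, ])
            if (val < phi[t] - 1e-14) { phi[t] <- val; changed <- TRUE }
          }
        }
        e <- sqrt(sum((coords[i, ] - coords[j, ])^2))
        if (phi[i] + e < phi[j] - 1e-14) { phi[j] <- phi[i] + e; changed <- TRUE }
        if (phi[j] + e < phi[i] - 1e-14) { phi[i] <- phi[j] + e; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  phi
}

# cells directly attached under the closure surface: for each closure facet,
# the adjacent cell on the upstream side of the valve axis
closure_layer_cells <- function(mesh, coords = mesh$vertices) {
  cf <- facet_set(mesh, "closure")
  if (!nrow(cf)) stop("closure surface untagged", call. = FALSE)
  adj <- facet_adjacency(mesh, cf)
  axis <- mesh$metadata$axis
  if (is.null(axis)) stop("mesh metadata lacks the valve axis", call. = FALSE)
  out <- integer(0)
  for (f in seq_len(nrow(cf))) {
    fc <- colMeans(coords[cf[f, ], , drop = FALSE])
    cells <- adj[f, !is.na(adj[f, ])]
    proj <- vapply(cells, function(c)
      sum((colMeans(coords[mesh$cells[c, ], , drop = FALSE]) - fc) * axis), 0)
    out <- c(out, cells[which.min(proj)])
  }
  sort(unique(out))
}

#' Close the valve by phase switching
#'
#' If the minimal leaflet distance is below the threshold, every fluid cell
#' directly attached under the closure surface (one layer on the upstream
#' side) flips its phase 1 -> 0 in a single step; the whole orifice is closed
#' at once, which is acceptable because the closing moment of a healthy valve
#' is very short.  Cell count and topology never change.  Idempotent when
#' already closed.
#'
#' @param mesh an `fsi_mesh` with a tagged `closure` facet set and axis
#'   metadata.
#' @param theta per-cell phase vector.
#' @param contact a `contact_state`.
#' @param d_min current minimal leaflet distance (m).
#' @param coords current coordinates.
#' @return list with updated `theta` and `contact`.
#' @export
check_and_close <- function(mesh, theta, contact, d_min, coords = mesh$vertices) {
  contact$d_min <- d_min
  if (!contact$closed && d_min < contact$threshold) {
    layer <- closure_layer_cells(mesh, coords)
    switched <- layer[theta[layer] == 1L]
    theta[switched] <- 0L
    contact$closed <- TRUE
    contact$closed_cells <- switched
  }
  list(theta = theta, contact = contact)
}

#' Release valve contact
#'
#' At the start of the next contraction phase (systole) all phase-switched
#' cells revert to fluid and their solid stress is zeroed.
#'
#' @param theta per-cell phase.
#' @param contact a `contact_state`.
#' @param tau_s per-cell solid stress matrix.
#' @param event cycle event name (release happens on `"systole_start"`).
#' @return list with updated `theta`, `contact`, `tau_s`.
#' @export
release_contact <- function(theta, contact, tau_s, event) {
  if (contact$closed && identical(event, "systole_start")) {
    theta[contact$closed_cells] <- 1L
    tau_s[contact$closed_cells, ] <- 0
    contact$closed <- FALSE
    contact$closed_cells <- integer(0)
  }
  list(theta = theta, contact = contact, tau_s = tau_s)
}

#' Hinge state of a bileaflet mechanical valve
#' @param n_leaflets number of leaflets (2).
#' @param alpha_max maximal opening angle (degrees, default 45).
#' @param alpha_closed closing angle limit (degrees, default 0).
#' @return list of class `hinge_state`.
#' @export
hinge_state <- function(n_leaflets = 2L, alpha_max = 45, alpha_closed = 0) {
  structure(list(alpha = rep(0, n_leaflets), omega = rep(0, n_leaflets),
                 locked_open = rep(FALSE, n_leaflets),
                 locked_closed = rep(FALSE, n_leaflets),
                 alpha_max = alpha_max, alpha_closed = alpha_closed),
            class = "hinge_state")
}

#' Advance hinge locking logic
#'
#' Release rules are checked before lock rules so a leaflet cannot oscillate
#' within one step: a leaflet locked open is released when the mean pressure
#' above the valve exceeds the mean pressure below it; a leaflet locked
#' closed is released when a new heart cycle starts.  A free leaflet locks
#' open when its angle reaches `alpha_max` (reported angle clamped there) and
#' locks closed at `alpha_closed`.
#'
#' @param hs a `hinge_state`.
#' @param alpha_new measured leaflet angles (degrees).
#' @param dt time step for the angular velocity estimate (s).
#' @param p_above,p_below mean pressures above/below the valve (Pa).
#' @param new_cycle `TRUE` when a cycle-start event fell in this step.
#' @return updated `hinge_state`; `locked_open | locked_closed` per leaflet
#'   indicates that zero-velocity constraints must be applied to that
#'   leaflet's vertices.
#' @export
update_hinge <- function(hs, alpha_new, dt, p_above, p_below, new_cycle = FALSE) {
  rel_open <- hs$locked_open & (p_above > p_below)
  hs$locked_open[rel_open] <- FALSE
  if (new_cycle) hs$locked_closed[] <- FALSE
  free <- !(hs$locked_open | hs$locked_closed)
  hit_open <- free & (alpha_new >= hs$alpha_max)
  hit_closed <- free & (alpha_new <= hs$alpha_closed)
  hs$locked_open[hit_open] <- TRUE
  hs$locked_closed[hit_closed] <- TRUE
  alpha_eff <- pmin(pmax(alpha_new, hs$alpha_closed), hs$alpha_max)
  alpha_eff[hs$locked_open] <- hs$alpha_max
  alpha_eff[hs$locked_closed] <- hs$alpha_closed
  hs$omega <- (alpha_eff - hs$alpha) / dt
  hs$alpha <- alpha_eff
  hs
}

#' Area-weighted mean pressure over a probe surface
#'
#' Exact for P1 pressure: per facet the vertex average equals the centroid
#' value of the linear field; facets are weighted by their measure.
#'
#' @param P vertex pressure vector.
#' @param mesh an `fsi_mesh`.
#' @param probe facet matrix, or the name of a tagged facet set.
#' @param coords current coordinates.
#' @return the mean pressure (Pa).
#' @export
mean_pressure <- function(P, mesh, probe, coords = mesh$vertices) {
  facets <- if (is.character(probe)) facet_set(mesh, probe) else probe
  if (!nrow(facets)) stop("mean_pressure: empty probe surface", call. = FALSE)
  areas <- facet_measures(coords, facets)
  vals <- rowMeans(matrix(P[facets], nrow(facets)))
  sum(areas * vals) / sum(areas)
}
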