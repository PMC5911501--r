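# Parametric valve geometries as tagged simplicial meshes.
#
# All three generators are fully procedural (structured): a triangulated disk
# cross-section is extruded level by level into prisms, and each prism is
# split into three tetrahedra by the minimal-vertex-index rule, which chooses
# every quad-face diagonal through the face's smallest global vertex index
# and cones the cell from its smallest vertex -- adjacent prisms therefore
# always agree on shared faces and the mesh is conforming by construction.
# Leaflets are tagged cell sets following grid lines snapped to the key
# heights, not CAD-fitted surfaces; at desk-scale resolution this preserves
# every quantity the model consumes (tags, closure surface, attachment,
# radii) while requiring no external mesher.
#
# Inputs are in millimetres (the natural unit of the anatomical parameters);
# mesh coordinates are stored in metres (SI).

MM <- 1e-3

#' Aortic-root generator parameters
#'
#' Anatomical defaults: inner annulus radius 20 mm, sinotubular radius 22 mm,
#' leaflet height (open position) 20 mm, commissure height 6 mm, leaflet
#' thickness 1 mm.  The annulus plane P_A (z = 0) and the sinotubular plane
#' P_S (z = h_l) are parallel; R_A, R_S and h_l define a truncated cone along
#' which the open leaflets lie.  The free edge of each leaflet is the cone cut
#' by a per-sector plane determined by the commissure height and the opening
#' angle beta: flat at height h_c over an angular span beta about the sector
#' centre, rising linearly to the commissures (at height h_l) at the sector
#' boundaries.  The sinus of Valsalva is a fixed bulge profile scaled to the
#' root (not a free parameter).
#'
#' @param R_A inner annulus radius (mm).
#' @param R_S inner sinotubular radius (mm).
#' @param h_l leaflet height in the open position (mm).
#' @param h_c commissure height (mm).
#' @param t_l leaflet thickness (mm).
#' @param beta rotational opening angle of the cutting plane (degrees,
#'   0 < beta < 120).
#' @param aorta_length length of the attached ascending-aorta cylinder (mm).
#' @param mesh_size target cell diameter (mm).
#' @return validated list of class `root_params`.
#' @export
root_params <- function(R_A = 20, R_S = 22, h_l = 20, h_c = 6, t_l = 1,
                        beta = 60, aorta_length = 15, mesh_size = 2.5) {
  geom_check(all(c(R_A, R_S, h_l, h_c, t_l, aorta_length, mesh_size) > 0),
             "all lengths must be positive")
  geom_check(t_l < h_l, "leaflet thickness t_l must be below leaflet height h_l")
  geom_check(h_c < h_l, "commissure height h_c must be below leaflet height h_l")
  geom_check(beta > 0 && beta < 120, "opening angle beta must lie in (0, 120)")
  structure(list(R_A = R_A, R_S = R_S, h_l = h_l, h_c = h_c, t_l = t_l,
                 beta = beta, aorta_length = aorta_length,
                 mesh_size = mesh_size), class = "root_params")
}

geom_check <- function(ok, msg) {
  if (!ok) stop(structure(class = c("valvefsi_geometry_error", "error", "condition"),
                          list(message = msg, call = NULL)))
  invisible(TRUE)
}

# ---- structured disk + extrusion ------------------------------------------

# triangulated unit disk: centre vertex + nr rings of n_phi vertices
disk_template <- function(nr, n_phi) {
  ang <- 2 * pi * (seq_len(n_phi) - 1L) / n_phi
  verts <- rbind(c(0, 0),
                 do.call(rbind, lapply(seq_len(nr), function(i)
                   cbind(cos(ang), sin(ang)) * (i / nr))))
  ring <- function(i, j) 1L + (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  tris <- NULL
  for (j in seq_len(n_phi)) tris <- rbind(tris, c(1L, ring(1L, j), ring(1L, j + 1L)))
  if (nr > 1L) for (i in seq_len(nr - 1L)) for (j in seq_len(n_phi)) {
    a <- ring(i, j); b <- ring(i, j + 1L); A <- ring(i + 1L, j); B <- ring(i + 1L, j + 1L)
    tris <- rbind(tris, c(a, b, B), c(a, B, A))
  }
  # radial fraction per vertex (0 at centre, 1 on rim)
  rfrac <- c(0, rep(seq_len(nr) / nr, each = n_phi))
  list(verts = verts, tris = tris, rfrac = rfrac, n = nrow(verts),
       rim = 1L + (nr - 1L) * n_phi + seq_len(n_phi))
}

# split prism (bottom tri a b c, top A B C; global ids) into 3 tets by the
# minimal-index rule
split_prism <- function(ids) {
  quads <- list(c(1L, 2L, 5L, 4L), c(2L, 3L, 6L, 5L), c(3L, 1L, 4L, 6L))
  tris <- list(c(1L, 2L, 3L), c(4L, 5L, 6L))
  for (q in quads) {
    gq <- ids[q]
    mpos <- which.min(gq)
    rot <- ((mpos - 1L + 0:3) %% 4L) + 1L
    qq <- q[rot]
    tris <- c(tris, list(qq[c(1L, 2L, 3L)]), list(qq[c(1L, 3L, 4L)]))
  }
  apex_loc <- which.min(ids)
  tets <- NULL
  for (tr in tris) {
    if (apex_loc %in% tr) next
    tets <- rbind(tets, c(ids[apex_loc], ids[tr]))
  }
  tets
}

# extrude a disk template along z with per-level radius scaling; returns
# vertices (m) and tets
extrude_disk <- function(tpl, z_levels, radius_at) {
  nz <- length(z_levels)
  n <- tpl$n
  verts <- NULL
  for (k in seq_len(nz)) {
    R <- radius_at(z_levels[k])
    verts <- rbind(verts, cbind(tpl$verts * R, z_levels[k]))
  }
  tets <- vector("list", (nz - 1L) * nrow(tpl$tris))
  prisms <- vector("list", length(tets))
  cnt <- 0L
  for (k in seq_len(nz - 1L)) {
    off0 <- (k - 1L) * n; off1 <- k * n
    for (tnum in seq_len(nrow(tpl$tris))) {
      tri <- tpl$tris[tnum, ]
      cnt <- cnt + 1L
      tt <- split_prism(c(off0 + tri, off1 + tri))
      tets[[cnt]] <- tt
      prisms[[cnt]] <- cbind(rep(cnt, nrow(tt)),
                             matrix(rep(c(off0 + tri, off1 + tri), each = nrow(tt)),
                                    nrow(tt)))
    }
  }
  pr <- do.call(rbind, prisms)
  list(verts = verts, cells = do.call(rbind, tets),
       prism_of_cell = pr[, 1L], prism_vertices = pr[, -1L, drop = FALSE])
}

# boundary facet classification for an extruded tube along z
tube_facet_tags <- function(verts, cells, z0, z1,
                            facet_names = c(inlet = 1L, outlet = 2L, wall = 3L)) {
  mesh0 <- list(vertices = verts, cells = cells, dim = 3L)
  bf <- boundary_facets(structure(mesh0, class = "fsi_mesh"))
  zf <- matrix(verts[bf, 3L], nrow(bf))
  tol <- 1e-9 * max(abs(z1), 1)
  tags <- rep(facet_names[["wall"]], nrow(bf))
  tags[apply(abs(zf - z0) < tol, 1L, all)] <- facet_names[["inlet"]]
  tags[apply(abs(zf - z1) < tol, 1L, all)] <- facet_names[["outlet"]]
  list(facets = bf, tags = tags)
}

# ---- native aortic root ----------------------------------------------------

# free-edge height profile (mm) at angle phi (radians), threefold periodic
root_free_edge_height <- function(phi, params) {
  deg <- (phi * 180 / pi) %% 120       # position within a sector
  psi <- abs(deg - 60)                 # distance to sector centre, 0..60
  b2 <- params$beta / 2
  # flat belly at h_c over the span beta about the sector centre, rising
  # linearly to h_l at the commissures (psi = 60)
  ramp <- pmax(0, (psi - b2) / (60 - b2))
  params$h_c + (params$h_l - params$h_c) * ramp
}

#' Generate the idealized native aortic root
#'
#' Produces a watertight tetrahedral mesh of the aortic root with threefold
#' symmetry about the z-axis: annulus plane at z = 0 with inner radius R_A,
#' sinotubular junction at z = h_l with inner radius R_S, a fixed sinus
#' bulge between them, an attached ascending-aorta cylinder of radius R_S,
#' three leaflets of thickness t_l tagged as solid cell shells along the
#' truncated cone, and an interior closure surface spanning the orifice at
#' the belly height of the leaflet free edges.
#'
#' @param params a [root_params()].
#' @return an `fsi_mesh` (coordinates in metres) with regions `fluid`,
#'   `leaflet1..3`, facet sets `inlet`, `outlet`, `wall`, `closure`, and
#'   metadata `axis = c(0,0,1)` plus the generating parameters.
#' @export
generate_aortic_root <- function(params = root_params()) {
  stopifnot(inherits(params, "root_params"))
  p <- params
  z_top <- p$h_l + p$aorta_length
  nz_root <- max(4L, ceiling(p$h_l / p$mesh_size))
  zr <- sort(unique(c(seq(0, p$h_l, length.out = nz_root + 1L), p$h_c)))
  # drop levels colliding with h_c
  zr <- zr[c(TRUE, diff(zr) > 0.2 * p$mesh_size) | zr %in% c(0, p$h_c, p$h_l)]
  zr <- sort(unique(c(zr, 0, p$h_c, p$h_l)))
  za <- seq(p$h_l, z_top, length.out = max(2L, ceiling(p$aorta_length / p$mesh_size)) + 1L)
  z_levels <- sort(unique(c(zr, za)))

  cone_radius <- function(z) p$R_A + (p$R_S - p$R_A) * pmin(z, p$h_l) / p$h_l
  bulge <- function(z) ifelse(z <= p$h_l,
                              0.25 * p$R_S * sin(pi * pmin(pmax(z, 0), p$h_l) / p$h_l), 0)
  wall_radius <- function(z) cone_radius(z) + bulge(z)

  nr <- max(4L, ceiling(p$R_S / p$mesh_size))
  n_phi <- 3L * max(4L, round(2 * pi * p$R_A / (3 * p$mesh_size)))
  tpl <- disk_template(nr, n_phi)
  ex <- extrude_disk(tpl, z_levels, wall_radius)

  verts_mm <- ex$verts
  cells <- ex$cells

  # leaflet tagging: thin shell just inside the cone, below the free edge.
  # Membership is decided per PRISM (the extrusion cell), not per tetrahedron:
  # the prism lattice is exactly threefold symmetric, whereas the tet split
  # depends on global vertex indices; tagging whole prisms keeps the leaflet
  # vertex sets bitwise symmetric under 120-degree rotation.
  pv <- ex$prism_vertices
  cent <- (verts_mm[pv[, 1L], ] + verts_mm[pv[, 2L], ] + verts_mm[pv[, 3L], ] +
           verts_mm[pv[, 4L], ] + verts_mm[pv[, 5L], ] + verts_mm[pv[, 6L], ]) / 6
  rc <- sqrt(cent[, 1L]^2 + cent[, 2L]^2)
  zc <- cent[, 3L]
  # thresholds carry a small offset (well above rounding noise, far below the
  # cell size) so lattice centroids never sit exactly on a membership boundary
  eps_r <- 1e-7 * p$R_S
  t_eff <- pmax(p$t_l, 1.4 * wall_radius(zc) / nr)
  in_shell <- rc >= cone_radius(zc) - t_eff - eps_r &
    rc <= cone_radius(zc) + eps_r & zc < p$h_l
  # local free-edge height: most permissive vertex of the prism, so the
  # leaflet reaches the commissures at z = h_l exactly
  vphi <- atan2(verts_mm[, 2L], verts_mm[, 1L])
  zfree_v <- root_free_edge_height(vphi, p)
  zfree_max <- apply(matrix(zfree_v[pv], nrow(pv)), 1L, max)
  zcell_top <- apply(matrix(verts_mm[pv, 3L], nrow(pv)), 1L, max)
  is_leaf <- in_shell & (zcell_top <= zfree_max + 1e-9)

  phic <- atan2(cent[, 2L], cent[, 1L]) %% (2 * pi)
  sector <- pmin(floor(phic / (2 * pi / 3)), 2)
  region <- rep(1L, nrow(cells))
  region[is_leaf] <- 2L + sector[is_leaf]
  geom_check(all(table(factor(region[is_leaf], levels = 2:4)) > 0),
             "cutting plane misses the cone: a leaflet received no cells")

  bt <- tube_facet_tags(verts_mm, cells, 0, z_top)
  facets <- bt$facets; ftags <- bt$tags

  # closure surface: interior horizontal facets at z = h_c inside the leaflets
  af <- cell_facets_all(cells, 3L)
  zfac <- matrix(verts_mm[af$facets, 3L], nrow(af$facets))
  horiz <- abs(zfac - p$h_c) < 1e-9 * max(1, p$h_c)
  flat <- which(apply(horiz, 1L, all))
  if (length(flat)) {
    ff <- af$sorted[flat, , drop = FALSE]
    ff <- ff[!duplicated(facet_key(ff)), , drop = FALSE]
    rf <- rowMeans(matrix(sqrt(verts_mm[ff, 1L]^2 + verts_mm[ff, 2L]^2), nrow(ff)))
    keep <- rf < cone_radius(p$h_c) - pmax(p$t_l, 1.4 * wall_radius(p$h_c) / nr)
    if (any(keep)) {
      facets <- rbind(facets, ff[keep, , drop = FALSE])
      ftags <- c(ftags, rep(5L, sum(keep)))
    }
  }

  fsi_mesh(verts_mm * MM, cells, region,
           facets = facets, facet_tags = ftags,
           region_names = c(fluid = 1L, leaflet1 = 2L, leaflet2 = 3L, leaflet3 = 4L),
           facet_names = c(inlet = 1L, outlet = 2L, wall = 3L, closure = 5L),
           metadata = list(kind = "aortic_root", axis = c(0, 0, 1),
                           params = unclass(p), units = "m (inputs mm)"))
}

#' Measured rim radii of a generated root (mm)
#'
#' Mean distance from the z-axis of the wall vertices on the annulus plane
#' (z = 0) and on the sinotubular junction plane (z = h_l); the generator's
#' self-consistency check against R_A and R_S.
#'
#' @param mesh a mesh from [generate_aortic_root()].
#' @return named numeric: `annulus`, `sinotubular` (mm).
#' @export
root_rim_radii <- function(mesh) {
  p <- mesh$metadata$params
  wv <- facet_set_vertices(mesh, "wall")
  z <- mesh$vertices[wv, 3L] / MM
  r <- sqrt(mesh$vertices[wv, 1L]^2 + mesh$vertices[wv, 2L]^2) / MM
  tol <- 1e-6
  c(annulus = mean(r[abs(z) < tol]),
    sinotubular = mean(r[abs(z - p$h_l) < tol]))
}

# ---- simplified BMHV in an idealized aorta --------------------------------

#' Bileaflet-mechanical-valve generator parameters
#'
#' Two rigid semicircular disc leaflets embedded in an idealized straight
#' aorta, reduced to the leaflets only; the housing is not modelled and the
#' geometry guarantees that the leaflets never touch each other.  Each
#' leaflet rotates about a hinge axis fixed by two edge points; the rotation
#' angle is limited to `[alpha_closed, alpha_open_max]`, with the maximal
#' angular opening 45 degrees by default.
#'
#' @param aorta_radius tube radius (mm).
#' @param leaflet_chord semicircular disc diameter (mm).
#' @param leaflet_thickness disc thickness (mm).
#' @param hinge_offset distance of each hinge axis from the tube axis (mm).
#' @param hinge_height axial position of the hinge plane (mm).
#' @param tube_length tube length (mm).
#' @param alpha_open_max maximal opening angle (degrees).
#' @param alpha_closed closed-position angle (degrees).
#' @param initial_angle starting angle of both leaflets (degrees).
#' @param mesh_size target cell diameter (mm).
#' @return validated list of class `bmhv_params`.
#' @export
bmhv_params <- function(aorta_radius = 12, leaflet_chord = 16,
                        leaflet_thickness = 1.5, hinge_offset = 3.5,
                        hinge_height = 15, tube_length = 45,
                        alpha_open_max = 45, alpha_closed = 0,
                        initial_angle = 0, mesh_size = 2.5) {
  geom_check(all(c(aorta_radius, leaflet_chord, leaflet_thickness,
                   tube_length, mesh_size) > 0), "all lengths must be positive")
  geom_check(initial_angle >= alpha_closed && initial_angle <= alpha_open_max,
             "initial_angle must lie within [alpha_closed, alpha_open_max]")
  geom_check(hinge_offset > 0 && hinge_offset < aorta_radius,
             "hinge axes must be distinct and inside the tube")
  geom_check(leaflet_chord / 2 <= aorta_radius,
             "leaflet disc would overlap the tube wall")
  geom_check(hinge_height > leaflet_chord / 2 &&
             hinge_height < tube_length - leaflet_chord / 2,
             "leaflets must fit inside the tube axially")
  structure(list(aorta_radius = aorta_radius, leaflet_chord = leaflet_chord,
                 leaflet_thickness = leaflet_thickness,
                 hinge_offset = hinge_offset, hinge_height = hinge_height,
                 tube_length = tube_length, alpha_open_max = alpha_open_max,
                 alpha_closed = alpha_closed, initial_angle = initial_angle,
                 mesh_size = mesh_size), class = "bmhv_params")
}

#' Generate the simplified BMHV-in-aorta mesh
#'
#' Straight tube of radius `aorta_radius` along z with two semicircular disc
#' leaflets tagged as solid cell sets.  Leaflet 1 hinges about the line
#' x = -hinge_offset (axis along y) and opens toward negative x; leaflet 2
#' mirrors it.  In the closed position (angle 0) the discs lie in the plane
#' z = hinge_height; `initial_angle` rotates both about their hinge axes
#' (tip moving downstream).  Hinge axes, angle limits and closed-reference
#' directions are recorded in the mesh metadata.
#'
#' @param params a [bmhv_params()].
#' @return an `fsi_mesh` with regions `fluid`, `leaflet1`, `leaflet2`.
#' @export
generate_bmhv <- function(params = bmhv_params()) {
  stopifnot(inherits(params, "bmhv_params"))
  p <- params
  nr <- max(4L, ceiling(p$aorta_radius / p$mesh_size))
  n_phi <- max(12L, 2L * round(pi * p$aorta_radius / p$mesh_size))
  nz <- max(8L, ceiling(p$tube_length / p$mesh_size))
  z_levels <- sort(unique(c(seq(0, p$tube_length, length.out = nz + 1L),
                            p$hinge_height)))
  tpl <- disk_template(nr, n_phi)
  ex <- extrude_disk(tpl, z_levels, function(z) p$aorta_radius)
  verts_mm <- ex$verts; cells <- ex$cells

  cent <- (verts_mm[cells[, 1L], ] + verts_mm[cells[, 2L], ] +
           verts_mm[cells[, 3L], ] + verts_mm[cells[, 4L], ]) / 4
  alpha <- p$initial_angle * pi / 180
  t_eff <- max(p$leaflet_thickness, 0.9 * p$mesh_size)
  region <- rep(1L, nrow(cells))
  hinge <- list()
  for (lf in 1:2) {
    sgn <- if (lf == 1L) -1 else 1
    xh <- sgn * p$hinge_offset
    # leaflet frame: xi = in-plane distance from the hinge line toward the
    # wall, rotated by alpha about the hinge axis (tip moves downstream)
    dx <- (cent[, 1L] - xh) * sgn
    dz <- cent[, 3L] - p$hinge_height
    xi <- dx * cos(alpha) + dz * sin(alpha)
    dn <- -dx * sin(alpha) + dz * cos(alpha)
    inside <- abs(dn) <= t_eff / 2 & xi >= 0 &
      (xi^2 + cent[, 2L]^2) <= (p$leaflet_chord / 2)^2 &
      sqrt(cent[, 1L]^2 + cent[, 2L]^2) <= p$aorta_radius - 0.05 * p$aorta_radius
    geom_check(any(inside), "leaflet received no cells (mesh too coarse?)")
    region[inside] <- 1L + lf
    yh <- sqrt(max((p$leaflet_chord / 2)^2 - 0, 0))
    hinge[[lf]] <- list(
      points = rbind(c(xh, -yh, p$hinge_height) * MM,
                     c(xh, yh, p$hinge_height) * MM),
      point = c(xh, 0, p$hinge_height) * MM,
      direction = c(0, 1, 0),
      closed_ref = c(sgn, 0, 0),
      region = paste0("leaflet", lf))
  }
  geom_check(!any(region[region > 1L] == 0),
             "leaflets overlap")

  bt <- tube_facet_tags(verts_mm, cells, 0, p$tube_length)
  fsi_mesh(verts_mm * MM, cells, region,
           facets = bt$facets, facet_tags = bt$tags,
           region_names = c(fluid = 1L, leaflet1 = 2L, leaflet2 = 3L),
           facet_names = c(inlet = 1L, outlet = 2L, wall = 3L),
           metadata = list(kind = "bmhv", axis = c(0, 0, 1),
                           params = unclass(p), hinges = hinge,
                           alpha_max = p$alpha_open_max,
                           alpha_closed = p$alpha_closed,
                           initial_angle = p$initial_angle))
}

# ---- 2D valve channel fixture ---------------------------------------------

#' Generate a 2D channel with flexible valve leaflets
#'
#' Desk-scale analogue of the valve problem: a rectangular channel with flow
#' along +x, one (bottom) or two (bottom and top) flexible leaflet strips
#' tagged as solid, and a closure line of interior facets across the full
#' channel cross-section at the leaflet station.  Facet sets: `inlet`
#' (x = 0), `outlet` (x = L), `wall` (y = 0, H), `closure`.
#'
#' @param channel_length,channel_height channel dimensions (m).
#' @param leaflet_length leaflet strip length (m), measured from the wall.
#' @param leaflet_thickness strip thickness (m).
#' @param mesh_size target cell size (m).
#' @param n_leaflets 1 or 2.
#' @param leaflet_x wall anchor station of the leaflet strips (m; default
#'   0.35 L).
#' @param tilt_deg resting tilt of the strips toward the outlet (degrees from
#'   the upright position; 0 = perpendicular to the walls).  A tilted rest
#'   position mimics a partially open valve: reversed flow then sweeps the
#'   tips through a long arc toward coaptation.
#' @return a 2D `fsi_mesh`.
#' @export
generate_2d_valve_channel <- function(channel_length, channel_height,
                                      leaflet_length, leaflet_thickness,
                                      mesh_size, n_leaflets = 2L,
                                      leaflet_x = 0.35 * channel_length,
                                      tilt_deg = 0) {
  geom_check(all(c(channel_length, channel_height, leaflet_length,
                   leaflet_thickness, mesh_size) > 0),
             "all dimensions must be positive")
  geom_check(leaflet_length < channel_height,
             "leaflet_length must be smaller than channel_height")
  geom_check(abs(tilt_deg) < 75, "resting tilt must stay below 75 degrees")
  tilt <- tilt_deg * pi / 180
  reach <- leaflet_length * cos(tilt)
  if (n_leaflets == 2L)
    geom_check(2 * reach < channel_height,
               "two leaflets must leave a gap between their tips")
  x_tip <- leaflet_x + leaflet_length * sin(tilt)
  geom_check(leaflet_x - leaflet_thickness > 0 &&
             x_tip + leaflet_thickness < channel_length,
             "leaflet must sit strictly inside the channel")

  snap_breaks <- function(from, to, size, must) {
    br <- seq(from, to, length.out = max(2L, ceiling((to - from) / size)) + 1L)
    br <- sort(unique(c(br, must)))
    keep <- c(TRUE, diff(br) > 0.3 * size)
    keep[match(must, br)] <- TRUE
    keep[1L] <- TRUE; keep[length(br)] <- TRUE
    sort(unique(br[keep]))
  }
  t_eff <- max(leaflet_thickness, 1.05 * mesh_size)
  x0 <- leaflet_x - t_eff / 2
  x1 <- leaflet_x + t_eff / 2
  xs <- snap_breaks(0, channel_length, mesh_size, unique(c(x0, x1, x_tip)))
  ymust <- leaflet_length
  if (n_leaflets == 2L) ymust <- c(ymust, channel_height - leaflet_length)
  ys <- snap_breaks(0, channel_height, mesh_size, ymust)

  nx <- length(xs); ny <- length(ys)
  verts <- cbind(rep(xs, times = ny), rep(ys, each = nx))
  vid <- function(i, j) (j - 1L) * nx + i
  cells <- NULL
  for (j in seq_len(ny - 1L)) for (i in seq_len(nx - 1L)) {
    a <- vid(i, j); b <- vid(i + 1L, j); c <- vid(i + 1L, j + 1L); d <- vid(i, j + 1L)
    if ((i + j) %% 2L == 0L) cells <- rbind(cells, c(a, b, c), c(a, c, d))
    else cells <- rbind(cells, c(a, b, d), c(b, c, d))
  }

  # leaflet membership: upright strips conforming to the grid; the resting
  # tilt is applied afterwards as a smooth pre-deformation of the whole mesh
  cent <- (verts[cells[, 1L], ] + verts[cells[, 2L], ] + verts[cells[, 3L], ]) / 3
  in_strip <- cent[, 1L] > x0 & cent[, 1L] < x1
  region <- rep(1L, nrow(cells))
  region[in_strip & cent[, 2L] < leaflet_length] <- 2L
  if (n_leaflets == 2L)
    region[in_strip & cent[, 2L] > channel_height - leaflet_length] <- 3L
  geom_check(sum(region > 1L) > 0L, "leaflet strip contains no cells")
  geom_check(sum(region == 1L) > 0L, "no fluid cells remain")

  # boundary facets
  mesh0 <- structure(list(vertices = verts, cells = cells, dim = 2L),
                     class = "fsi_mesh")
  bf <- boundary_facets(mesh0)
  fx <- matrix(verts[bf, 1L], nrow(bf)); fy <- matrix(verts[bf, 2L], nrow(bf))
  tol <- 1e-12 * channel_length
  tags <- rep(3L, nrow(bf))
  tags[apply(abs(fx) < tol, 1L, all)] <- 1L
  tags[apply(abs(fx - channel_length) < tol, 1L, all)] <- 2L
  # closure line: interior vertical edges spanning the channel at the
  # downstream face of the upright leaflet station -- the coapting tips
  # converge onto this line, so the switched cell layer blocks them
  iy <- which(abs(xs - x1) < 1e-12)
  cl_edges <- cbind(vid(iy, seq_len(ny - 1L)), vid(iy, seq_len(ny - 1L) + 1L))
  facets <- rbind(bf, cl_edges)
  tags <- c(tags, rep(5L, nrow(cl_edges)))

  rn <- c(fluid = 1L, leaflet1 = 2L)
  if (n_leaflets == 2L) rn <- c(rn, leaflet2 = 3L)
  mesh <- fsi_mesh(verts, cells, region, facets = facets, facet_tags = tags,
                   region_names = rn,
                   facet_names = c(inlet = 1L, outlet = 2L, wall = 3L, closure = 5L),
                   metadata = list(kind = "channel2d", axis = c(1, 0),
                                   leaflet_x = leaflet_x, tilt_deg = tilt_deg,
                                   channel = c(channel_length, channel_height),
                                   leaflet = c(leaflet_length, leaflet_thickness),
                                   gap = if (n_leaflets == 2L)
                                     channel_height - 2 * reach
                                   else channel_height - reach))
  if (tilt != 0) {
    # pre-bend: shear each strip toward the outlet (tip displacement
    # sin(tilt)*xi downstream, (1 - cos(tilt))*xi toward the wall, xi the
    # distance from the anchor wall), harmonically extended into the fluid.
    # The deformed configuration is the stress-free rest state.
    th <- initial_phase(mesh)
    sv <- solid_vertices(mesh, th)
    n_all <- nrow(mesh$vertices)
    disp <- matrix(0, n_all, 2L)
    y <- mesh$vertices[sv, 2L]
    xi <- ifelse(y <= channel_height / 2, y, channel_height - y)
    sgn <- ifelse(y <= channel_height / 2, 1, -1)
    disp[sv, 1L] <- sin(tilt) * xi
    disp[sv, 2L] <- -sgn * (1 - cos(tilt)) * xi
    # applied in small increments with quality-driven relaxation in between,
    # exactly as the solver moves the mesh during a run
    n_inc <- max(5L, ceiling(abs(tilt_deg) / 4))
    free <- setdiff(seq_len(n_all), c(sv, unique(as.vector(facets))))
    for (k in seq_len(n_inc)) {
      step <- disp / n_inc
      ext <- linear_smooth(mesh, th, list(idx = sv, values = step[sv, , drop = FALSE]),
                           fixed_boundary_tags = c("inlet", "outlet", "wall"))
      ext[sv, ] <- step[sv, , drop = FALSE]
      cand <- mesh$vertices + ext
      geom_check(all(simplex_signed_measures(cand, mesh$cells) > 0),
                 "resting tilt too large for this mesh size (inverted cell)")
      q <- mesh_cell_quality(cand, mesh$cells, 2L)
      if (max(q) > 4) {
        ns <- nonlinear_smooth(mesh, smoothing_config(pseudo_steps = 30L,
                                                      quality_trigger = 2,
                                                      max_quality = 1e6),
                               free_vertices = free, coords = cand)
        cand <- ns$coords
      }
      mesh$vertices <- cand
    }
  }
  mesh
}
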