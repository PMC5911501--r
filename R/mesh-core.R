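# Mesh container and per-cell geometry for the moving-mesh FSI solver.
#
# A mesh is a plain list of class "fsi_mesh": simplicial (triangles in 2D,
# tetrahedra in 3D), with integer region tags per cell and integer tags on an
# explicit facet list (boundary facets plus tagged interior facets such as the
# valve closure surface).  Cells are kept positively oriented so that all
# signed measures and deformation-gradient determinants are > 0.

#' Construct a tagged simplicial mesh
#'
#' @param vertices numeric matrix, one row per vertex (`n x dim`), coordinates
#'   in metres.
#' @param cells integer matrix, one row per simplex (`m x (dim+1)`), 1-based
#'   vertex indices.  Cells with negative orientation are reordered.
#' @param region_tags integer vector of length `m`; which named region each
#'   cell belongs to (see `region_names`).
#' @param facets integer matrix (`f x dim`) of tagged facets (edges in 2D,
#'   triangles in 3D), or `NULL` for none.
#' @param facet_tags integer vector of length `f`.
#' @param region_names named integer vector mapping region names (must include
#'   `"fluid"`) to tag values.
#' @param facet_names named integer vector mapping facet-set names (e.g.
#'   `"inlet"`, `"outlet"`, `"wall"`, `"closure"`) to tag values.
#' @param metadata free-form list (generator parameters, valve axis, hinge
#'   definitions, ...).
#'
#' @return an object of class `fsi_mesh`.
#' @export
fsi_mesh <- function(vertices, cells, region_tags = NULL,
                     facets = NULL, facet_tags = NULL,
                     region_names = c(fluid = 1L),
                     facet_names = integer(0),
                     metadata = list()) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dim <- ncol(vertices)
  if (!dim %in% c(2L, 3L))
    stop("fsi_mesh: only 2D and 3D meshes are supported", call. = FALSE)
  cells <- as.matrix(cells)
  storage.mode(cells) <- "integer"
  if (ncol(cells) != dim + 1L)
    stop("fsi_mesh: cells must have dim+1 vertices (simplices only)", call. = FALSE)
  if (any(cells < 1L) || any(cells > nrow(vertices)))
    stop("fsi_mesh: cell vertex index out of range", call. = FALSE)
  if (is.null(region_tags)) region_tags <- rep(1L, nrow(cells))
  region_tags <- as.integer(region_tags)
  if (length(region_tags) != nrow(cells))
    stop("fsi_mesh: one region tag per cell required", call. = FALSE)

  # enforce positive orientation
  vol <- simplex_signed_measures(vertices, cells)
  flip <- which(vol < 0)
  if (length(flip)) {
    tmp <- cells[flip, 1L]
    cells[flip, 1L] <- cells[flip, 2L]
    cells[flip, 2L] <- tmp
    vol[flip] <- -vol[flip]
  }
  if (any(vol <= 0))
    stop("fsi_mesh: degenerate (zero-measure) cell", call. = FALSE)

  if (is.null(facets)) {
    facets <- matrix(integer(0), 0L, dim)
    facet_tags <- integer(0)
  } else {
    facets <- as.matrix(facets)
    storage.mode(facets) <- "integer"
    if (ncol(facets) != dim)
      stop("fsi_mesh: facets must have dim vertices", call. = FALSE)
    facet_tags <- as.integer(facet_tags)
    if (length(facet_tags) != nrow(facets))
      stop("fsi_mesh: one tag per facet required", call. = FALSE)
  }

  m <- structure(list(
    vertices = vertices, cells = cells, dim = dim,
    region_tags = region_tags, facets = facets, facet_tags = facet_tags,
    region_names = region_names, facet_names = facet_names,
    metadata = metadata), class = "fsi_mesh")
  m
}

#' @export
print.fsi_mesh <- function(x, ...) {
  cat(sprintf("<fsi_mesh> %dD, %d vertices, %d cells, %d tagged facets\n",
              x$dim, nrow(x$vertices), nrow(x$cells), nrow(x$facets)))
  cat("  regions:", paste(sprintf("%s=%d(%d cells)", names(x$region_names),
      x$region_names, vapply(x$region_names, function(t)
        sum(x$region_tags == t), 0L)), collapse = ", "), "\n")
  if (length(x$facet_names))
    cat("  facet sets:", paste(sprintf("%s=%d(%d)", names(x$facet_names),
        x$facet_names, vapply(x$facet_names, function(t)
          sum(x$facet_tags == t), 0L)), collapse = ", "), "\n")
  invisible(x)
}

# signed simplex measures: area (2D) or volume (3D)
simplex_signed_measures <- function(vertices, cells) {
  d <- ncol(vertices)
  a <- vertices[cells[, 1L], , drop = FALSE]
  if (d == 2L) {
    e1 <- vertices[cells[, 2L], , drop = FALSE] - a
    e2 <- vertices[cells[, 3L], , drop = FALSE] - a
    (e1[, 1L] * e2[, 2L] - e1[, 2L] * e2[, 1L]) / 2
  } else {
    e1 <- vertices[cells[, 2L], , drop = FALSE] - a
    e2 <- vertices[cells[, 3L], , drop = FALSE] - a
    e3 <- vertices[cells[, 4L], , drop = FALSE] - a
    (e1[, 1L] * (e2[, 2L] * e3[, 3L] - e2[, 3L] * e3[, 2L]) -
     e1[, 2L] * (e2[, 1L] * e3[, 3L] - e2[, 3L] * e3[, 1L]) +
     e1[, 3L] * (e2[, 1L] * e3[, 2L] - e2[, 2L] * e3[, 1L])) / 6
  }
}

#' Cell measures (areas in 2D, volumes in 3D)
#' @param mesh an `fsi_mesh`.
#' @return numeric vector, one positive measure per cell.
#' @export
cell_volumes <- function(mesh) {
  simplex_signed_measures(mesh$vertices, mesh$cells)
}

#' Per-cell diameters and the minimum diameter
#'
#' The diameter of a simplex is its maximal edge length; the minimum over
#' cells drives CFL time-step control.
#'
#' @param mesh an `fsi_mesh`.
#' @return `cell_diameters`: numeric vector of per-cell maximal edge lengths.
#' @export
cell_diameters <- function(mesh) {
  cl <- mesh$cells
  nv <- ncol(cl)
  dmax <- rep(0, nrow(cl))
  for (i in seq_len(nv - 1L)) for (j in seq.int(i + 1L, nv)) {
    e <- mesh$vertices[cl[, j], , drop = FALSE] - mesh$vertices[cl[, i], , drop = FALSE]
    dmax <- pmax(dmax, sqrt(rowSums(e * e)))
  }
  dmax
}

#' @rdname cell_diameters
#' @return `min_diameter`: the smallest cell diameter of the mesh.
#' @export
min_diameter <- function(mesh) min(cell_diameters(mesh))

# Reference equilateral simplex edge matrices (columns = edge vectors from
# vertex 1). Scale is irrelevant to the quality measure, which is invariant
# under uniform scaling of either the cell or the reference.
reference_edge_matrix <- function(d) {
  if (d == 2L) {
    matrix(c(1, 0, 0.5, sqrt(3) / 2), 2L, 2L)
  } else {
    matrix(c(1, 0, 0,
             0.5, sqrt(3) / 2, 0,
             0.5, sqrt(3) / 6, sqrt(2 / 3)), 3L, 3L)
  }
}

#' Simplex shape quality Q(K)
#'
#' Q(K) = ||F||_F^2 / (d * det(F)^(2/d)), where F is the deformation gradient
#' mapping a scaled equilateral reference simplex onto the cell and d the
#' spatial dimension.  Q = 1 exactly when the cell is similar to the
#' equilateral reference (AM-GM equality on the singular values of F) and
#' grows without bound as the cell degenerates; it is invariant under rigid
#' motions and uniform scaling.
#'
#' @param cell_coords `(d+1) x d` matrix of simplex vertex coordinates.
#' @param dim spatial dimension, 2 or 3 (defaults to `ncol(cell_coords)`).
#' @return the quality value, a scalar `>= 1`.
#' @export
cell_quality <- function(cell_coords, dim = ncol(cell_coords)) {
  cell_coords <- as.matrix(cell_coords)
  d <- as.integer(dim)
  if (nrow(cell_coords) != d + 1L || ncol(cell_coords) != d)
    stop("cell_quality: expected a (d+1) x d coordinate matrix", call. = FALSE)
  D <- t(cell_coords[-1L, , drop = FALSE]) - cell_coords[1L, ]
  F <- D %*% solve(reference_edge_matrix(d))
  dtF <- det(F)
  if (!is.finite(dtF) || abs(dtF) < .Machine$double.eps * sum(F * F))
    stop("cell_quality: degenerate simplex (collinear/coplanar vertices)",
         call. = FALSE)
  if (dtF < 0) { # orientation does not affect shape; reflect one coordinate
    D[1L, ] <- -D[1L, ]; F <- D %*% solve(reference_edge_matrix(d)); dtF <- det(F)
  }
  sum(F * F) / (d * dtF^(2 / d))
}

#' Mesh-wide quality report
#'
#' Evaluates the quality measure Q(K) on every cell.
#'
#' @param mesh an `fsi_mesh`.
#' @return a list with `Q_per_cell`, `Q_max` and `Q_mean`.
#' @export
quality_report <- function(mesh) {
  q <- mesh_cell_quality(mesh$vertices, mesh$cells, mesh$dim)
  list(Q_per_cell = q, Q_max = max(q), Q_mean = mean(q))
}

# vectorized Q over all cells; assumes positive orientation
mesh_cell_quality <- function(vertices, cells, d) {
  Sinv <- solve(reference_edge_matrix(d))
  a <- vertices[cells[, 1L], , drop = FALSE]
  if (d == 2L) {
    e1 <- vertices[cells[, 2L], , drop = FALSE] - a
    e2 <- vertices[cells[, 3L], , drop = FALSE] - a
    # F = [e1 e2] %*% Sinv, per cell
    F11 <- e1[, 1] * Sinv[1, 1] + e2[, 1] * Sinv[2, 1]
    F12 <- e1[, 1] * Sinv[1, 2] + e2[, 1] * Sinv[2, 2]
    F21 <- e1[, 2] * Sinv[1, 1] + e2[, 2] * Sinv[2, 1]
    F22 <- e1[, 2] * Sinv[1, 2] + e2[, 2] * Sinv[2, 2]
    dtF <- F11 * F22 - F12 * F21
    if (any(dtF <= 0)) stop("quality: inverted or degenerate cell", call. = FALSE)
    (F11^2 + F12^2 + F21^2 + F22^2) / (2 * dtF)
  } else {
    E <- lapply(2:4, function(k) vertices[cells[, k], , drop = FALSE] - a)
    Fc <- vector("list", 9L) # F[i,j] per cell, column-major
    for (i in 1:3) for (j in 1:3) {
      Fc[[i + 3L * (j - 1L)]] <-
        E[[1L]][, i] * Sinv[1, j] + E[[2L]][, i] * Sinv[2, j] + E[[3L]][, i] * Sinv[3, j]
    }
    Fm <- function(i, j) Fc[[i + 3L * (j - 1L)]]
    dtF <- Fm(1,1) * (Fm(2,2) * Fm(3,3) - Fm(2,3) * Fm(3,2)) -
           Fm(1,2) * (Fm(2,1) * Fm(3,3) - Fm(2,3) * Fm(3,1)) +
           Fm(1,3) * (Fm(2,1) * Fm(3,2) - Fm(2,2) * Fm(3,1))
    if (any(dtF <= 0)) stop("quality: inverted or degenerate cell", call. = FALSE)
    fro <- Reduce(`+`, lapply(Fc, function(x) x^2))
    fro / (3 * dtF^(2 / 3))
  }
}

#' P1 element geometry: measures and constant basis gradients
#'
#' For piecewise-linear elements on simplices the basis-function gradients are
#' constant per cell; they are the workhorse of all assembly routines.
#'
#' @param mesh an `fsi_mesh` (or a list with `vertices`, `cells`).
#' @return list with `vol` (per-cell measure) and `grads`, an array of
#'   dimension `m x (d+1) x d` holding grad(lambda_i) per cell.
#' @export
p1_geometry <- function(mesh) {
  v <- mesh$vertices; cl <- mesh$cells; d <- ncol(v)
  m <- nrow(cl)
  a <- v[cl[, 1L], , drop = FALSE]
  grads <- array(0, c(m, d + 1L, d))
  if (d == 2L) {
    e1 <- v[cl[, 2L], , drop = FALSE] - a
    e2 <- v[cl[, 3L], , drop = FALSE] - a
    det <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
    # rows of inv([e1 e2]): grad lambda2 = (e2y, -e2x)/det etc.
    grads[, 2L, 1L] <-  e2[, 2] / det; grads[, 2L, 2L] <- -e2[, 1] / det
    grads[, 3L, 1L] <- -e1[, 2] / det; grads[, 3L, 2L] <-  e1[, 1] / det
    grads[, 1L, ] <- -(grads[, 2L, ] + grads[, 3L, ])
    list(vol = det / 2, grads = grads)
  } else {
    e1 <- v[cl[, 2L], , drop = FALSE] - a
    e2 <- v[cl[, 3L], , drop = FALSE] - a
    e3 <- v[cl[, 4L], , drop = FALSE] - a
    # inverse of J = [e1 e2 e3] via cofactors; rows of J^{-1} are the gradients
    c11 <-  e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]
    c12 <- -(e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1])
    c13 <-  e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1]
    c21 <- -(e1[, 2] * e3[, 3] - e1[, 3] * e3[, 2])
    c22 <-  e1[, 1] * e3[, 3] - e1[, 3] * e3[, 1]
    c23 <- -(e1[, 1] * e3[, 2] - e1[, 2] * e3[, 1])
    c31 <-  e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
    c32 <- -(e1[, 1] * e2[, 3] - e1[, 3] * e2[, 1])
    c33 <-  e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
    det <- e1[, 1] * c11 + e1[, 2] * c12 + e1[, 3] * c13
    grads[, 2L, 1L] <- c11 / det; grads[, 2L, 2L] <- c12 / det; grads[, 2L, 3L] <- c13 / det
    grads[, 3L, 1L] <- c21 / det; grads[, 3L, 2L] <- c22 / det; grads[, 3L, 3L] <- c23 / det
    grads[, 4L, 1L] <- c31 / det; grads[, 4L, 2L] <- c32 / det; grads[, 4L, 3L] <- c33 / det
    grads[, 1L, ] <- -(grads[, 2L, ] + grads[, 3L, ] + grads[, 4L, ])
    list(vol = det / 6, grads = grads)
  }
}

# ---- facet utilities -------------------------------------------------------

# all facets of all cells; returns list(facets = f x d matrix (sorted vertex
# ids), cell = owning cell index, local = local facet index)
cell_facets_all <- function(cells, d) {
  if (d == 2L) {
    loc <- list(c(1L, 2L), c(2L, 3L), c(3L, 1L))
  } else {
    loc <- list(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))
  }
  m <- nrow(cells)
  fac <- do.call(rbind, lapply(loc, function(ix) cells[, ix, drop = FALSE]))
  own <- rep(seq_len(m), times = length(loc))
  key <- t(apply(fac, 1L, sort))
  list(facets = fac, sorted = key, cell = own)
}

facet_key <- function(sorted_facets) {
  apply(sorted_facets, 1L, paste, collapse = "_")
}

#' Facet-to-cell adjacency
#'
#' For each facet in `facets`, finds the indices of the cells that contain it
#' (1 for a boundary facet, 2 for an interior facet).
#'
#' @param mesh an `fsi_mesh`.
#' @param facets integer matrix of facets (default: the mesh's tagged facets).
#' @return integer matrix `f x 2` of adjacent cell indices (`NA` for absent
#'   second neighbour).
#' @export
facet_adjacency <- function(mesh, facets = mesh$facets) {
  af <- cell_facets_all(mesh$cells, mesh$dim)
  keys <- facet_key(af$sorted)
  want <- facet_key(t(apply(facets, 1L, sort)))
  idx <- split(af$cell, keys)
  out <- matrix(NA_integer_, nrow(facets), 2L)
  hit <- idx[want]
  for (i in seq_along(hit)) {
    ci <- hit[[i]]
    if (is.null(ci)) stop("facet_adjacency: facet not part of the mesh", call. = FALSE)
    out[i, seq_along(ci)] <- ci
  }
  out
}

#' Boundary facets of a mesh
#'
#' @param mesh an `fsi_mesh`.
#' @return integer matrix of facets belonging to exactly one cell, with the
#'   vertex ordering induced by the owning cell.
#' @export
boundary_facets <- function(mesh) {
  af <- cell_facets_all(mesh$cells, mesh$dim)
  keys <- facet_key(af$sorted)
  cnt <- table(keys)
  bnd <- names(cnt)[cnt == 1L]
  af$facets[match(bnd, keys), , drop = FALSE]
}

# measures (lengths/areas) of facets
facet_measures <- function(vertices, facets) {
  d <- ncol(vertices)
  if (d == 2L) {
    e <- vertices[facets[, 2L], , drop = FALSE] - vertices[facets[, 1L], , drop = FALSE]
    sqrt(rowSums(e * e))
  } else {
    e1 <- vertices[facets[, 2L], , drop = FALSE] - vertices[facets[, 1L], , drop = FALSE]
    e2 <- vertices[facets[, 3L], , drop = FALSE] - vertices[facets[, 1L], , drop = FALSE]
    cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
    cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
    cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
    sqrt(cx^2 + cy^2 + cz^2) / 2
  }
}

# vertex indices carrying a named facet tag
facet_set_vertices <- function(mesh, name) {
  tag <- mesh$facet_names[[name]]
  if (is.null(tag)) stop(sprintf("mesh has no facet set '%s'", name), call. = FALSE)
  sort(unique(as.vector(mesh$facets[mesh$facet_tags == tag, , drop = FALSE])))
}

facet_set <- function(mesh, name) {
  tag <- mesh$facet_names[[name]]
  if (is.null(tag)) stop(sprintf("mesh has no facet set '%s'", name), call. = FALSE)
  mesh$facets[mesh$facet_tags == tag, , drop = FALSE]
}

region_cells <- function(mesh, name) {
  tag <- mesh$region_names[[name]]
  if (is.null(tag)) stop(sprintf("mesh has no region '%s'", name), call. = FALSE)
  which(mesh$region_tags == tag)
}

#' Solid / fluid cell indicator from region tags
#'
#' The phase function theta is 1 on fluid cells and 0 on solid (leaflet)
#' cells; initially the solid cells are exactly the tagged leaflet regions.
#'
#' @param mesh an `fsi_mesh`.
#' @return integer vector of 0/1 per cell.
#' @export
initial_phase <- function(mesh) {
  as.integer(mesh$region_tags == mesh$region_names[["fluid"]])
}

# vertices incident to any solid cell under the given phase
solid_vertices <- function(mesh, theta) {
  sort(unique(as.vector(mesh$cells[theta == 0L, , drop = FALSE])))
}

# fluid-structure interface vertices: shared by fluid and solid cells
interface_vertices <- function(mesh, theta) {
  sv <- solid_vertices(mesh, theta)
  fv <- sort(unique(as.vector(mesh$cells[theta == 1L, , drop = FALSE])))
  intersect(sv, fv)
}
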