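# Mesh and field I/O: Gmsh .msh v4.1 ASCII (read/write, lossless round trip),
# XDMF with inline-XML data items (read/write), and VTU/PVD ASCII writers for
# visualization tools.

msh_cell_type <- function(d, codim0 = TRUE) {
  # gmsh element type codes: 1 = 2-node line, 2 = 3-node triangle, 4 = tet
  if (codim0) { if (d == 2L) 2L else 4L } else { if (d == 2L) 1L else 2L }
}

#' Write a tagged mesh to disk
#'
#' `format = "msh"` writes Gmsh ASCII v4.1 with one entity per region/facet
#' tag and matching physical names; coordinates are written with 17 significant
#' digits so that `read_mesh(write_mesh(m))` is bit-exact.  `format = "xdmf"`
#' writes a single-file XDMF document with inline (XML) data items.
#'
#' @param mesh an `fsi_mesh`.
#' @param path output file path.
#' @param format `"msh"` or `"xdmf"` (default: from the file extension).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = tools::file_ext(path)) {
  format <- tolower(format)
  if (format == "msh") write_msh(mesh, path)
  else if (format == "xdmf") write_xdmf(mesh, path)
  else stop(sprintf("write_mesh: unsupported format '%s'", format), call. = FALSE)
  invisible(path)
}

#' Read a tagged mesh
#'
#' @param path input file (.msh ASCII v4.1 or inline-XML .xdmf).
#' @param format `"msh"` or `"xdmf"`.
#' @return an `fsi_mesh`.
#' @export
read_mesh <- function(path, format = tools::file_ext(path)) {
  if (!file.exists(path))
    stop(sprintf("read_mesh: file '%s' does not exist", path), call. = FALSE)
  format <- tolower(format)
  if (format == "msh") read_msh(path)
  else if (format == "xdmf") read_xdmf(path)
  else stop(sprintf("read_mesh: unsupported format '%s'", format), call. = FALSE)
}

num17 <- function(x) sprintf("%.17g", x)

write_msh <- function(mesh, path) {
  d <- mesh$dim
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w("$MeshFormat", "4.1 0 8", "$EndMeshFormat")

  ftags <- sort(unique(mesh$facet_tags))
  rtags <- sort(unique(mesh$region_tags))
  # physical names
  pn <- character(0)
  for (t in ftags) {
    nm <- names(mesh$facet_names)[match(t, mesh$facet_names)]
    if (is.na(nm)) nm <- sprintf("facet_%d", t)
    pn <- c(pn, sprintf('%d %d "%s"', d - 1L, t, nm))
  }
  for (t in rtags) {
    nm <- names(mesh$region_names)[match(t, mesh$region_names)]
    if (is.na(nm)) nm <- sprintf("region_%d", t)
    pn <- c(pn, sprintf('%d %d "%s"', d, t, nm))
  }
  w("$PhysicalNames", as.character(length(pn)), pn, "$EndPhysicalNames")

  # entities: one (d-1)-entity per facet tag, one d-entity per region tag
  bb <- c(apply(mesh$vertices, 2L, range), rep(0, 2 * (3 - d)))
  lo <- paste(num17(c(bb[1], bb[3], if (d == 3L) bb[5] else 0)), collapse = " ")
  hi <- paste(num17(c(bb[2], bb[4], if (d == 3L) bb[6] else 0)), collapse = " ")
  ent_line <- function(t) sprintf("%d %s %s 1 %d 0", t, lo, hi, t)
  w("$Entities")
  if (d == 2L) {
    w(sprintf("0 %d %d 0", length(ftags), length(rtags)))
  } else {
    w(sprintf("0 0 %d %d", length(ftags), length(rtags)))
  }
  for (t in ftags) w(ent_line(t))
  for (t in rtags) w(ent_line(t))
  w("$EndEntities")

  n <- nrow(mesh$vertices)
  w("$Nodes", sprintf("1 %d 1 %d", n, n),
    sprintf("%d %d 0 %d", d, rtags[1L], n),
    as.character(seq_len(n)))
  z <- if (d == 3L) mesh$vertices[, 3L] else rep(0, n)
  w(paste(num17(mesh$vertices[, 1L]), num17(mesh$vertices[, 2L]), num17(z)))
  w("$EndNodes")

  # elements grouped by entity
  blocks <- list()
  eid <- 0L
  for (t in ftags) {
    rows <- which(mesh$facet_tags == t)
    lines <- paste(eid + seq_along(rows),
                   apply(mesh$facets[rows, , drop = FALSE], 1L, paste, collapse = " "))
    blocks[[length(blocks) + 1L]] <- c(
      sprintf("%d %d %d %d", d - 1L, t, msh_cell_type(d, FALSE), length(rows)), lines)
    eid <- eid + length(rows)
  }
  for (t in rtags) {
    rows <- which(mesh$region_tags == t)
    lines <- paste(eid + seq_along(rows),
                   apply(mesh$cells[rows, , drop = FALSE], 1L, paste, collapse = " "))
    blocks[[length(blocks) + 1L]] <- c(
      sprintf("%d %d %d %d", d, t, msh_cell_type(d, TRUE), length(rows)), lines)
    eid <- eid + length(rows)
  }
  w("$Elements", sprintf("%d %d 1 %d", length(blocks), eid, eid))
  for (b in blocks) w(b)
  w("$EndElements")
  invisible(path)
}

read_msh <- function(path) {
  lines <- readLines(path)
  sec <- function(name) {
    i0 <- match(paste0("$", name), lines)
    i1 <- match(paste0("$End", name), lines)
    if (is.na(i0) || is.na(i1))
      stop(sprintf("read_msh: missing $%s section", name), call. = FALSE)
    lines[(i0 + 1L):(i1 - 1L)]
  }
  fmt <- strsplit(trimws(sec("MeshFormat")[1L]), "\\s+")[[1L]]
  if (!startsWith(fmt[1L], "4"))
    stop("read_msh: only MSH format 4.x ASCII is supported", call. = FALSE)
  if (fmt[2L] != "0")
    stop("read_msh: binary MSH files are not supported", call. = FALSE)

  # physical names (optional)
  fnames <- integer(0); rnames <- integer(0)
  if (paste0("$", "PhysicalNames") %in% lines) {
    pn <- sec("PhysicalNames")
    for (ln in pn[-1L]) {
      m <- regmatches(ln, regexec('^(\\d+)\\s+(\\d+)\\s+"(.*)"$', trimws(ln)))[[1L]]
      if (length(m) == 4L) {
        v <- as.integer(m[3L]); names(v) <- m[4L]
        if (as.integer(m[2L]) >= 2L) { # provisional; resolved after dims known
          rnames <- c(rnames, stats::setNames(v, m[4L]))
        } else fnames <- c(fnames, stats::setNames(v, m[4L]))
        attr(rnames, "dims") <- c(attr(rnames, "dims"), as.integer(m[2L]))
      }
    }
  }

  # nodes
  nl <- sec("Nodes")
  hdr <- as.integer(strsplit(trimws(nl[1L]), "\\s+")[[1L]])
  nblocks <- hdr[1L]; ntot <- hdr[2L]
  coords <- matrix(NA_real_, ntot, 3L)
  tags <- integer(ntot)
  pos <- 2L; got <- 0L
  for (b in seq_len(nblocks)) {
    bh <- as.numeric(strsplit(trimws(nl[pos]), "\\s+")[[1L]])
    nb <- as.integer(bh[4L]); pos <- pos + 1L
    btags <- as.integer(nl[pos:(pos + nb - 1L)]); pos <- pos + nb
    for (k in seq_len(nb)) {
      xyz <- as.numeric(strsplit(trimws(nl[pos]), "\\s+")[[1L]])
      coords[got + k, ] <- xyz[1:3]
      pos <- pos + 1L
    }
    tags[got + seq_len(nb)] <- btags
    got <- got + nb
  }
  ord <- order(tags)
  coords <- coords[ord, , drop = FALSE]
  remap <- integer(max(tags)); remap[tags[ord]] <- seq_len(ntot)

  # elements
  el <- sec("Elements")
  hdr <- as.integer(strsplit(trimws(el[1L]), "\\s+")[[1L]])
  nblocks <- hdr[1L]
  pos <- 2L
  elems <- list()
  for (b in seq_len(nblocks)) {
    bh <- as.integer(strsplit(trimws(el[pos]), "\\s+")[[1L]])
    edim <- bh[1L]; etag <- bh[2L]; etype <- bh[3L]; ne <- bh[4L]
    pos <- pos + 1L
    if (!etype %in% c(1L, 2L, 4L))
      stop(sprintf("read_msh: unsupported element type %d (simplices only)", etype),
           call. = FALSE)
    nv <- c(`1` = 2L, `2` = 3L, `4` = 4L)[[as.character(etype)]]
    conn <- matrix(NA_integer_, ne, nv)
    for (k in seq_len(ne)) {
      row <- as.integer(strsplit(trimws(el[pos]), "\\s+")[[1L]])
      conn[k, ] <- row[2:(1 + nv)]
      pos <- pos + 1L
    }
    elems[[length(elems) + 1L]] <- list(type = etype, tag = etag, conn = conn)
  }
  types <- vapply(elems, function(e) e$type, 0L)
  d <- if (4L %in% types) 3L else if (2L %in% types && !any(coords[, 3L] != 0)) 2L
       else if (2L %in% types) 3L else
    stop("read_msh: no volume cells found", call. = FALSE)
  # in a 3D file triangles are facets; in 2D triangles are cells, lines facets
  ct <- msh_cell_type(d, TRUE); ft <- msh_cell_type(d, FALSE)
  if (!any(types == ct)) stop("read_msh: no cells of the expected type", call. = FALSE)
  cells <- do.call(rbind, lapply(elems[types == ct], function(e) e$conn))
  region_tags <- unlist(lapply(elems[types == ct], function(e) rep(e$tag, nrow(e$conn))))
  facets <- do.call(rbind, lapply(elems[types == ft], function(e) e$conn))
  facet_tags <- unlist(lapply(elems[types == ft], function(e) rep(e$tag, nrow(e$conn))))
  cells[] <- remap[cells]
  if (!is.null(facets)) facets[] <- remap[facets]

  verts <- coords[, seq_len(d), drop = FALSE]
  rn <- if (length(rnames)) {
    dims <- attr(rnames, "dims"); attr(rnames, "dims") <- NULL
    rnames[dims == d]
  } else c(fluid = 1L)
  if (!length(rn) || !"fluid" %in% names(rn)) rn <- c(rn, fluid = 1L)
  fsi_mesh(verts, cells, region_tags, facets, facet_tags,
           region_names = rn, facet_names = fnames)
}

# ---- XDMF (inline XML data) ------------------------------------------------

xdmf_data_item <- function(x, per_row) {
  vals <- num17(t(x))
  rows <- matrix(vals, ncol = per_row, byrow = TRUE)
  paste(apply(rows, 1L, paste, collapse = " "), collapse = "\n")
}

write_xdmf <- function(mesh, path, point_data = list(), cell_data = list()) {
  d <- mesh$dim
  topo <- if (d == 2L) "Triangle" else "Tetrahedron"
  geom <- if (d == 2L) "XY" else "XYZ"
  n <- nrow(mesh$vertices); m <- nrow(mesh$cells)
  attr_xml <- function(name, x, center) {
    x <- as.matrix(x)
    dims <- if (ncol(x) == 1L) sprintf("%d", nrow(x)) else sprintf("%d %d", nrow(x), ncol(x))
    type <- if (center == "Cell" && ncol(x) == 1L && is.integer(x[, 1L])) "Int" else "Float"
    sprintf(paste0(
      '   <Attribute Name="%s" AttributeType="%s" Center="%s">\n',
      '    <DataItem Dimensions="%s" NumberType="%s" Format="XML">\n%s\n    </DataItem>\n',
      '   </Attribute>'),
      name, if (ncol(x) == 1L) "Scalar" else "Vector", center, dims, type,
      xdmf_data_item(x, ncol(x)))
  }
  attrs <- c(
    attr_xml("region", matrix(as.integer(mesh$region_tags), ncol = 1L), "Cell"),
    vapply(names(point_data), function(nm) attr_xml(nm, point_data[[nm]], "Node"), ""),
    vapply(names(cell_data), function(nm) attr_xml(nm, cell_data[[nm]], "Cell"), ""))
  xml <- sprintf(paste0(
    '<?xml version="1.0"?>\n<Xdmf Version="3.0">\n <Domain>\n  <Grid Name="mesh">\n',
    '   <Topology TopologyType="%s" NumberOfElements="%d">\n',
    '    <DataItem Dimensions="%d %d" NumberType="Int" Format="XML">\n%s\n    </DataItem>\n',
    '   </Topology>\n',
    '   <Geometry GeometryType="%s">\n',
    '    <DataItem Dimensions="%d %d" NumberType="Float" Format="XML">\n%s\n    </DataItem>\n',
    '   </Geometry>\n%s\n  </Grid>\n </Domain>\n</Xdmf>'),
    topo, m, m, d + 1L, xdmf_data_item(mesh$cells - 1L, d + 1L),
    geom, n, d, xdmf_data_item(mesh$vertices, d),
    paste(attrs, collapse = "\n"))
  writeLines(xml, path)
  invisible(path)
}

# minimal reader for the files written above (inline XML data only)
read_xdmf <- function(path) {
  txt <- paste(readLines(path), collapse = "\n")
  grab <- function(pattern) {
    m <- regmatches(txt, regexec(pattern, txt))[[1L]]
    if (length(m) < 2L) stop("read_xdmf: malformed file", call. = FALSE)
    m[2L]
  }
  topo <- grab('TopologyType="([A-Za-z]+)"')
  d <- if (topo == "Triangle") 2L else if (topo == "Tetrahedron") 3L else
    stop(sprintf("read_xdmf: unsupported topology '%s'", topo), call. = FALSE)
  body <- function(section) {
    m <- regmatches(txt, regexec(paste0(
      "<", section, "[^>]*>\\s*<DataItem[^>]*>\\s*\n?(.*?)\\s*</DataItem>"), txt))[[1L]]
    m[2L]
  }
  conn <- matrix(as.integer(strsplit(body("Topology"), "\\s+")[[1L]]) + 1L,
                 ncol = d + 1L, byrow = TRUE)
  verts <- matrix(as.numeric(strsplit(body("Geometry"), "\\s+")[[1L]]),
                  ncol = d, byrow = TRUE)
  reg <- rep(1L, nrow(conn))
  m <- regmatches(txt, regexec(paste0(
    '<Attribute Name="region"[^>]*>\\s*<DataItem[^>]*>\\s*\n?(.*?)\\s*</DataItem>'), txt))[[1L]]
  if (length(m) == 2L) reg <- as.integer(strsplit(m[2L], "\\s+")[[1L]])
  rn <- c(fluid = 1L)
  extra <- setdiff(sort(unique(reg)), 1L)
  if (length(extra)) rn <- c(rn, stats::setNames(extra, sprintf("region_%d", extra)))
  fsi_mesh(verts, conn, reg, region_names = rn)
}

# ---- VTU / PVD -------------------------------------------------------------

#' Write a VTU (XML unstructured grid) snapshot
#'
#' ASCII, for inspection with ParaView and similar tools.
#'
#' @param mesh an `fsi_mesh` (current coordinates are written).
#' @param path output .vtu path.
#' @param point_data named list of per-vertex vectors/matrices.
#' @param cell_data named list of per-cell vectors.
#' @return `path`, invisibly.
#' @export
write_vtu <- function(mesh, path, point_data = list(), cell_data = list()) {
  n <- nrow(mesh$vertices); m <- nrow(mesh$cells); d <- mesh$dim
  pts <- cbind(mesh$vertices, matrix(0, n, 3L - d))
  vtk_type <- if (d == 2L) 5L else 10L
  da <- function(name, x, comps) {
    sprintf('<DataArray type="Float64" Name="%s" NumberOfComponents="%d" format="ascii">\n%s\n</DataArray>',
            name, comps, paste(num17(as.vector(t(as.matrix(x)))), collapse = " "))
  }
  pd <- paste(vapply(names(point_data), function(nm) {
    x <- as.matrix(point_data[[nm]])
    if (ncol(x) == d && d == 2L) x <- cbind(x, 0)
    da(nm, x, ncol(x))
  }, ""), collapse = "\n")
  cd <- paste(vapply(names(cell_data), function(nm)
    da(nm, as.matrix(cell_data[[nm]]), 1L), ""), collapse = "\n")
  xml <- paste0(
    '<?xml version="1.0"?>\n<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">\n',
    '<UnstructuredGrid><Piece NumberOfPoints="', n, '" NumberOfCells="', m, '">\n',
    '<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">\n',
    paste(num17(as.vector(t(pts))), collapse = " "), '\n</DataArray></Points>\n',
    '<Cells><DataArray type="Int32" Name="connectivity" format="ascii">\n',
    paste(as.vector(t(mesh$cells - 1L)), collapse = " "), '\n</DataArray>\n',
    '<DataArray type="Int32" Name="offsets" format="ascii">\n',
    paste(seq_len(m) * (d + 1L), collapse = " "), '\n</DataArray>\n',
    '<DataArray type="Int32" Name="types" format="ascii">\n',
    paste(rep(vtk_type, m), collapse = " "), '\n</DataArray></Cells>\n',
    if (nzchar(pd)) paste0("<PointData>\n", pd, "\n</PointData>\n") else "",
    if (nzchar(cd)) paste0("<CellData>\n", cd, "\n</CellData>\n") else "",
    '</Piece></UnstructuredGrid></VTKFile>')
  writeLines(xml, path)
  invisible(path)
}

#' Write a PVD index for a VTU time series
#' @param vtu_paths character vector of .vtu files (relative to the pvd).
#' @param times numeric vector of time stamps.
#' @param path output .pvd path.
#' @return `path`, invisibly.
#' @export
write_pvd <- function(vtu_paths, times, path) {
  ds <- sprintf('  <DataSet timestep="%s" part="0" file="%s"/>',
                num17(times), vtu_paths)
  writeLines(c('<?xml version="1.0"?>',
               '<VTKFile type="Collection" version="0.1">',
               ' <Collection>', ds, ' </Collection>', '</VTKFile>'), path)
  invisible(path)
}
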