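#' Read a VRML97 IndexedFaceSet surface
#'
#' Parses the `Coordinate point` and `coordIndex` arrays of every
#' IndexedFaceSet in a VRML97 (`#VRML V2.0 utf8`) file — the export format
#' of angiographic 3D workstations. Polygons with more than three vertices
#' are triangulated by fanning from their first vertex. Units are assumed
#' to be millimeters. Scene-graph features are ignored except that a
#' single top-level `Transform { translation ... scale ... }` is applied
#' if present. Non-manifold input yields a warning, not a rejection.
#'
#' @param path path to a `.wrl`/`.vrml` file.
#' @return a `surface_mesh` (with `strip`/`cap` unset).
#' @export
read_vrml_surface <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  txt <- gsub("#VRML[^\n]*", "", txt)        # header line
  txt <- gsub("(?m)#[^\n]*$", "", txt, perl = TRUE)  # comments
  if (!grepl("IndexedFaceSet", txt))
    stop("no IndexedFaceSet found in VRML file")

  grab_block <- function(text, keyword) {
    # returns the numbers inside the first [ ... ] following the keyword
    m <- regexpr(paste0(keyword, "\\s*\\["), text)
    if (m < 0) return(NULL)
    start <- m + attr(m, "match.length")
    close <- regexpr("\\]", substring(text, start))
    if (close < 0) stop(sprintf("unterminated '%s' array", keyword))
    body <- substring(text, start, start + close - 2L)
    as.numeric(strsplit(trimws(gsub("[,\n]", " ", body)), "\\s+")[[1]])
  }

  # optional single top-level transform
  shift <- c(0, 0, 0); scale <- c(1, 1, 1)
  tr <- regmatches(txt, regexpr("Transform\\s*\\{[^{]*", txt))
  if (length(tr) == 1L) {
    g <- function(kw, default) {
      m <- regmatches(tr, regexpr(paste0(kw, "\\s+[-0-9.eE+ ]+"), tr))
      if (length(m) == 0L) return(default)
      as.numeric(strsplit(trimws(sub(kw, "", m)), "\\s+")[[1]])[1:3]
    }
    shift <- g("translation", shift)
    scale <- g("scale", scale)
    if (anyNA(shift)) shift <- c(0, 0, 0)
    if (anyNA(scale)) scale <- c(1, 1, 1)
  }

  verts_all <- NULL
  tris_all <- NULL
  rest <- txt
  repeat {
    m <- regexpr("IndexedFaceSet", rest)
    if (m < 0) break
    chunk <- substring(rest, m)
    pts <- grab_block(chunk, "point")
    idx <- grab_block(chunk, "coordIndex")
    rest <- substring(chunk, 15L)
    if (is.null(pts) || is.null(idx)) next
    if (length(pts) %% 3 != 0) stop("Coordinate point array not a multiple of 3")
    v <- matrix(pts, ncol = 3, byrow = TRUE)
    v <- sweep(sweep(v, 2, scale, `*`), 2, shift, `+`)
    offset <- if (is.null(verts_all)) 0L else nrow(verts_all)
    # faces are -1-terminated runs of 0-based indices
    faces <- split(idx, cumsum(c(0, head(idx, -1) == -1)))
    tris <- do.call(rbind, lapply(faces, function(f) {
      f <- f[f >= 0]
      if (length(f) < 3) return(NULL)
      cbind(f[1], f[seq(2, length(f) - 1)], f[seq(3, length(f))])
    }))
    if (!is.null(tris)) {
      tris_all <- rbind(tris_all, tris + 1L + offset)
      verts_all <- rbind(verts_all, v)
    }
  }
  if (is.null(tris_all)) stop("no usable IndexedFaceSet geometry found")
  mesh <- structure(list(vertices = verts_all,
                         triangles = unname(tris_all),
                         strip = rep(NA_integer_, nrow(tris_all)),
                         cap = rep(NA_character_, nrow(tris_all)),
                         n_circ = NA_integer_, n_stations = NA_integer_),
                    class = "surface_mesh")
  ed <- rbind(mesh$triangles[, c(1, 2)], mesh$triangles[, c(2, 3)],
              mesh$triangles[, c(3, 1)])
  cnt <- table(paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2])))
  if (any(cnt > 2L)) warning("non-manifold VRML surface (edge shared by > 2 faces)")
  mesh
}

#' Write a surface mesh as a VRML97 IndexedFaceSet
#'
#' @param mesh a `surface_mesh`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vrml_surface <- function(mesh, path) {
  v <- mesh$vertices; tr <- mesh$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#VRML V2.0 utf8",
               "Shape {",
               "  geometry IndexedFaceSet {",
               "    coord Coordinate {",
               "      point ["), con)
  writeLines(sprintf("        %.9g %.9g %.9g,", v[, 1], v[, 2], v[, 3]), con)
  writeLines(c("      ]", "    }", "    coordIndex ["), con)
  writeLines(sprintf("      %d, %d, %d, -1,",
                     tr[, 1] - 1L, tr[, 2] - 1L, tr[, 3] - 1L), con)
  writeLines(c("    ]", "  }", "}"), con)
  invisible(path)
}

#' Export a mesh to a standard file format
#'
#' Surface meshes export to ASCII or binary STL and legacy VTK polydata;
#' volume meshes export to legacy VTK unstructured grids and XML `.vtu`
#' (ASCII appended data). Re-import reproduces vertex and element counts
#' and coordinates at format precision.
#'
#' @param mesh a `surface_mesh` or `volume_mesh`.
#' @param path output path.
#' @param format one of `"stl"`, `"stl_binary"`, `"vtk"`, `"vtu"`.
#' @param cell_data optional named list of per-cell numeric vectors
#'   (VTK/VTU only).
#' @return `path`, invisibly.
#' @export
export_mesh <- function(mesh, path, format = c("stl", "stl_binary", "vtk", "vtu"),
                        cell_data = NULL) {
  format <- match.arg(format)
  is_surface <- inherits(mesh, "surface_mesh")
  if (!is_surface && !inherits(mesh, "volume_mesh"))
    stop("unknown mesh type")
  switch(format,
    stl = {
      if (!is_surface) stop("STL export requires a surface mesh")
      .write_stl_ascii(mesh, path)
    },
    stl_binary = {
      if (!is_surface) stop("STL export requires a surface mesh")
      .write_stl_binary(mesh, path)
    },
    vtk = if (is_surface) .write_vtk_polydata(mesh, path, cell_data)
          else .write_vtk_unstructured(mesh, path, cell_data),
    vtu = {
      if (is_surface) stop("VTU export is for volume meshes")
      .write_vtu(mesh, path, cell_data)
    })
  invisible(path)
}

.triangle_normals <- function(v, tr) {
  e1 <- v[tr[, 2], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  e2 <- v[tr[, 3], , drop = FALSE] - v[tr[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  len <- sqrt(rowSums(n^2))
  len[len == 0] <- 1
  n / len
}

.write_stl_ascii <- function(mesh, path) {
  v <- mesh$vertices; tr <- mesh$triangles
  nrm <- .triangle_normals(v, tr)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid coroflow", con)
  for (k in seq_len(nrow(tr))) {
    writeLines(c(
      sprintf("  facet normal %.9g %.9g %.9g", nrm[k, 1], nrm[k, 2], nrm[k, 3]),
      "    outer loop",
      sprintf("      vertex %.9g %.9g %.9g",
              v[tr[k, ], 1], v[tr[k, ], 2], v[tr[k, ], 3]),
      "    endloop",
      "  endfacet"), con)
  }
  writeLines("endsolid coroflow", con)
}

.write_stl_binary <- function(mesh, path) {
  v <- mesh$vertices; tr <- mesh$triangles
  nrm <- .triangle_normals(v, tr)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(formatC("coroflow binary STL", width = 80, flag = "-")), con)
  writeBin(as.integer(nrow(tr)), con, size = 4, endian = "little")
  for (k in seq_len(nrow(tr))) {
    writeBin(as.numeric(c(nrm[k, ], t(v[tr[k, ], ]))), con,
             size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
}

#' Read an STL surface (ASCII or binary, auto-detected)
#'
#' Vertices are de-duplicated exactly, so meshes written by
#' [export_mesh()] round-trip their vertex and triangle counts.
#'
#' @param path path to an `.stl` file.
#' @return a `surface_mesh`.
#' @export
read_stl <- function(path) {
  head_raw <- readBin(path, "raw", n = 5)
  is_ascii <- identical(rawToChar(head_raw), "solid")
  if (is_ascii) {
    txt <- readLines(path)
    vl <- grep("^\\s*vertex", txt, value = TRUE)
    xyz <- t(vapply(strsplit(trimws(vl), "\\s+"),
                    function(f) as.numeric(f[2:4]), numeric(3)))
  } else {
    con <- file(path, "rb")
    on.exit(close(con))
    invisible(readBin(con, "raw", n = 80))
    nt <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    xyz <- matrix(0, 3 * nt, 3)
    for (k in seq_len(nt)) {
      vals <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
      invisible(readBin(con, "raw", n = 2))
      xyz[3 * k - 2:0, ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
    }
  }
  if (nrow(xyz) %% 3 != 0) stop("corrupt STL: vertex count not divisible by 3")
  key <- paste(xyz[, 1], xyz[, 2], xyz[, 3])
  uid <- match(key, unique(key))
  verts <- xyz[!duplicated(key), , drop = FALSE]
  tris <- matrix(uid, ncol = 3, byrow = TRUE)
  structure(list(vertices = verts, triangles = tris,
                 strip = rep(NA_integer_, nrow(tris)),
                 cap = rep(NA_character_, nrow(tris)),
                 n_circ = NA_integer_, n_stations = NA_integer_),
            class = "surface_mesh")
}

.write_vtk_polydata <- function(mesh, path, cell_data = NULL) {
  v <- mesh$vertices; tr <- mesh$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "coroflow surface", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nrow(v))), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(tr), 4L * nrow(tr)), con)
  writeLines(sprintf("3 %d %d %d", tr[, 1] - 1L, tr[, 2] - 1L, tr[, 3] - 1L), con)
  .write_vtk_cell_data(con, cell_data, nrow(tr))
}

.write_vtk_unstructured <- function(mesh, path, cell_data = NULL) {
  v <- mesh$vertices; tt <- mesh$tets
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "coroflow volume", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", nrow(v))), con)
  writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  writeLines(sprintf("CELLS %d %d", nrow(tt), 5L * nrow(tt)), con)
  writeLines(sprintf("4 %d %d %d %d", tt[, 1] - 1L, tt[, 2] - 1L,
                     tt[, 3] - 1L, tt[, 4] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", nrow(tt)), con)
  writeLines(rep("10", nrow(tt)), con)
  .write_vtk_cell_data(con, cell_data, nrow(tt))
}

.write_vtk_cell_data <- function(con, cell_data, n_cells) {
  if (is.null(cell_data)) return(invisible(NULL))
  writeLines(sprintf("CELL_DATA %d", n_cells), con)
  for (nm in names(cell_data)) {
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", cell_data[[nm]]), con)
  }
}

.write_vtu <- function(mesh, path, cell_data = NULL) {
  v <- mesh$vertices; tt <- mesh$tets
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('  <UnstructuredGrid>')
  w('    <Piece NumberOfPoints="%d" NumberOfCells="%d">', nrow(v), nrow(tt))
  w('      <Points>')
  w('        <DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  writeLines(sprintf("          %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
  w('        </DataArray>')
  w('      </Points>')
  w('      <Cells>')
  w('        <DataArray type="Int32" Name="connectivity" format="ascii">')
  writeLines(sprintf("          %d %d %d %d", tt[, 1] - 1L, tt[, 2] - 1L,
                     tt[, 3] - 1L, tt[, 4] - 1L), con)
  w('        </DataArray>')
  w('        <DataArray type="Int32" Name="offsets" format="ascii">')
  writeLines(sprintf("          %d", 4L * seq_len(nrow(tt))), con)
  w('        </DataArray>')
  w('        <DataArray type="UInt8" Name="types" format="ascii">')
  writeLines(sprintf("          %d", rep(10L, nrow(tt))), con)
  w('        </DataArray>')
  w('      </Cells>')
  if (!is.null(cell_data)) {
    w('      <CellData>')
    for (nm in names(cell_data)) {
      w('        <DataArray type="Float64" Name="%s" format="ascii">', nm)
      writeLines(sprintf("          %.9g", cell_data[[nm]]), con)
      w('        </DataArray>')
    }
    w('      </CellData>')
  }
  w('    </Piece>')
  w('  </UnstructuredGrid>')
  w('</VTKFile>')
}
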