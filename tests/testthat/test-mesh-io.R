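make_vrml_cube <- function(path) {
  writeLines(c(
    "#VRML V2.0 utf8",
    "Shape {",
    "  geometry IndexedFaceSet {",
    "    coord Coordinate {",
    "      point [",
    "        0 0 0, 1 0 0, 1 1 0, 0 1 0,",
    "        0 0 1, 1 0 1, 1 1 1, 0 1 1",
    "      ]",
    "    }",
    "    coordIndex [",
    "      0, 3, 2, 1, -1,  4, 5, 6, 7, -1,",
    "      0, 1, 5, 4, -1,  2, 3, 7, 6, -1,",
    "      1, 2, 6, 5, -1,  0, 4, 7, 3, -1",
    "    ]",
    "  }",
    "}"), path)
}

test_that("VRML cube: 8 points, 6 quads fan to 12 triangles", {
  f <- tempfile(fileext = ".wrl")
  make_vrml_cube(f)
  m <- read_vrml_surface(f)
  expect_equal(nrow(m$vertices), 8)
  expect_equal(nrow(m$triangles), 12)
  unlink(f)
})

test_that("VRML round trip of a built cylinder preserves counts", {
  v <- straight_tube(length = 10, radius = 1.5, step = 1)
  sm <- build_surface_mesh(v, n_circ = 16, caps = FALSE)
  f <- tempfile(fileext = ".wrl")
  write_vrml_surface(sm, f)
  m2 <- read_vrml_surface(f)
  expect_equal(nrow(m2$vertices), nrow(sm$vertices))
  expect_equal(nrow(m2$triangles), nrow(sm$triangles))
  expect_equal(m2$vertices, sm$vertices, tolerance = 1e-7)
  unlink(f)
})

test_that("VRML reader rejects files without an IndexedFaceSet and flags non-manifold input", {
  f <- tempfile(fileext = ".wrl")
  writeLines(c("#VRML V2.0 utf8", "Shape { geometry Sphere { radius 1 } }"), f)
  expect_error(read_vrml_surface(f), "IndexedFaceSet")
  # two triangles sharing an edge plus a third on the same edge: non-manifold
  writeLines(c(
    "#VRML V2.0 utf8",
    "Shape { geometry IndexedFaceSet {",
    "  coord Coordinate { point [0 0 0, 1 0 0, 0 1 0, 0 0 1, 1 1 1] }",
    "  coordIndex [0, 1, 2, -1, 0, 1, 3, -1, 0, 1, 4, -1]",
    "} }"), f)
  expect_warning(read_vrml_surface(f), "non-manifold")
  unlink(f)
})

test_that("STL round trips preserve geometry (ascii and binary)", {
  v <- stenosed_tube(severity = 0.4, length = 12, s_center = 6,
                     lesion_length = 5, step = 1)
  sm <- build_surface_mesh(v, n_circ = 16)
  for (fmt in c("stl", "stl_binary")) {
    f <- tempfile(fileext = ".stl")
    export_mesh(sm, f, fmt)
    m2 <- read_stl(f)
    expect_equal(nrow(m2$triangles), nrow(sm$triangles))
    expect_equal(nrow(m2$vertices), nrow(sm$vertices))
    # binary STL stores float32
    expect_equal(sort(m2$vertices[, 1]), sort(sm$vertices[, 1]),
                 tolerance = 1e-6)
    unlink(f)
  }
})

test_that("ASCII STL of one triangle follows the facet grammar", {
  m <- structure(list(
    vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
    triangles = matrix(c(1L, 2L, 3L), 1),
    strip = NA_integer_, cap = NA_character_,
    n_circ = NA_integer_, n_stations = NA_integer_), class = "surface_mesh")
  f <- tempfile(fileext = ".stl")
  export_mesh(m, f, "stl")
  txt <- readLines(f)
  expect_match(txt[1], "^solid")
  expect_match(txt[2], "^\\s*facet normal")
  expect_match(txt[3], "^\\s*outer loop")
  expect_length(grep("^\\s*vertex", txt), 3)
  expect_match(txt[7], "^\\s*endloop")
  expect_match(txt[8], "^\\s*endfacet")
  expect_match(txt[9], "^endsolid")
  unlink(f)
})

test_that("VTK and VTU exports preserve cell counts and parse as declared", {
  v <- straight_tube(length = 10, step = 2)
  vm <- build_volume_mesh(v, n_circ = 8, axial_step = 2.5)
  f1 <- tempfile(fileext = ".vtk"); f2 <- tempfile(fileext = ".vtu")
  export_mesh(vm, f1, "vtk")
  export_mesh(vm, f2, "vtu", cell_data = list(slab = vm$slab_of_tet))
  t1 <- readLines(f1)
  expect_equal(as.integer(strsplit(grep("^CELLS", t1, value = TRUE), " ")[[1]][2]),
               nrow(vm$tets))
  expect_equal(sum(t1 == "10"), nrow(vm$tets))
  t2 <- readLines(f2)
  expect_match(t2[grep("NumberOfCells", t2)],
               sprintf('NumberOfCells="%d"', nrow(vm$tets)))
  expect_true(any(grepl('Name="slab"', t2)))
  expect_error(export_mesh(vm, f1, "stl"), "surface")
  unlink(c(f1, f2))
})

test_that("cross-section fitting recovers a straight tube's radii", {
  v <- straight_tube(length = 30, radius = 1.5, step = 1)
  sm <- build_surface_mesh(v, n_circ = 32, caps = FALSE)
  fit <- fit_cross_sections(sm, step = 2)
  # equivalent-area radius of the inscribed 32-gon is slightly under 1.5
  expect_equal(mean(fit$sections$r), 1.5, tolerance = 0.01)
  expect_lt(stats::sd(fit$sections$r), 0.01)
  # recovered arc-length range equals the tube length within one step
  expect_equal(vessel_length(fit), 30, tolerance = 2)
})

test_that("elliptical sections are recovered as equivalent-area circles", {
  # hand-built elliptical tube: semi-axes a = 2, b = 1
  a <- 2; b <- 1; nc <- 48; ns <- 21
  th <- 2 * pi * (seq_len(nc) - 1) / nc
  verts <- do.call(rbind, lapply(seq_len(ns), function(i)
    cbind((i - 1), a * cos(th), b * sin(th))))
  vid <- function(i, j) (i - 1) * nc + ((j - 1) %% nc) + 1
  js <- seq_len(nc)
  tri <- do.call(rbind, lapply(seq_len(ns - 1), function(i)
    rbind(cbind(vid(i, js), vid(i, js + 1), vid(i + 1, js + 1)),
          cbind(vid(i, js), vid(i + 1, js + 1), vid(i + 1, js)))))
  m <- structure(list(vertices = verts, triangles = tri,
                      strip = rep(NA_integer_, nrow(tri)),
                      cap = rep(NA_character_, nrow(tri)),
                      n_circ = nc, n_stations = ns), class = "surface_mesh")
  fit <- fit_cross_sections(m, step = 2)
  expect_equal(mean(fit$sections$r), sqrt(a * b), tolerance = 0.02)
})

test_that("branched surfaces (more than two boundary loops) are rejected", {
  v <- straight_tube(length = 10, step = 1)
  sm <- build_surface_mesh(v, n_circ = 12, caps = FALSE)
  # graft a third boundary loop: an annulus strip off to the side
  nc <- 8
  th <- 2 * pi * (seq_len(nc) - 1) / nc
  ring1 <- cbind(50 + cos(th), sin(th), 5)
  ring2 <- cbind(50 + 2 * cos(th), 2 * sin(th), 5)
  off <- nrow(sm$vertices)
  vid1 <- off + seq_len(nc); vid2 <- off + nc + seq_len(nc)
  wrap <- function(x) ((x - 1) %% nc) + 1
  tri <- rbind(cbind(vid1, vid1[wrap(seq_len(nc) + 1)], vid2),
               cbind(vid1[wrap(seq_len(nc) + 1)],
                     vid2[wrap(seq_len(nc) + 1)], vid2))
  m <- structure(list(vertices = rbind(sm$vertices, ring1, ring2),
                      triangles = rbind(sm$triangles, tri),
                      strip = c(sm$strip, rep(NA_integer_, nrow(tri))),
                      cap = c(sm$cap, rep(NA_character_, nrow(tri))),
                      n_circ = sm$n_circ, n_stations = sm$n_stations),
                 class = "surface_mesh")
  expect_error(fit_cross_sections(m), "branched|loops")
})
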