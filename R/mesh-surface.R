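#' Rotation-minimizing frames along a centerline (double reflection)
#'
#' Returns, for each station, a unit normal `e1` such that the moving frame
#' `(e1, t x e1, t)` twists as little as possible between stations. Used so
#' that the circumferential sampling of consecutive rings stays aligned and
#' the triangle strips do not twist.
#'
#' @param centers n x 3 matrix of centerline points.
#' @param tangents n x 3 matrix of unit tangents.
#' @return n x 3 matrix of unit normals.
#' @keywords internal
rotation_minimizing_frames <- function(centers, tangents) {
  n <- nrow(centers)
  e1 <- matrix(0, n, 3)
  t0 <- tangents[1, ]
  # any vector not parallel to t0
  a <- if (abs(t0[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- a - sum(a * t0) * t0
  e1[1, ] <- v / sqrt(sum(v^2))
  for (i in seq_len(n - 1L)) {
    v1 <- centers[i + 1L, ] - centers[i, ]
    c1 <- sum(v1^2)
    rL <- e1[i, ] - (2 / c1) * sum(v1 * e1[i, ]) * v1
    tL <- tangents[i, ] - (2 / c1) * sum(v1 * tangents[i, ]) * v1
    v2 <- tangents[i + 1L, ] - tL
    c2 <- sum(v2^2)
    e1[i + 1L, ] <- if (c2 < 1e-30) rL else rL - (2 / c2) * sum(v2 * rL) * v2
    # re-orthonormalize against accumulated drift
    e <- e1[i + 1L, ] - sum(e1[i + 1L, ] * tangents[i + 1L, ]) * tangents[i + 1L, ]
    e1[i + 1L, ] <- e / sqrt(sum(e^2))
  }
  e1
}

#' Build the triangle-strip lumen surface of a vessel
#'
#' Each cross-section is discretized as `n_circ` points on its circle, in
#' the plane normal to the local tangent, oriented by a rotation-minimizing
#' frame. Consecutive rings are joined by `2 * n_circ` wall triangles; the
#' default `n_circ = 64` gives the canonical 128 triangles per
#' inter-station strip. Optional planar fan caps close the inlet and outlet
#' so the surface is watertight.
#'
#' @param vessel a `vessel_geometry`.
#' @param n_circ circumferential resolution (even, >= 8); default 64.
#' @param caps close the inlet/outlet with planar fans (default TRUE).
#' @return an object of class `surface_mesh`: `vertices` (V x 3, mm),
#'   `triangles` (F x 3, 1-based), `strip` (inter-station strip index per
#'   triangle, NA on caps), `cap` (NA, "inlet" or "outlet" per triangle),
#'   `n_circ`, `n_stations`.
#' @export
build_surface_mesh <- function(vessel, n_circ = 64L, caps = TRUE) {
  validate_vessel(vessel)
  n_circ <- as.integer(n_circ)
  if (n_circ < 8L || n_circ %% 2L != 0L)
    stop("n_circ must be an even integer >= 8")
  sec <- vessel$sections
  n <- nrow(sec)
  centers <- as.matrix(sec[, c("x", "y", "z")])
  tangents <- as.matrix(sec[, c("tx", "ty", "tz")])
  e1 <- rotation_minimizing_frames(centers, tangents)

  theta <- 2 * pi * (seq_len(n_circ) - 1L) / n_circ
  verts <- matrix(0, n * n_circ, 3)
  for (i in seq_len(n)) {
    e2 <- .cross3(tangents[i, ], e1[i, ])
    ring <- centers[rep(i, n_circ), ] +
      sec$r[i] * (cos(theta) %o% e1[i, ] + sin(theta) %o% e2)
    verts[(i - 1L) * n_circ + seq_len(n_circ), ] <- ring
  }

  # guard against adjacent ring planes crossing inside the lumen
  for (i in seq_len(n - 1L)) {
    d <- centers[i + 1L, ] - centers[i, ]
    a <- verts[(i) * n_circ + seq_len(n_circ), ] -
         verts[(i - 1L) * n_circ + seq_len(n_circ), ]
    if (any(a %*% d <= 0))
      stop("adjacent cross-section planes intersect inside the lumen; ",
           "resample the vessel at a finer step")
  }

  vid <- function(i, j) (i - 1L) * n_circ + ((j - 1L) %% n_circ) + 1L
  js <- seq_len(n_circ)
  tri <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    a <- vid(i, js); b <- vid(i, js + 1L)
    cc <- vid(i + 1L, js); d <- vid(i + 1L, js + 1L)
    tri[[i]] <- rbind(cbind(a, b, d), cbind(a, d, cc))
  }
  triangles <- do.call(rbind, tri)
  strip <- rep(seq_len(n - 1L), each = 2L * n_circ)
  cap <- rep(NA_character_, nrow(triangles))

  if (caps) {
    c_in <- nrow(verts) + 1L
    c_out <- nrow(verts) + 2L
    verts <- rbind(verts, centers[1, ], centers[n, ])
    tri_in <- cbind(rep(c_in, n_circ), vid(1L, js + 1L), vid(1L, js))
    tri_out <- cbind(rep(c_out, n_circ), vid(n, js), vid(n, js + 1L))
    triangles <- rbind(triangles, tri_in, tri_out)
    strip <- c(strip, rep(NA_integer_, 2L * n_circ))
    cap <- c(cap, rep("inlet", n_circ), rep("outlet", n_circ))
  }
  dimnames(triangles) <- NULL
  structure(list(vertices = verts, triangles = triangles,
                 strip = strip, cap = cap,
                 n_circ = n_circ, n_stations = n),
            class = "surface_mesh")
}

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles (%d wall, %d cap)\n",
              nrow(x$vertices), nrow(x$triangles),
              sum(!is.na(x$strip)), sum(!is.na(x$cap))))
  invisible(x)
}

#' Validate watertightness and orientation of a surface mesh
#'
#' For a capped (closed) mesh: every edge must be shared by exactly two
#' triangles and every directed edge must appear exactly once (consistent
#' orientation). For an open tube the boundary edges must form loops.
#' Also reports the Euler characteristic and the signed enclosed volume
#' (positive for outward orientation).
#'
#' @param mesh a `surface_mesh`.
#' @param closed is the mesh expected to be closed (default: caps present)?
#' @return list with `n_vertices`, `n_edges`, `n_triangles`,
#'   `euler_characteristic`, `n_boundary_edges`, `signed_volume` (mm^3);
#'   stops on a violated invariant.
#' @export
validate_surface_mesh <- function(mesh, closed = any(!is.na(mesh$cap))) {
  tr <- mesh$triangles
  ed <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  cnt <- table(key)
  if (any(cnt > 2L)) stop("non-manifold edge (shared by > 2 triangles)")
  n_boundary <- sum(cnt == 1L)
  if (closed && n_boundary > 0L)
    stop("mesh is not watertight: boundary edges present")
  dkey <- paste(ed[, 1], ed[, 2])
  if (anyDuplicated(dkey))
    stop("inconsistent triangle orientation (repeated directed edge)")
  v <- mesh$vertices
  svol <- sum(apply(tr, 1, function(t)
    det(rbind(v[t[1], ], v[t[2], ], v[t[3], ])))) / 6
  list(n_vertices = nrow(v), n_edges = length(cnt), n_triangles = nrow(tr),
       euler_characteristic = nrow(v) - length(cnt) + nrow(tr),
       n_boundary_edges = n_boundary,
       signed_volume = svol)
}

#' Total wall area of a surface mesh (mm^2), excluding caps
#' @param mesh a `surface_mesh`.
#' @return scalar area.
#' @export
wall_area <- function(mesh) {
  idx <- which(is.na(mesh$cap))
  v <- mesh$vertices
  sum(vapply(idx, function(k) {
    t <- mesh$triangles[k, ]
    0.5 * sqrt(sum(.cross3(v[t[2], ] - v[t[1], ], v[t[3], ] - v[t[1], ])^2))
  }, numeric(1)))
}
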