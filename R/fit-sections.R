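#' Fit circular cross-sections to a tubular surface mesh
#'
#' Inverse of [build_surface_mesh()]: ingests a single-lumen tubular
#' surface (e.g. a workstation VRML export) into the cross-section model.
#' The surface must be an open tube with exactly two boundary loops (side
#' branches are not supported — more than two loops is rejected). A
#' centroid path is estimated by binning vertices along the tube axis and
#' smoothed with a moving average; cutting planes are swept along it every
#' `step` mm, the intersection polygon with the surface is assembled, and
#' each cut is represented by its equivalent-area circle,
#' `radius = sqrt(area / pi)`.
#'
#' @param surface a `surface_mesh` with two boundary loops.
#' @param step arc-length sampling step (mm).
#' @return a `vessel_geometry`.
#' @export
fit_cross_sections <- function(surface, step = 0.5) {
  v <- surface$vertices
  tr <- surface$triangles

  # boundary loops: edges used by exactly one triangle
  ed <- rbind(tr[, c(1, 2)], tr[, c(2, 3)], tr[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  single <- names(which(table(key) == 1L))
  if (length(single) == 0L)
    stop("surface is closed; fit_cross_sections needs an open tube ",
         "(build the surface with caps = FALSE or remove the caps)")
  bedges <- do.call(rbind, lapply(strsplit(single, " "), as.integer))
  n_loops <- .count_loops(bedges)
  if (n_loops != 2L)
    stop(sprintf(paste0("expected a single tube with 2 boundary loops, ",
                        "found %d: branched surfaces are not supported"),
                 n_loops))

  # initial axis: principal component of the vertex cloud
  ctr <- colMeans(v)
  pc <- prcomp(v, center = TRUE)
  axis1 <- pc$rotation[, 1]
  t_axis <- as.numeric((v - matrix(ctr, nrow(v), 3, byrow = TRUE)) %*% axis1)

  # centroid path by binning along the axis, then moving-average smoothing
  nb <- max(8L, min(200L, floor(diff(range(t_axis)) / step)))
  bins <- cut(t_axis, breaks = nb, labels = FALSE)
  path <- do.call(rbind, lapply(sort(unique(bins)), function(b)
    colMeans(v[bins == b, , drop = FALSE])))
  if (nrow(path) >= 5L) {
    sm <- function(x) stats::filter(x, rep(1 / 3, 3), sides = 2)
    mid <- 2:(nrow(path) - 1L)
    for (k in 1:3) path[mid, k] <- sm(path[, k])[mid]
  }
  seg <- sqrt(rowSums(diff(path)^2))
  s_path <- c(0, cumsum(seg))

  # sweep cutting planes
  s_out <- seq(0, max(s_path), by = step)
  if (max(s_out) < max(s_path) - 1e-9) s_out <- c(s_out, max(s_path))
  # drop the exact end planes (they graze the boundary loops)
  eps <- min(step, max(s_path) / 100) * 0.25
  s_cut <- pmin(pmax(s_out, eps), max(s_path) - eps)

  centers <- matrix(NA_real_, length(s_out), 3)
  radii <- numeric(length(s_out))
  for (i in seq_along(s_out)) {
    p0 <- .path_point(s_path, path, s_cut[i])
    tn <- .path_tangent(s_path, path, s_cut[i])
    cut <- .plane_cut(v, tr, p0, tn)
    if (is.null(cut)) stop("cutting plane missed the surface; reduce step")
    centers[i, ] <- cut$centroid
    radii[i] <- sqrt(cut$area / pi)
  }
  vessel_geometry(s_out, centers, radii, name = "fitted")
}

.count_loops <- function(bedges) {
  # union-find over boundary edge endpoints
  verts <- unique(as.vector(bedges))
  parent <- seq_along(verts)
  idx <- function(x) match(x, verts)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in seq_len(nrow(bedges))) {
    a <- find(idx(bedges[k, 1])); b <- find(idx(bedges[k, 2]))
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_along(verts), find, integer(1))))
}

.path_point <- function(s_path, path, s) {
  cbind(stats::approx(s_path, path[, 1], s)$y,
        stats::approx(s_path, path[, 2], s)$y,
        stats::approx(s_path, path[, 3], s)$y)[1, ]
}

.path_tangent <- function(s_path, path, s) {
  i <- max(1L, min(nrow(path) - 1L, findInterval(s, s_path)))
  d <- path[i + 1L, ] - path[i, ]
  d / sqrt(sum(d^2))
}

# Intersect a triangle mesh with the plane through p0 with normal tn and
# return the area and centroid of the intersection loop nearest p0.
.plane_cut <- function(v, tr, p0, tn) {
  h <- as.numeric((v - matrix(p0, nrow(v), 3, byrow = TRUE)) %*% tn)
  # planes passing exactly through mesh vertices: push those vertices to
  # the positive side so the cut polygon is still well defined
  tol0 <- 1e-9 * max(1, max(abs(h)))
  h[abs(h) < tol0] <- tol0
  hs <- h[tr]
  dim(hs) <- dim(tr)
  crossing <- (apply(hs, 1, max) > 0) & (apply(hs, 1, min) < 0)
  if (!any(crossing)) return(NULL)
  segs <- list()
  for (k in which(crossing)) {
    t3 <- tr[k, ]; hh <- h[t3]
    pts <- list()
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      a <- e[1]; b <- e[2]
      if ((hh[a] > 0) != (hh[b] > 0)) {
        w <- hh[a] / (hh[a] - hh[b])
        pts[[length(pts) + 1L]] <- v[t3[a], ] + w * (v[t3[b], ] - v[t3[a], ])
      }
    }
    if (length(pts) == 2L) segs[[length(segs) + 1L]] <- do.call(rbind, pts)
  }
  if (length(segs) == 0L) return(NULL)
  # chain segments into loops by snapping endpoints
  allp <- do.call(rbind, segs)
  key <- paste(round(allp[, 1], 9), round(allp[, 2], 9), round(allp[, 3], 9))
  uid <- match(key, unique(key))
  np <- max(uid)
  e1 <- uid[seq(1, length(uid), by = 2)]
  e2 <- uid[seq(2, length(uid), by = 2)]
  adj <- vector("list", np)
  for (k in seq_along(e1)) {
    adj[[e1[k]]] <- c(adj[[e1[k]]], e2[k])
    adj[[e2[k]]] <- c(adj[[e2[k]]], e1[k])
  }
  upts <- allp[!duplicated(key), , drop = FALSE]
  visited <- logical(np)
  best <- NULL; best_d <- Inf
  for (start in seq_len(np)) {
    if (visited[start]) next
    loop <- integer(0)
    cur <- start; prev <- 0L
    repeat {
      visited[cur] <- TRUE
      loop <- c(loop, cur)
      nxt <- setdiff(adj[[cur]], prev)
      nxt <- nxt[!visited[nxt] | nxt == start]
      if (length(nxt) == 0L) break
      prev <- cur; cur <- nxt[1]
      if (cur == start) break
    }
    if (length(loop) >= 3L) {
      pts <- upts[loop, , drop = FALSE]
      cen <- colMeans(pts)
      d <- sum((cen - p0)^2)
      if (d < best_d) { best_d <- d; best <- pts }
    }
  }
  if (is.null(best)) return(NULL)
  # polygon area via the cross-product (Newell) formula
  cen <- colMeans(best)
  n <- nrow(best)
  acc <- c(0, 0, 0)
  for (k in seq_len(n)) {
    a <- best[k, ] - cen
    b <- best[(k %% n) + 1L, ] - cen
    acc <- acc + .cross3(a, b)
  }
  list(area = 0.5 * sqrt(sum(acc^2)), centroid = cen)
}
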