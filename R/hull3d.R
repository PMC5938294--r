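# Incremental 3D convex hull (beneath-beyond), plain R.
#
# Returns triangular faces with outward orientation. Robust enough for the
# point sets arising here (voxel centers, up to a few thousand points):
# visibility uses a scaled epsilon, and a point coplanar with a face it
# lies outside of is always strictly visible from the adjacent face, so
# grid degeneracies resolve correctly.

convex_hull3 <- function(points, eps_rel = 1e-10) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  n <- nrow(points)
  if (n < 4L)
    stop("degenerate geometry: need at least 4 points for a 3D hull",
         call. = FALSE)
  scale <- max(apply(points, 2, function(x) diff(range(x))), 1e-12)
  eps <- eps_rel * scale

  # --- initial non-degenerate tetrahedron ---------------------------------
  i1 <- which.min(points[, 1])
  d1 <- rowSums(sweep(points, 2, points[i1, ])^2)
  i2 <- which.max(d1)
  if (sqrt(d1[i2]) <= eps)
    stop("degenerate geometry: all points coincide", call. = FALSE)
  e1 <- points[i2, ] - points[i1, ]
  # distance from line i1-i2
  rel <- sweep(points, 2, points[i1, ])
  t <- (rel %*% e1) / sum(e1^2)
  perp <- rel - t %*% t(e1)
  i3 <- which.max(rowSums(perp^2))
  if (sqrt(sum(perp[i3, ]^2)) <= eps)
    stop("degenerate geometry: points are collinear", call. = FALSE)
  nrm <- cross3(points[i2, ] - points[i1, ], points[i3, ] - points[i1, ])
  h <- abs(rel %*% nrm) / sqrt(sum(nrm^2))
  i4 <- which.max(h)
  if (h[i4] <= eps)
    stop("degenerate geometry: points are coplanar", call. = FALSE)

  verts <- c(i1, i2, i3, i4)
  faces <- rbind(c(1L, 2L, 3L), c(1L, 2L, 4L), c(1L, 3L, 4L), c(2L, 3L, 4L))
  faces <- matrix(verts[faces], ncol = 3)
  centroid <- colMeans(points[verts, ])
  faces <- t(apply(faces, 1, orient_face, points = points, inside = centroid))
  planes <- face_planes(faces, points)

  for (p in setdiff(seq_len(n), verts)) {
    d <- planes$normals %*% points[p, ] - planes$offsets
    vis <- which(d > eps)
    if (length(vis) == 0L) next
    # horizon: edges belonging to exactly one visible face
    vf <- faces[vis, , drop = FALSE]
    edges <- rbind(vf[, c(1, 2)], vf[, c(2, 3)], vf[, c(1, 3)])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    horizon <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    keep <- setdiff(seq_len(nrow(faces)), vis)
    inside <- colMeans(points[unique(as.vector(faces)), , drop = FALSE])
    new_faces <- cbind(horizon, p)
    new_faces <- t(apply(new_faces, 1, orient_face, points = points,
                         inside = inside))
    faces <- rbind(faces[keep, , drop = FALSE], new_faces)
    planes <- face_planes(faces, points)
  }
  list(faces = faces, points = points,
       normals = planes$normals, offsets = planes$offsets)
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# flip a face (vertex index triple) so its normal points away from `inside`
orient_face <- function(f, points, inside) {
  nrm <- cross3(points[f[2], ] - points[f[1], ], points[f[3], ] - points[f[1], ])
  if (sum(nrm * (points[f[1], ] - inside)) < 0) f[c(1, 3, 2)] else f
}

face_planes <- function(faces, points) {
  a <- points[faces[, 1], , drop = FALSE]
  b <- points[faces[, 2], , drop = FALSE]
  c_ <- points[faces[, 3], , drop = FALSE]
  u <- b - a; v <- c_ - a
  normals <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                   u[, 3] * v[, 1] - u[, 1] * v[, 3],
                   u[, 1] * v[, 2] - u[, 2] * v[, 1])
  len <- sqrt(rowSums(normals^2))
  normals <- normals / len
  list(normals = normals, offsets = rowSums(normals * a))
}

# enclosed volume and boundary area of a triangulated hull
hull_metrics <- function(hull) {
  p <- hull$points; f <- hull$faces
  a <- p[f[, 1], , drop = FALSE]
  b <- p[f[, 2], , drop = FALSE]
  c_ <- p[f[, 3], , drop = FALSE]
  u <- b - a; v <- c_ - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  area <- sum(sqrt(rowSums(cr^2))) / 2
  # divergence theorem with outward-oriented faces
  vol <- sum(rowSums(a * cr)) / 6
  list(volume = abs(vol), surface = area)
}
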