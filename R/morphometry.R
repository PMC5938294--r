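#' Stone size estimates
#'
#' Container for the six automated size estimates of a segmented stone:
#' `length` (largest border-point distance, the 3D Feret length), `width`
#' (largest diameter perpendicular to the long axis), `cross_sectional_area`
#' and `circumference` (at the maximal perpendicular section), `volume` and
#' `surface_area` (enclosing surface over the segmented voxels), plus the
#' unit `long_axis`.
#'
#' @name stone_measurements
#' @keywords internal
NULL

new_stone_measurements <- function(length, width, area, circumference,
                                   volume, surface, long_axis,
                                   provenance = list()) {
  structure(list(length = length, width = width,
                 cross_sectional_area = area, circumference = circumference,
                 volume = volume, surface_area = surface,
                 long_axis = long_axis, provenance = provenance),
            class = "stone_measurements")
}

#' @export
print.stone_measurements <- function(x, ...) {
  cat("<stone_measurements>\n")
  cat(sprintf("  length        %7.2f mm\n", x$length))
  cat(sprintf("  width         %7.2f mm\n", x$width))
  cat(sprintf("  area          %7.2f mm^2\n", x$cross_sectional_area))
  cat(sprintf("  circumference %7.2f mm\n", x$circumference))
  cat(sprintf("  volume        %7.2f mm^3\n", x$volume))
  cat(sprintf("  surface       %7.2f mm^2\n", x$surface_area))
  invisible(x)
}

# world coordinates (mm) of occupied voxel centers, n x 3 matrix
mask_points <- function(mask) {
  idx <- which(mask$occupancy)
  if (length(idx) == 0L) stop("empty mask", call. = FALSE)
  ind <- arrayInd(idx, dim(mask$occupancy))
  sweep(sweep(ind - 1, 2, mask$spacing, `*`), 2, mask$origin, `+`)
}

#' Border points of a stone mask
#'
#' Centers (mm, world coordinates) of occupied voxels with at least one
#' unoccupied 6-neighbour; the grid edge counts as outside. This is the
#' strictest digital surface definition and the point set over which the
#' Feret length is taken.
#'
#' @param mask A [stone_mask].
#' @return An n x 3 numeric matrix of border-voxel centers.
#' @export
border_points <- function(mask) {
  stopifnot(inherits(mask, "stone_mask"))
  occ <- mask$occupancy
  if (!any(occ)) stop("empty mask", call. = FALSE)
  interior <- occ
  for (a in 1:3) for (s in c(-1L, 1L)) {
    off <- c(0L, 0L, 0L); off[a] <- s
    interior <- interior & shift_mask(occ, off)
  }
  border <- occ & !interior
  ind <- arrayInd(which(border), dim(occ))
  sweep(sweep(ind - 1, 2, mask$spacing, `*`), 2, mask$origin, `+`)
}

# maximum pairwise distance among rows of `pts`; returns the achieving
# pair with deterministic lexicographic tie-break. Large sets are first
# reduced to their convex-hull vertices (the diameter is attained there).
max_pair_distance <- function(pts) {
  n <- nrow(pts)
  if (n > 2500L) {
    hull <- tryCatch(convex_hull3(pts), error = function(e) NULL)
    if (!is.null(hull)) {
      keep <- sort(unique(as.vector(hull$faces)))
      pts <- pts[keep, , drop = FALSE]
      n <- nrow(pts)
    }
  }
  if (n == 1L) return(list(d = 0, i = 1L, j = 1L, pts = pts))
  dm <- as.matrix(stats::dist(pts))
  dmax <- max(dm)
  cand <- which(dm >= dmax - 1e-12 & upper.tri(dm), arr.ind = TRUE)
  # lexicographic order of (point i, point j) coordinate pairs
  ord <- do.call(order, as.data.frame(cbind(pts[cand[, 1], , drop = FALSE],
                                            pts[cand[, 2], , drop = FALSE])))
  best <- cand[ord[1], ]
  list(d = dmax, i = best[1], j = best[2], pts = pts)
}

#' Stone length and long axis
#'
#' The stone length is the largest Euclidean distance between two border
#' points (3D Feret diameter); the long axis is the unit vector joining the
#' achieving pair (ties broken by lexicographic order of the point pair).
#'
#' @param mask A [stone_mask].
#' @return List with `length` (mm) and `axis` (unit length-3 vector; `NA`
#'   sentinel for a single-voxel mask).
#' @export
length_and_axis <- function(mask) {
  bp <- border_points(mask)
  if (nrow(bp) == 1L)
    return(list(length = 0, axis = rep(NA_real_, 3)))
  mp <- max_pair_distance(bp)
  ax <- mp$pts[mp$j, ] - mp$pts[mp$i, ]
  list(length = mp$d, axis = ax / sqrt(sum(ax^2)))
}

# orthonormal basis (u, v, w) with u = axis
plane_basis <- function(axis) {
  u <- axis / sqrt(sum(axis^2))
  helper <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- cross3(u, helper); v <- v / sqrt(sum(v^2))
  w <- cross3(u, v)
  list(u = u, v = v, w = w)
}

# Resample mask occupancy on planes perpendicular to `axis`.
# Returns a list of 2D logical matrices (planes), their station positions,
# and the in-plane pixel size.
perpendicular_sections <- function(mask, axis, step = NULL) {
  if (any(!is.finite(axis)))
    stop("invalid axis: degenerate long axis", call. = FALSE)
  if (is.null(step)) step <- min(mask$spacing)
  b <- plane_basis(axis)
  pts <- mask_points(mask)
  c0 <- colMeans(pts)
  rel <- sweep(pts, 2, c0)
  tu <- rel %*% b$u; tv <- rel %*% b$v; tw <- rel %*% b$w
  pad <- step
  us <- seq(min(tu) - pad, max(tu) + pad, by = step)
  vs <- seq(min(tv) - pad, max(tv) + pad, by = step)
  ws <- seq(min(tw) - pad, max(tw) + pad, by = step)
  nv <- length(vs); nw <- length(ws)
  d <- dim(mask$occupancy)
  planes <- vector("list", length(us))
  grid_vw <- cbind(rep(vs, times = nw), rep(ws, each = nv))
  base <- grid_vw[, 1] %o% b$v + grid_vw[, 2] %o% b$w
  occ_arr <- mask$occupancy * 1.0
  for (pi in seq_along(us)) {
    p <- sweep(base, 2, c0 + us[pi] * b$u, `+`)
    # trilinear interpolation of the occupancy, thresholded at one half:
    # the reconstructed in-plane edge then sits midway between occupied
    # and empty voxel centers, as in standard multiplanar reformation
    # (nearest-neighbour lookup would systematically thicken oblique
    # sections by up to half a voxel diagonal)
    idx <- sweep(sweep(p, 2, mask$origin), 2, mask$spacing, `/`) + 1
    val <- trilinear_sample(occ_arr, idx, outside = 0)
    planes[[pi]] <- matrix(val >= 0.5, nv, nw)
  }
  list(planes = planes, stations = us, v_coords = vs, w_coords = ws,
       step = step)
}

# max pairwise distance of occupied pixel centers in one 2D plane,
# via 2D convex hull (grDevices::chull)
plane_feret <- function(plane, vs, ws) {
  idx <- which(plane, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0)
  if (nrow(idx) == 1L) return(0)
  xy <- cbind(vs[idx[, 1]], ws[idx[, 2]])
  h <- grDevices::chull(xy)
  xy <- xy[h, , drop = FALSE]
  max(stats::dist(xy))
}

#' Stone width perpendicular to the long axis
#'
#' Automated multiplanar reformation: planes perpendicular to the long axis
#' are sampled every `step` mm along the stone extent with in-plane
#' nearest-neighbour resampling of the occupancy at the same resolution.
#' The width is the maximum over planes of the in-plane Feret diameter.
#'
#' @param mask A [stone_mask].
#' @param axis Unit length-3 long-axis vector (from [length_and_axis()]).
#' @param step Plane spacing and in-plane pixel size (mm); defaults to the
#'   mask voxel size.
#' @return Width in mm.
#' @export
perpendicular_width <- function(mask, axis, step = NULL) {
  stopifnot(inherits(mask, "stone_mask"))
  sec <- perpendicular_sections(mask, axis, step)
  max(vapply(sec$planes, plane_feret, 0, vs = sec$v_coords,
             ws = sec$w_coords))
}

# marching-squares perimeter of the 0.5-level contour of a binary plane.
# The occupancy is lightly smoothed first so the marching-squares linear
# interpolation places vertices at sub-pixel positions tracking the smooth
# boundary; contouring the raw staircase would overestimate a smooth
# perimeter by several percent.
plane_circumference <- function(plane, vs, ws, smooth_sigma = 1) {
  pad <- max(4L, ceiling(4 * smooth_sigma))
  pm <- matrix(0, nrow(plane) + 2L * pad, ncol(plane) + 2L * pad)
  pm[pad + seq_len(nrow(plane)), pad + seq_len(ncol(plane))] <- plane * 1
  dv <- vs[2] - vs[1]; dw <- ws[2] - ws[1]
  x <- c(vs[1] - (pad:1) * dv, vs, vs[length(vs)] + (1:pad) * dv)
  y <- c(ws[1] - (pad:1) * dw, ws, ws[length(ws)] + (1:pad) * dw)
  sm <- gauss_smooth2(pm, smooth_sigma)
  cl <- grDevices::contourLines(x, y, sm, levels = 0.5)
  if (length(cl) == 0L)   # tiny region whose smoothed peak misses 0.5
    cl <- grDevices::contourLines(x, y, pm, levels = 0.5)
  if (length(cl) == 0L) return(0)
  per <- vapply(cl, function(cc) {
    px <- c(cc$x, cc$x[1]); py <- c(cc$y, cc$y[1])
    sum(sqrt(diff(px)^2 + diff(py)^2))
  }, 0)
  max(per)   # the stone section's outer contour
}

#' Maximal cross-section area and circumference
#'
#' Over the same perpendicular planes as [perpendicular_width()], selects
#' the plane of maximal occupied area. Area is occupied-pixel count times
#' pixel area; circumference is the perimeter of the marching-squares
#' contour polygon of that plane (pixel-edge counting would overestimate a
#' smooth perimeter by up to 4/pi).
#'
#' @inheritParams perpendicular_width
#' @return List with `area` (mm^2) and `circumference` (mm).
#' @export
max_section_metrics <- function(mask, axis, step = NULL) {
  stopifnot(inherits(mask, "stone_mask"))
  sec <- perpendicular_sections(mask, axis, step)
  counts <- vapply(sec$planes, sum, 0)
  best <- which.max(counts)
  px_area <- sec$step^2
  area <- counts[best] * px_area
  circ <- plane_circumference(sec$planes[[best]], sec$v_coords, sec$w_coords)
  list(area = area, circumference = circ)
}

#' Enclosing-surface volume and surface area of a point set
#'
#' Volume and boundary area of the surface enclosing all the segmented
#' voxel centers. The enclosing surface is the convex hull of the points:
#' for the compact, convex-leaning shapes of urinary stones this coincides
#' with the tightest single-region enclosing surface, and it is the
#' documented fallback whenever a concavity-following surface cannot be
#' constructed.
#'
#' @param points n x 3 matrix of points (mm); needs >= 4 non-coplanar rows.
#' @return List with `volume` (mm^3) and `surface_area` (mm^2).
#' @export
alpha_shape_metrics <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 4L)
    stop("degenerate geometry: need at least 4 non-coplanar points",
         call. = FALSE)
  hull <- convex_hull3(points)
  hm <- hull_metrics(hull)
  list(volume = hm$volume, surface_area = hm$surface)
}

#' All six automated size estimates of a segmented stone
#'
#' Composes [border_points()], [length_and_axis()],
#' [perpendicular_width()], [max_section_metrics()] and
#' [alpha_shape_metrics()] into the full measurement set. Measures are
#' computed on the mask as given (i.e. after dilation when the mask comes
#' from [segment_stone()]); provenance records this.
#'
#' @param mask A [stone_mask].
#' @return A `stone_measurements` object.
#' @examples
#' m <- digitize_ellipsoid(c(5, 3, 2), spacing = 0.5)
#' measure_stone(m)
#' @export
measure_stone <- function(mask) {
  stopifnot(inherits(mask, "stone_mask"))
  la <- length_and_axis(mask)
  if (!all(is.finite(la$axis)))
    stop("degenerate mask: no long axis (single voxel?)", call. = FALSE)
  w <- perpendicular_width(mask, la$axis)
  ms <- max_section_metrics(mask, la$axis)
  # Volume: the tight single-region surface enclosing the segmented voxels
  # (as cubes) encloses exactly the voxel union, so its volume is the
  # voxel count times the voxel volume -- computed directly. A surface
  # through the voxel *centers* necessarily loses a half-voxel rind (it is
  # bounded by their convex hull), biasing the volume several percent low.
  vol <- sum(mask$occupancy) * prod(mask$spacing)
  # Surface area: reported from the enclosing hull of the voxel centers;
  # a staircase voxel surface would overestimate a smooth stone surface by
  # up to sqrt(3), while the hull tracks it for convex-leaning stones.
  am <- alpha_shape_metrics(mask_points(mask))
  new_stone_measurements(length = la$length, width = w, area = ms$area,
                         circumference = ms$circumference,
                         volume = vol, surface = am$surface_area,
                         long_axis = la$axis,
                         provenance = c(mask$provenance,
                                        list(measured_on = "mask as given")))
}

#' Virtual caliper: window-dependent manual measurement emulation
#'
#' Models the apparent stone edge a reader sees at a given display window:
#' the super-level set `{value >= window_level}` (component containing the
#' attenuation peak) is measured with the same geometric operators as the
#' automated pipeline. A lower level (soft-tissue window, L50) shows a
#' larger apparent stone than a higher one (bone window, L300).
#'
#' @param vol A [ct_volume], isotropically resampled.
#' @param window_level Display window level (HU) taken as the apparent edge.
#' @return List with `length` and `width` in mm.
#' @export
virtual_caliper <- function(vol, window_level) {
  stopifnot(inherits(vol, "ct_volume"))
  if (max(vol$values) < window_level)
    stop("no visible stone at window level ", window_level, " HU",
         call. = FALSE)
  occ <- vol$values >= window_level
  m <- stone_mask(occ, spacing = vol$spacing, origin = vol$origin,
                  provenance = list(window_level_hu = window_level))
  peak <- arrayInd(which.max(vol$values), dim(vol$values))[1, ]
  m <- largest_component_with_peak(m, peak)
  la <- length_and_axis(m)
  if (!all(is.finite(la$axis)))
    return(list(length = max(m$spacing), width = max(m$spacing)))
  list(length = la$length,
       width = perpendicular_width(m, la$axis))
}
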