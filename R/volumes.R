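#' CT volume container
#'
#' A `ct_volume` holds a 3D attenuation grid in Hounsfield units (HU)
#' together with its physical geometry: per-axis voxel spacing in mm and the
#' world coordinate (mm) of the *center* of voxel `[1, 1, 1]`. World
#' coordinates are right-handed millimetres with a voxel-center convention,
#' so voxel `[i, j, k]` sits at `origin + (c(i, j, k) - 1) * spacing`.
#'
#' Values are clamped to the representable CT range \[-1024, 3071\] HU.
#'
#' @param values 3D numeric array of attenuation values (HU).
#' @param spacing Numeric length-3, voxel spacing in mm per axis; all > 0.
#' @param origin Numeric length-3, world position (mm) of the first voxel
#'   center. Default `c(0, 0, 0)`.
#' @return An object of class `ct_volume`.
#' @examples
#' vol <- ct_volume(array(100, c(4, 4, 4)), spacing = c(0.7, 0.7, 1))
#' vol
#' @export
ct_volume <- function(values, spacing, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  if (any(dim(values) < 2L))
    stop("volume needs at least 2 samples per axis", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive reals (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite reals (mm)", call. = FALSE)
  if (any(!is.finite(values)))
    stop("attenuation values must be finite", call. = FALSE)
  storage.mode(values) <- "double"
  values[values < -1024] <- -1024
  values[values > 3071] <- 3071
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$values)
  cat("<ct_volume> ", paste(d, collapse = " x "), " voxels, spacing ",
      paste(signif(x$spacing, 4), collapse = " x "), " mm\n", sep = "")
  cat("  HU range [", round(min(x$values), 1), ", ", round(max(x$values), 1),
      "], origin (", paste(signif(x$origin, 4), collapse = ", "), ") mm\n",
      sep = "")
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$values)

#' Rectangular region of interest in world coordinates
#'
#' An axis-aligned box, given by its center and half-extent in mm, used to
#' restrict segmentation to the stone and its immediate surroundings.
#'
#' @param center Numeric length-3, box center (mm, world coordinates).
#' @param half_extent Numeric length-3, half side lengths (mm); all > 0.
#' @return An object of class `roi_box`.
#' @export
roi_box <- function(center, half_extent) {
  center <- as.numeric(center)
  half_extent <- as.numeric(half_extent)
  if (length(center) != 3L || any(!is.finite(center)))
    stop("`center` must be 3 finite reals (mm)", call. = FALSE)
  if (length(half_extent) != 3L || any(!is.finite(half_extent)) ||
      any(half_extent <= 0))
    stop("`half_extent` must be 3 positive reals (mm)", call. = FALSE)
  structure(list(center = center, half_extent = half_extent),
            class = "roi_box")
}

# world-coordinate positions of voxel centers along one axis
axis_coords <- function(vol, axis) {
  vol$origin[axis] + (seq_len(dim(vol$values)[axis]) - 1) * vol$spacing[axis]
}

#' Read a CT volume from a NIfTI-1 file
#'
#' Spacing is taken from the NIfTI `pixdim` fields and the origin from the
#' translation column of the stored affine. Attenuation values are clamped
#' to \[-1024, 3071\] HU on read.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [ct_volume].
#' @export
read_ct_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  if (length(dim(vals)) != 3L)
    stop("expected a 3D NIfTI volume", call. = FALSE)
  sp <- RNifti::pixdim(img)[1:3]
  aff <- RNifti::xform(img)
  ct_volume(vals, spacing = as.numeric(sp), origin = as.numeric(aff[1:3, 4]))
}

#' Write a CT volume to a NIfTI-1 file
#'
#' @param vol A [ct_volume].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type, `"float"` (default) or `"int16"`.
#' @return `path`, invisibly.
#' @export
write_ct_volume <- function(vol, path, datatype = c("float", "int16")) {
  datatype <- match.arg(datatype)
  stopifnot(inherits(vol, "ct_volume"))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  aff <- diag(c(vol$spacing, 1))
  aff[1:3, 4] <- vol$origin
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Resample a CT volume to isotropic voxels
#'
#' Trilinear interpolation onto an isotropic grid, the first step of the
#' automated stone measurement pipeline (CT stacks are typically
#' anisotropic, e.g. 0.7 x 0.7 x 1.0 mm; the stone algorithm runs on
#' 0.25-mm isotropic voxels). The output grid starts at the same first voxel
#' center and preserves the physical extent to within one voxel.
#' Samples beyond the input grid (possible only at the far edge) are
#' clamped to the nearest edge voxel.
#'
#' @param vol A [ct_volume].
#' @param target_spacing Isotropic voxel size in mm, default 0.25.
#' @return A [ct_volume] with spacing `rep(target_spacing, 3)`.
#' @examples
#' vol <- ct_volume(array(rnorm(8 * 8 * 6, 40, 5), c(8, 8, 6)),
#'                  spacing = c(0.7, 0.7, 1))
#' iso <- resample_isotropic(vol, 0.5)
#' dim(iso)
#' @export
resample_isotropic <- function(vol, target_spacing = 0.25) {
  stopifnot(inherits(vol, "ct_volume"))
  if (!is.numeric(target_spacing) || length(target_spacing) != 1L ||
      !is.finite(target_spacing) || target_spacing <= 0)
    stop("`target_spacing` must be a single positive number (mm)",
         call. = FALSE)
  d <- dim(vol$values)
  # preserve center-to-center extent; at least 2 samples per axis
  n_out <- pmax(2L, as.integer(round((d - 1) * vol$spacing / target_spacing)) + 1L)
  # fractional input index (1-based) of each output sample, per axis
  idx <- lapply(1:3, function(a) {
    x <- (seq_len(n_out[a]) - 1) * target_spacing / vol$spacing[a] + 1
    pmin(pmax(x, 1), d[a])   # edge clamp
  })
  # snap samples landing on input voxel centers (within 1e-9 voxel) so the
  # identity resampling and plateau maxima are numerically exact
  idx <- lapply(idx, function(x) {
    r <- round(x)
    near <- abs(x - r) < 1e-9
    x[near] <- r[near]
    x
  })
  lo <- lapply(1:3, function(a) pmin(floor(idx[[a]]), d[a] - 1L))
  fr <- lapply(1:3, function(a) idx[[a]] - lo[[a]])

  i0 <- as.integer(lo[[1]]); j0 <- as.integer(lo[[2]]); k0 <- as.integer(lo[[3]])
  fx <- fr[[1]]; fy <- fr[[2]]; fz <- fr[[3]]
  nx <- n_out[1]; ny <- n_out[2]; nz <- n_out[3]

  v <- vol$values
  out <- array(0, n_out)
  wsum <- array(0, n_out)
  # gather the 8 trilinear corners with vectorized index arithmetic
  FX <- array(fx, n_out)
  FY <- array(rep(fy, each = nx), n_out)
  FZ <- array(rep(fz, each = nx * ny), n_out)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    ii <- i0 + dx; jj <- j0 + dy; kk <- k0 + dz
    lin <- array(0L, n_out)
    lin <- array(rep(ii, times = ny * nz), n_out) +
      (array(rep(jj, each = nx), n_out) - 1L) * d[1] +
      (array(rep(kk, each = nx * ny), n_out) - 1L) * (d[1] * d[2])
    w <- (if (dx == 1) FX else 1 - FX) *
         (if (dy == 1) FY else 1 - FY) *
         (if (dz == 1) FZ else 1 - FZ)
    out <- out + w * v[lin]
    wsum <- wsum + w
  }
  # renormalise: the eight weights sum to one analytically; dividing by
  # their computed sum keeps constant plateaus (and so half-max
  # thresholds) numerically exact
  out <- out / wsum
  ct_volume(out, spacing = rep(target_spacing, 3), origin = vol$origin)
}

#' Crop a CT volume to a region of interest
#'
#' Extracts the subvolume of voxel centers falling inside the box (clipped
#' to the volume bounds), updating the origin so world coordinates are
#' preserved.
#'
#' @param vol A [ct_volume].
#' @param roi A [roi_box].
#' @return A [ct_volume] covering the intersection of `roi` and `vol`.
#' @export
crop_roi <- function(vol, roi) {
  stopifnot(inherits(vol, "ct_volume"), inherits(roi, "roi_box"))
  d <- dim(vol$values)
  rng <- lapply(1:3, function(a) {
    x <- axis_coords(vol, a)
    which(x >= roi$center[a] - roi$half_extent[a] - 1e-9 &
          x <= roi$center[a] + roi$half_extent[a] + 1e-9)
  })
  if (any(vapply(rng, length, 1L) == 0L))
    stop("ROI does not intersect the volume (empty crop)", call. = FALSE)
  i <- rng[[1]]; j <- rng[[2]]; k <- rng[[3]]
  # keep at least 2 samples per axis so the result is a valid volume
  for (a in 1:3) {
    if (length(rng[[a]]) == 1L) {
      v <- rng[[a]]
      rng[[a]] <- if (v < d[a]) c(v, v + 1L) else c(v - 1L, v)
    }
  }
  i <- rng[[1]]; j <- rng[[2]]; k <- rng[[3]]
  ct_volume(vol$values[i, j, k, drop = FALSE], spacing = vol$spacing,
            origin = vol$origin + (c(i[1], j[1], k[1]) - 1) * vol$spacing)
}
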