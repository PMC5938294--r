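#' Binary stone mask
#'
#' Voxel-aligned stone segmentation sharing the grid geometry of its source
#' [ct_volume]. `provenance` records how the mask was produced (applied
#' threshold in HU, dilation radius in voxels, ...).
#'
#' @param occupancy 3D logical array.
#' @param spacing Numeric length-3 voxel spacing (mm).
#' @param origin Numeric length-3 world position of the first voxel center (mm).
#' @param provenance Named list of processing metadata.
#' @return An object of class `stone_mask`.
#' @export
stone_mask <- function(occupancy, spacing, origin = c(0, 0, 0),
                       provenance = list()) {
  if (!is.array(occupancy) || length(dim(occupancy)) != 3L)
    stop("`occupancy` must be a 3D array", call. = FALSE)
  storage.mode(occupancy) <- "logical"
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive reals (mm)", call. = FALSE)
  structure(list(occupancy = occupancy, spacing = spacing,
                 origin = as.numeric(origin), provenance = provenance),
            class = "stone_mask")
}

#' @export
print.stone_mask <- function(x, ...) {
  d <- dim(x$occupancy)
  cat("<stone_mask> ", paste(d, collapse = " x "), " voxels (",
      sum(x$occupancy), " occupied), spacing ",
      paste(signif(x$spacing, 4), collapse = " x "), " mm\n", sep = "")
  if (!is.null(x$provenance$threshold_hu))
    cat("  threshold ", x$provenance$threshold_hu, " HU, dilation radius ",
        x$provenance$dilation_radius_vox %||% 0, " voxels\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Adaptive segmentation threshold
#'
#' The stone threshold is one half of the maximum attenuation in the stone,
#' floored at 200 HU (the floor keeps image noise out of faint stones).
#'
#' @param max_hu Maximum attenuation in the stone region (HU).
#' @return Threshold in HU: `max(max_hu / 2, 200)`.
#' @examples
#' compute_threshold(1200)  # 600
#' compute_threshold(350)   # 200 (floor)
#' @export
compute_threshold <- function(max_hu) {
  if (!is.finite(max_hu)) stop("`max_hu` must be finite", call. = FALSE)
  max(max_hu / 2, 200)
}

#' Threshold a resampled CT volume into a stone mask
#'
#' Voxels with attenuation `>=` the adaptive threshold (computed from the
#' volume maximum) are labelled stone. Comparison is inclusive so the
#' 400-HU boundary case (half-max equals the floor) is deterministic.
#'
#' @param vol A [ct_volume], already resampled to an isotropic grid.
#' @return A [stone_mask] with `threshold_hu` recorded in its provenance.
#' @export
threshold_segment <- function(vol) {
  stopifnot(inherits(vol, "ct_volume"))
  mx <- max(vol$values)
  thr <- compute_threshold(mx)
  occ <- vol$values >= thr
  if (!any(occ))
    stop("no stone found: no voxel reaches the ", thr, " HU threshold",
         call. = FALSE)
  stone_mask(occ, spacing = vol$spacing, origin = vol$origin,
             provenance = list(threshold_hu = thr, max_hu = mx))
}

# 26-neighbourhood integer offsets (excluding the origin)
offsets26 <- local({
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
})

# shift a logical 3D array by an integer offset, zero-filling
shift_mask <- function(occ, off) {
  d <- dim(occ)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    o <- off[a]
    if (o >= 0) { src[[a]] <- seq_len(d[a] - o); dst[[a]] <- src[[a]] + o }
    else        { dst[[a]] <- seq_len(d[a] + o); src[[a]] <- dst[[a]] - o }
    if (length(src[[a]]) == 0L) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <-
    occ[src[[1]], src[[2]], src[[3]]]
  out
}

#' Keep the connected component containing the attenuation peak
#'
#' Thresholding "the stone and the surrounding tissue" can pick up other
#' bright islands; the stone is the 26-connected component containing the
#' maximum-attenuation voxel. Implemented as an iterative flood fill from
#' the peak.
#'
#' @param mask A [stone_mask].
#' @param peak_index Integer length-3 voxel index (1-based) of the peak.
#' @return A [stone_mask] containing only that component.
#' @export
largest_component_with_peak <- function(mask, peak_index) {
  stopifnot(inherits(mask, "stone_mask"))
  occ <- mask$occupancy
  peak_index <- as.integer(peak_index)
  if (length(peak_index) != 3L ||
      any(peak_index < 1L) || any(peak_index > dim(occ)))
    stop("`peak_index` outside the grid", call. = FALSE)
  if (!occ[peak_index[1], peak_index[2], peak_index[3]])
    stop("inconsistent input: peak voxel is not inside the mask", call. = FALSE)
  comp <- array(FALSE, dim(occ))
  comp[peak_index[1], peak_index[2], peak_index[3]] <- TRUE
  repeat {
    grown <- comp
    for (i in seq_len(nrow(offsets26)))
      grown <- grown | shift_mask(comp, offsets26[i, ])
    grown <- grown & occ
    if (sum(grown) == sum(comp)) break
    comp <- grown
  }
  stone_mask(comp, spacing = mask$spacing, origin = mask$origin,
             provenance = mask$provenance)
}

# integer-lattice ball offsets: squared norm <= radius^2, origin excluded
ball_offsets <- function(radius) {
  r <- floor(radius)
  g <- as.matrix(expand.grid(dx = -r:r, dy = -r:r, dz = -r:r))
  g <- g[rowSums(g^2) <= radius^2 + 1e-9, , drop = FALSE]
  g[!(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0), , drop = FALSE]
}

#' Morphological dilation with a spherical structuring element
#'
#' Dilates the mask with the digital ball of integer offsets whose squared
#' Euclidean norm is at most `radius_vox^2` (33 voxels at the default
#' radius 2, i.e. 0.5 mm at 0.25-mm voxels). The dilation compensates the
#' half-maximum threshold's bias towards the manual bone-window size.
#'
#' @param mask A [stone_mask].
#' @param radius_vox Structuring-element radius in voxels, default 2.
#' @return A dilated [stone_mask]; provenance gains `dilation_radius_vox`.
#' @export
dilate_spherical <- function(mask, radius_vox = 2) {
  stopifnot(inherits(mask, "stone_mask"))
  if (radius_vox < 0)
    stop("`radius_vox` must be >= 0", call. = FALSE)
  occ <- mask$occupancy
  if (radius_vox >= 1) {
    offs <- ball_offsets(radius_vox)
    out <- occ
    for (i in seq_len(nrow(offs)))
      out <- out | shift_mask(occ, offs[i, ])
    occ <- out
  }
  prov <- mask$provenance
  prov$dilation_radius_vox <- radius_vox
  stone_mask(occ, spacing = mask$spacing, origin = mask$origin,
             provenance = prov)
}

#' Automated three-step stone segmentation
#'
#' The full pipeline: crop the stone neighbourhood, resample to 0.25-mm
#' isotropic voxels, threshold at half of the maximum attenuation (200-HU
#' floor), keep the component containing the attenuation peak, and dilate
#' with a 2-voxel (0.5-mm) spherical structuring element.
#'
#' @param vol A [ct_volume] (native acquisition grid).
#' @param roi A [roi_box] around the stone.
#' @param target_spacing Isotropic working voxel size (mm), default 0.25.
#' @param dilation_radius_vox Dilation radius in voxels, default 2.
#' @return A [stone_mask] on the isotropic grid with full provenance.
#' @examples
#' ph <- synth_stone_volume(phantom_spec(c(3, 3, 3)))
#' m <- segment_stone(ph$volume, roi_box(c(0, 0, 0), c(5, 5, 5)))
#' m$provenance$threshold_hu
#' @export
segment_stone <- function(vol, roi, target_spacing = 0.25,
                          dilation_radius_vox = 2) {
  stopifnot(inherits(vol, "ct_volume"), inherits(roi, "roi_box"))
  cropped <- crop_roi(vol, roi)
  iso <- resample_isotropic(cropped, target_spacing)
  m <- threshold_segment(iso)
  peak <- arrayInd(which.max(iso$values), dim(iso$values))[1, ]
  m <- largest_component_with_peak(m, peak)
  m <- dilate_spherical(m, dilation_radius_vox)
  m$provenance$target_spacing_mm <- target_spacing
  m
}
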