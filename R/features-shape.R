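shapeFeatureNames <- c("volume", "surface_area", "sphericity",
                       "surface_to_volume_ratio")

# Iso-surface area of a binary mask: pad, lightly smooth the indicator
# (sub-voxel anti-aliasing), then march tetrahedra at iso 0.5. The
# smoothing width (0.6 voxels) was calibrated against analytic spheres
# and irregular thresholded-noise shapes.
maskSurfaceArea <- function(mask, spacing, sigmaVox = 0.6) {
    # crop to the mask bounding box before padding (area is unaffected)
    bb <- maskBoundingBox(mask, pad = 0L)
    mask <- mask[bb$x[1]:bb$x[2], bb$y[1]:bb$y[2], bb$z[1]:bb$z[2],
                 drop = FALSE]
    d <- dim(mask)
    r <- as.integer(ceiling(3 * sigmaVox) + 1L)
    dp <- d + 2L * r
    f <- array(0, dim = dp)
    f[(r + 1):(r + d[1]), (r + 1):(r + d[2]), (r + 1):(r + d[3])] <-
        as.numeric(mask > 0)
    fs <- cpp_smooth3(as.numeric(f), dp, rep(sigmaVox, 3))
    cpp_mesh_area(fs, dp, as.numeric(spacing), 0.5)
}

#' Shape features of a tumor mask
#'
#' Volume (masked voxel count times voxel volume), mesh surface area of the
#' mask iso-surface, sphericity `pi^(1/3) * (6V)^(2/3) / A` (1 for a
#' perfect sphere), and the surface-to-volume ratio `A / V`. These are
#' sequence-independent and computed once per study.
#'
#' @param mask 3D 0/1 array.
#' @param spacing numeric(3) voxel spacing in mm.
#' @return Named numeric vector: volume (mm^3), surface_area (mm^2),
#'   sphericity, surface_to_volume_ratio (1/mm).
#' @export
shapeFeatures <- function(mask, spacing = c(1, 1, 1)) {
    if (!any(mask > 0)) stop("mask is empty")
    v <- sum(mask > 0) * prod(spacing)
    a <- maskSurfaceArea(mask, spacing)
    c(volume = v, surface_area = a,
      sphericity = pi^(1 / 3) * (6 * v)^(2 / 3) / a,
      surface_to_volume_ratio = a / v)
}
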