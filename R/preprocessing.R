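#' Gray-level quantization of a masked volume
#'
#' Rescales intensities inside the mask to Q discrete gray levels by
#' `round((Q - 1) * (x - vmin) / (vmax - vmin) + 1)` where vmin/vmax are
#' the minimum and maximum intensity inside the mask. Rounding is
#' half-up (half away from zero), so a voxel at vmin maps to level 1 and a
#' voxel at vmax maps to level Q. Voxels outside the mask are NA. The
#' mapping is invariant to affine rescaling a*x + b (a > 0) of the input.
#'
#' @param volume 3D numeric array.
#' @param mask 3D 0/1 array of the same dimensions.
#' @param Q integer number of gray levels (>= 2; default 128).
#' @return A [QuantizedVolume-class].
#' @examples
#' v <- array(runif(64), dim = c(4, 4, 4))
#' m <- array(1L, dim = c(4, 4, 4))
#' q <- quantizeVolume(v, m, Q = 16)
#' range(grayLevels(q), na.rm = TRUE)  # 1 16
#' @export
quantizeVolume <- function(volume, mask, Q = 128L) {
    Q <- as.integer(Q)
    if (Q < 2L) stop("Q must be >= 2")
    stopifnot(identical(dim(volume), dim(mask)))
    inMask <- mask > 0
    if (!any(inMask)) stop("mask is empty")
    x <- volume[inMask]
    vmin <- min(x)
    vmax <- max(x)
    if (vmax <= vmin)
        stop("degenerate-intensity error: constant image within mask")
    lv <- array(NA_integer_, dim = dim(volume))
    scaled <- (Q - 1) * (volume[inMask] - vmin) / (vmax - vmin) + 1
    lv[inMask] <- pmin.int(Q, pmax.int(1L, as.integer(floor(scaled + 0.5))))
    new("QuantizedVolume", levels = lv, Q = Q, vmin = vmin, vmax = vmax,
        mask = array(as.integer(inMask), dim = dim(mask)))
}

# One-octave-bandwidth Gaussian width for a given carrier wavelength.
gaborSigma <- function(wavelength) {
    wavelength / pi * sqrt(log(2) / 2) * 3
}

#' 2D Gabor quadrature kernel pair
#'
#' Builds the even (cosine) and odd (sine) kernels of a 2D Gabor filter
#' with isotropic Gaussian envelope (aspect ratio 1) whose width follows
#' the one-octave-bandwidth relation sigma = 3 * lambda / pi * sqrt(ln2/2).
#' `theta` is measured from the image x-axis (first array dimension), so
#' theta = 0 responds maximally to intensity variation along x.
#'
#' @param theta orientation in degrees.
#' @param wavelength carrier wavelength in pixels.
#' @return list with matrices `even`, `odd` and the scalar `sigma`.
#' @export
gaborKernel <- function(theta, wavelength) {
    sigma <- gaborSigma(wavelength)
    hs <- max(3L, as.integer(ceiling(3 * sigma)))
    g <- seq(-hs, hs)
    xx <- matrix(g, 2 * hs + 1, 2 * hs + 1)
    yy <- t(xx)
    th <- theta * pi / 180
    xr <- xx * cos(th) + yy * sin(th)
    env <- exp(-(xx^2 + yy^2) / (2 * sigma^2))
    list(even = env * cos(2 * pi * xr / wavelength),
         odd = env * sin(2 * pi * xr / wavelength),
         sigma = sigma)
}

# Padded bounding box of the mask (1-based inclusive limits per axis).
maskBoundingBox <- function(mask, pad = 0L) {
    d <- dim(mask)
    w <- which(mask > 0, arr.ind = TRUE)
    lim <- function(ax) c(max(1L, min(w[, ax]) - pad),
                          min(d[ax], max(w[, ax]) + pad))
    list(x = lim(1L), y = lim(2L), z = lim(3L))
}

#' Gabor edge filter bank
#'
#' Applies the 2D Gabor quadrature pair slice-wise in the axial plane
#' (third array dimension) to each of the three sequences, for the four
#' orientations theta = 0, 30, 45, 90 degrees and the two frequency labels
#' "2" and "2sqrt2" (carrier wavelengths of 2 and 2*sqrt(2) pixels),
#' yielding exactly 24 magnitude edge maps per study. Filtering uses the
#' unscaled (pre-quantization) volumes. Responses are computed over the
#' mask bounding box padded by the kernel radius (plus `pad`); values
#' outside that region are 0 and are never used by masked statistics.
#'
#' @param study an [MRIStudy-class].
#' @param sequences subset of sequences to filter (default all three).
#' @param thetas orientations in degrees (default c(0, 30, 45, 90)).
#' @param frequencies frequency labels (default c("2", "2sqrt2")).
#' @param pad extra padding (voxels) added around the mask bounding box.
#' @param restrict "bbox" (default) computes responses over the padded
#'   bounding box; "mask" computes them at masked voxels only (identical
#'   masked statistics at a fraction of the cost).
#' @return Named list of [GaborEdgeMap-class] objects; names follow
#'   `<sequence>.gabor.theta<theta>_f<label>`.
#' @export
gaborBank <- function(study, sequences = c("T1WI", "T1WI_CE", "FLAIR"),
                      thetas = c(0, 30, 45, 90),
                      frequencies = c("2", "2sqrt2"), pad = 2L,
                      restrict = c("bbox", "mask")) {
    restrict <- match.arg(restrict)
    raw <- gaborRaw(study, sequences, thetas, frequencies, pad, restrict)
    maps <- lapply(raw, function(r)
        new("GaborEdgeMap", response = r$response, theta = r$theta,
            frequency = r$frequency, wavelength = r$wavelength,
            sequence = r$sequence))
    names(maps) <- names(raw)
    maps
}

# Raw response arrays plus metadata, without S4 wrapping (fast path shared
# by gaborBank and extractFeatures).
gaborRaw <- function(study, sequences, thetas, frequencies, pad,
                     restrict) {
    stopifnot(is(study, "MRIStudy"))
    wl <- c("2" = 2, "2sqrt2" = 2 * sqrt(2))
    d <- dim(study@mask)
    out <- list()
    kernels <- list()
    for (f in frequencies)
        for (th in thetas)
            kernels[[paste(th, f)]] <- gaborKernel(th, wl[[f]])
    maxHs <- max(vapply(kernels, function(k) nrow(k$even) %/% 2L, 1L))
    bb <- maskBoundingBox(study@mask, pad = maxHs + pad)
    sel <- if (restrict == "mask") as.integer(study@mask) else integer(0)
    for (sq in sequences) {
        vol <- as.numeric(getSequence(study, sq))
        for (f in frequencies) {
            for (th in thetas) {
                k <- kernels[[paste(th, f)]]
                resp <- cpp_gabor_response(vol, d, k$even, k$odd,
                                           bb$x, bb$y, bb$z, sel)
                nm <- sprintf("%s.gabor.theta%d_f%s", sq, th, f)
                out[[nm]] <- list(response = resp, theta = th,
                                  frequency = f,
                                  wavelength = unname(wl[[f]]),
                                  sequence = sq)
            }
        }
    }
    out
}
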