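# Population (biased) central moments; skewness m3/m2^1.5, excess kurtosis.
popMoments <- function(x) {
    n <- length(x)
    mu <- mean(x)
    m2 <- mean((x - mu)^2)
    m3 <- mean((x - mu)^3)
    m4 <- mean((x - mu)^4)
    list(mean = mu, m2 = m2,
         skewness = if (m2 > 0) m3 / m2^1.5 else NA_real_,
         kurtosis = if (m2 > 0) m4 / m2^2 - 3 else NA_real_)
}

histogramFeatureNames <- c(
    "min", "max", "range", "mean", "median", "sd", "variance", "skewness",
    "kurtosis", "p10", "p25", "p75", "p90", "iqr", "energy", "entropy",
    "rms", "mad", "cv", "uniformity")

#' Intensity-histogram features of a masked volume
#'
#' The 20-feature first-order block computed from unscaled intensities
#' inside the mask: min, max, range, mean, median, SD, variance, skewness,
#' excess kurtosis, 10th/25th/75th/90th percentiles, interquartile range,
#' energy, entropy, root mean square, mean absolute deviation, coefficient
#' of variation and uniformity. SD/variance and the standardized moments
#' use population (biased) denominators; percentiles use linear
#' interpolation between order statistics; entropy and uniformity use 128
#' equal-width bins over the masked intensity range (log base 2). Features
#' undefined for a degenerate distribution (e.g. skewness of a constant
#' region) are returned as NA.
#'
#' @param volume 3D numeric array.
#' @param mask 3D 0/1 array.
#' @return Named numeric vector of length 20.
#' @export
histogramFeatures <- function(volume, mask) {
    x <- volume[mask > 0]
    if (length(x) == 0) stop("mask is empty")
    mo <- popMoments(x)
    qs <- quantile(x, c(0.10, 0.25, 0.75, 0.90), names = FALSE, type = 7)
    rng <- max(x) - min(x)
    if (rng > 0) {
        br <- seq(min(x), max(x), length.out = 129L)
        h <- tabulate(pmin.int(128L, findInterval(x, br)), nbins = 128L)
        p <- h / length(x)
        p <- p[p > 0]
        entropy <- -sum(p * log2(p))
        uniformity <- sum(p^2)
    } else {
        entropy <- 0
        uniformity <- 1
    }
    c(min = min(x), max = max(x), range = rng, mean = mo$mean,
      median = median(x),
      sd = sqrt(mo$m2), variance = mo$m2, skewness = mo$skewness,
      kurtosis = mo$kurtosis,
      p10 = qs[1], p25 = qs[2], p75 = qs[3], p90 = qs[4],
      iqr = qs[3] - qs[2],
      energy = sum(x^2), entropy = entropy, rms = sqrt(mean(x^2)),
      mad = mean(abs(x - mo$mean)),
      cv = if (mo$mean != 0) sqrt(mo$m2) / mo$mean else NA_real_,
      uniformity = uniformity)
}

gaborStatNames <- c("mean", "sd", "skewness", "kurtosis")

#' Histogram statistics of a Gabor edge map inside the mask
#'
#' Mean, standard deviation, skewness and excess kurtosis (population
#' moments) of the magnitude responses at masked voxels. Skewness and
#' kurtosis of a zero-variance response are NA.
#'
#' @param map a [GaborEdgeMap-class].
#' @param mask 3D 0/1 array on the same grid.
#' @return Named numeric vector of length 4.
#' @export
gaborStats <- function(map, mask) {
    stopifnot(is(map, "GaborEdgeMap"))
    x <- map@response[mask > 0]
    if (length(x) == 0) stop("mask is empty")
    mo <- popMoments(x)
    c(mean = mo$mean, sd = sqrt(mo$m2), skewness = mo$skewness,
      kurtosis = mo$kurtosis)
}
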