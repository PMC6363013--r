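glcmFeatureNames <- c(
    "joint_maximum", "joint_average", "joint_variance", "joint_entropy",
    "difference_average", "difference_variance", "difference_entropy",
    "sum_average", "sum_variance", "sum_entropy",
    "angular_second_moment", "contrast", "dissimilarity",
    "inverse_difference", "inverse_difference_normalized",
    "inverse_difference_moment", "inverse_difference_moment_normalized",
    "inverse_variance", "correlation", "autocorrelation",
    "cluster_tendency", "cluster_shade", "cluster_prominence",
    "information_correlation_1", "information_correlation_2",
    "maximal_correlation_coefficient")

glszmFeatureNames <- c(
    "small_zone_emphasis", "large_zone_emphasis",
    "low_gray_level_zone_emphasis", "high_gray_level_zone_emphasis",
    "small_zone_low_gray_level_emphasis",
    "small_zone_high_gray_level_emphasis",
    "large_zone_low_gray_level_emphasis",
    "large_zone_high_gray_level_emphasis",
    "gray_level_non_uniformity", "gray_level_non_uniformity_normalized",
    "zone_size_non_uniformity", "zone_size_non_uniformity_normalized",
    "zone_percentage", "gray_level_variance", "zone_size_variance",
    "zone_size_entropy")

#' Merged 3D gray-level co-occurrence matrix
#'
#' Counts co-occurring gray-level pairs at an offset of one voxel in all
#' directions (26-connectivity, i.e. the 13 unique 3D offsets and both
#' orderings) over pairs whose two voxels both lie inside the mask, merged
#' into a single symmetric Q x Q matrix.
#'
#' @param q a [QuantizedVolume-class].
#' @return Q x Q symmetric matrix of pair counts.
#' @export
glcmMatrix <- function(q) {
    stopifnot(is(q, "QuantizedVolume"))
    lv <- q@levels
    lv[is.na(lv)] <- 0L
    counts <- cpp_glcm(as.integer(lv), as.logical(q@mask > 0),
                       dim(lv), q@Q)
    if (sum(counts) == 0)
        stop("empty-matrix error: no co-occurring voxel pairs in mask")
    counts
}

#' GLCM texture features
#'
#' The 26-feature co-occurrence block computed from the normalized merged
#' matrix, with gray values 1..Q: joint maximum/average/variance/entropy,
#' difference and sum average/variance/entropy, angular second moment,
#' contrast, dissimilarity, inverse difference (+/- normalized), inverse
#' difference moment (+/- normalized), inverse variance, correlation,
#' autocorrelation, cluster tendency/shade/prominence, the two information
#' correlation measures, and the maximal correlation coefficient. Entropies
#' use log base 2. Features with zero-variance denominators (e.g.
#' correlation of a single-level region) are NA.
#'
#' @param counts Q x Q co-occurrence count (or probability) matrix.
#' @return Named numeric vector of length 26.
#' @export
glcmFeatures <- function(counts) {
    Q <- nrow(counts)
    p <- counts / sum(counts)
    i <- matrix(seq_len(Q), Q, Q)
    j <- t(i)
    px <- rowSums(p)
    mu <- sum(i * p)
    sig2 <- sum((i - mu)^2 * p)
    # diagonal (|i-j|) and cross-diagonal (i+j) probability distributions
    kd <- 0:(Q - 1)
    pd <- numeric(Q)
    rs <- rowsum(as.vector(p), group = as.vector(abs(i - j)))
    pd[as.integer(rownames(rs)) + 1L] <- rs[, 1]
    ks <- 2:(2 * Q)
    ps <- numeric(2 * Q - 1)
    rs <- rowsum(as.vector(p), group = as.vector(i + j))
    ps[as.integer(rownames(rs)) - 1L] <- rs[, 1]
    da <- sum(kd * pd)
    sa <- sum(ks * ps)
    ent <- function(w) {
        w <- w[w > 0]
        -sum(w * log2(w))
    }
    hxy <- ent(p)
    pxy <- outer(px, px)
    ok <- p > 0 & pxy > 0
    hxy1 <- -sum(p[ok] * log2(pxy[ok]))
    hxy2 <- ent(pxy)
    hx <- ent(px)
    ic1 <- if (hx > 0) (hxy - hxy1) / hx else NA_real_
    ic2 <- sqrt(max(0, 1 - exp(-2 * log(2) * (hxy2 - hxy))))
    # maximal correlation coefficient over levels with px > 0
    keep <- which(px > 0)
    mcc <- NA_real_
    if (length(keep) >= 2) {
        pk <- p[keep, keep, drop = FALSE]
        pxk <- px[keep]
        # Q(i,j) = sum_k p(i,k) p(j,k) / (px(i) px(k))
        Qm <- (pk / pxk) %*% (t(pk) / pxk)
        ev <- Re(eigen(Qm, only.values = TRUE)$values)
        ev <- sort(ev, decreasing = TRUE)
        mcc <- sqrt(min(1, max(0, ev[2])))
    }
    invvar <- sum(p[i != j] / (i - j)[i != j]^2)
    c(joint_maximum = max(p),
      joint_average = mu,
      joint_variance = sig2,
      joint_entropy = hxy,
      difference_average = da,
      difference_variance = sum((kd - da)^2 * pd),
      difference_entropy = ent(pd),
      sum_average = sa,
      sum_variance = sum((ks - sa)^2 * ps),
      sum_entropy = ent(ps),
      angular_second_moment = sum(p^2),
      contrast = sum((i - j)^2 * p),
      dissimilarity = sum(abs(i - j) * p),
      inverse_difference = sum(p / (1 + abs(i - j))),
      inverse_difference_normalized = sum(p / (1 + abs(i - j) / Q)),
      inverse_difference_moment = sum(p / (1 + (i - j)^2)),
      inverse_difference_moment_normalized = sum(p / (1 + (i - j)^2 / Q^2)),
      inverse_variance = invvar,
      correlation = if (sig2 > 0) (sum(i * j * p) - mu^2) / sig2
                    else NA_real_,
      autocorrelation = sum(i * j * p),
      cluster_tendency = sum((i + j - 2 * mu)^2 * p),
      cluster_shade = sum((i + j - 2 * mu)^3 * p),
      cluster_prominence = sum((i + j - 2 * mu)^4 * p),
      information_correlation_1 = ic1,
      information_correlation_2 = ic2,
      maximal_correlation_coefficient = mcc)
}

#' Gray-level size-zone matrix
#'
#' Zones are maximal 26-connected components of constant gray level
#' restricted to the mask. Returned compactly as one row per distinct
#' (gray level, zone size) cell with its count, plus the masked voxel
#' count; the zone-size-weighted total always equals the number of masked
#' voxels.
#'
#' @param q a [QuantizedVolume-class].
#' @return List with `zones` (data.frame g, s, n), `nVoxels`, `Q`.
#' @export
glszmMatrix <- function(q) {
    stopifnot(is(q, "QuantizedVolume"))
    lv <- q@levels
    lv[is.na(lv)] <- 0L
    z <- cpp_glszm_zones(as.integer(lv), as.logical(q@mask > 0), dim(lv))
    key <- paste(z[, 1], z[, 2])
    agg <- as.data.frame(table(key), stringsAsFactors = FALSE)
    parts <- strsplit(agg$key, " ", fixed = TRUE)
    zones <- data.frame(g = as.integer(vapply(parts, `[`, "", 1L)),
                        s = as.integer(vapply(parts, `[`, "", 2L)),
                        n = as.integer(agg$Freq))
    zones <- zones[order(zones$g, zones$s), , drop = FALSE]
    rownames(zones) <- NULL
    list(zones = zones, nVoxels = sum(q@mask > 0), Q = q@Q)
}

#' GLSZM texture features
#'
#' The 16-feature size-zone block: small/large zone emphasis, low/high
#' gray-level zone emphasis and their four combinations, gray-level and
#' zone-size non-uniformity (raw and normalized), zone percentage,
#' gray-level variance, zone-size variance, and zone-size entropy (log
#' base 2).
#'
#' @param szm result of [glszmMatrix()].
#' @return Named numeric vector of length 16.
#' @export
glszmFeatures <- function(szm) {
    z <- szm$zones
    nz <- sum(z$n)
    g <- z$g
    s <- z$s
    n <- z$n
    p <- n / nz
    mug <- sum(p * g)
    mus <- sum(p * s)
    ng <- tapply(n, g, sum)
    ns <- tapply(n, s, sum)
    c(small_zone_emphasis = sum(n / s^2) / nz,
      large_zone_emphasis = sum(n * s^2) / nz,
      low_gray_level_zone_emphasis = sum(n / g^2) / nz,
      high_gray_level_zone_emphasis = sum(n * g^2) / nz,
      small_zone_low_gray_level_emphasis = sum(n / (g^2 * s^2)) / nz,
      small_zone_high_gray_level_emphasis = sum(n * g^2 / s^2) / nz,
      large_zone_low_gray_level_emphasis = sum(n * s^2 / g^2) / nz,
      large_zone_high_gray_level_emphasis = sum(n * g^2 * s^2) / nz,
      gray_level_non_uniformity = sum(ng^2) / nz,
      gray_level_non_uniformity_normalized = sum(ng^2) / nz^2,
      zone_size_non_uniformity = sum(ns^2) / nz,
      zone_size_non_uniformity_normalized = sum(ns^2) / nz^2,
      zone_percentage = nz / szm$nVoxels,
      gray_level_variance = sum(p * (g - mug)^2),
      zone_size_variance = sum(p * (s - mus)^2),
      zone_size_entropy = -sum(p * log2(p)))
}
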