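# Independent brute-force oracles used across the suite. These deliberately
# share no code with the implementation paths they check.

# Co-occurrence counts by exhaustive enumeration of all 26 ordered unit
# offsets over masked voxel pairs.
oracleGlcm <- function(levels, mask, Q) {
    d <- dim(levels)
    counts <- matrix(0, Q, Q)
    offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
        if (mask[x, y, z] == 0) next
        for (o in seq_len(nrow(offs))) {
            xx <- x + offs[o, 1]; yy <- y + offs[o, 2]; zz <- z + offs[o, 3]
            if (xx < 1 || xx > d[1] || yy < 1 || yy > d[2] ||
                zz < 1 || zz > d[3]) next
            if (mask[xx, yy, zz] == 0) next
            li <- levels[x, y, z]; lj <- levels[xx, yy, zz]
            counts[li, lj] <- counts[li, lj] + 1
        }
    }
    counts
}

# Size zones by recursive flood fill (26-connectivity, constant level).
oracleGlszm <- function(levels, mask) {
    d <- dim(levels)
    seen <- array(FALSE, dim = d)
    offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
    zones <- NULL
    for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
        if (mask[x, y, z] == 0 || seen[x, y, z]) next
        g <- levels[x, y, z]
        queue <- matrix(c(x, y, z), ncol = 3)
        seen[x, y, z] <- TRUE
        size <- 0L
        while (nrow(queue) > 0) {
            v <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
            size <- size + 1L
            for (o in seq_len(nrow(offs))) {
                w <- v + offs[o, ]
                if (any(w < 1) || any(w > d)) next
                if (mask[w[1], w[2], w[3]] == 0 || seen[w[1], w[2], w[3]] ||
                    levels[w[1], w[2], w[3]] != g) next
                seen[w[1], w[2], w[3]] <- TRUE
                queue <- rbind(queue, w)
            }
        }
        zones <- rbind(zones, data.frame(g = g, s = size))
    }
    agg <- aggregate(list(n = rep(1L, nrow(zones))), by = zones, FUN = sum)
    agg <- agg[order(agg$g, agg$s), , drop = FALSE]
    rownames(agg) <- NULL
    agg
}

# Youden cutpoint by exhaustive search over midpoints and orientations.
oracleYouden <- function(values, status) {
    status <- as.logical(status)
    u <- sort(unique(values))
    cand <- (u[-1] + u[-length(u)]) / 2
    best <- list(J = -Inf, cutoff = NA)
    for (ct in cand) {
        sens_ge <- mean(values[status] >= ct)
        spec_ge <- mean(values[!status] < ct)
        sens_lt <- mean(values[status] < ct)
        spec_lt <- mean(values[!status] >= ct)
        for (J in c(sens_ge + spec_ge - 1, sens_lt + spec_lt - 1)) {
            if (J > best$J + 1e-12) best <- list(J = J, cutoff = ct)
        }
    }
    best
}

# Product-limit estimate by hand: returns data.frame(time, surv) at event
# times.
oracleKm <- function(time, event) {
    ut <- sort(unique(time[event > 0]))
    s <- 1
    out <- NULL
    for (t in ut) {
        atRisk <- sum(time >= t)
        deaths <- sum(time == t & event > 0)
        s <- s * (1 - deaths / atRisk)
        out <- rbind(out, data.frame(time = t, surv = s))
    }
    out
}

# Two-group log-rank chi-square by hand: sum of (O-E) with hypergeometric
# variance at each event time.
oracleLogrank <- function(time, event, group) {
    group <- as.integer(factor(group))
    ut <- sort(unique(time[event > 0]))
    oe <- 0; v <- 0
    for (t in ut) {
        n <- sum(time >= t)
        n1 <- sum(time >= t & group == 1)
        d <- sum(time == t & event > 0)
        d1 <- sum(time == t & event > 0 & group == 1)
        oe <- oe + d1 - d * n1 / n
        if (n > 1)
            v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    oe^2 / v
}

# QuantizedVolume straight from a level array (bypasses quantizeVolume).
mkQuantized <- function(levels, mask, Q) {
    lv <- levels
    lv[mask == 0] <- NA_integer_
    new("QuantizedVolume", levels = lv, Q = as.integer(Q),
        vmin = 0, vmax = 1, mask = array(as.integer(mask > 0), dim(mask)))
}

# Random small quantized instance for property tests.
randomInstance <- function(seed, maxDim = 6L, maxQ = 5L) {
    set.seed(seed)
    d <- sample(2:maxDim, 3, replace = TRUE)
    Q <- sample(2:maxQ, 1)
    levels <- array(sample(seq_len(Q), prod(d), replace = TRUE), dim = d)
    repeat {
        mask <- array(as.integer(runif(prod(d)) < 0.7), dim = d)
        if (sum(mask) >= 2) break
    }
    list(levels = levels, mask = mask, Q = Q, d = d)
}

# Small phantom settings for fast unit tests (the package defaults stay at
# the full 48^3 study size).
smallPhantom <- function(seed = 1L, ...) {
    args <- utils::modifyList(
        list(gridSize = c(32L, 32L, 32L), axes = c(8, 7, 6.5),
             haloWidth = 2, seed = seed),
        list(...))
    do.call(PhantomSpec, args)
}

smallCohort <- function(n = 20L, seed = 1L, ...) {
    args <- utils::modifyList(
        list(n = n, seed = seed,
             template = PhantomSpec(gridSize = c(32L, 32L, 32L),
                                    haloWidth = 2),
             axesRange = c(6, 8.5)),
        list(...))
    do.call(CohortSpec, args)
}
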