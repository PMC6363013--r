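# Smoothed, unit-variance random field with correlation length ell (mm).
# Returns a plain vector (dim attribute set by the caller).
textureField <- function(dim, spacing, ell, sd) {
    f <- cpp_smooth3(rnorm(prod(dim)), as.integer(dim), ell / spacing)
    attributes(f) <- NULL
    s <- stats::sd(f)
    if (s > 0) f <- f * (sd / s)
    f
}

#' Generate a synthetic MRI study
#'
#' Builds one phantom patient: the tumor mask is an ellipsoid; the
#' contrast-enhanced channel carries an enhancing rim whose profile is a
#' Gaussian of the (approximate) distance to the ellipsoid surface with
#' width `rimWidth` (sigma_edge) -- small widths give a thin, sharp ring
#' and strong Gabor edge responses; the interior texture of every channel
#' is a smoothed-noise field with correlation length `textureLength`;
#' FLAIR shows an edema-like halo (the ellipsoid enlarged by `haloWidth`);
#' white Gaussian noise is added everywhere. Deterministic given
#' `spec@seed`.
#'
#' @param spec a [PhantomSpec-class].
#' @param patientId character identifier (default "phantom").
#' @return An [MRIStudy-class].
#' @examples
#' study <- makePhantom(PhantomSpec(seed = 7))
#' sum(tumorMask(study))
#' @export
makePhantom <- function(spec, patientId = "phantom") {
    stopifnot(is(spec, "PhantomSpec"))
    validObject(spec)
    set.seed(spec@seed)
    d <- spec@gridSize
    sp <- spec@spacing
    ctr <- (d + 1) / 2 * sp
    ax <- lapply(1:3, function(k) ((seq_len(d[k]) * sp[k]) - ctr[k]))
    # normalized elliptical radius s: s=1 on the surface
    s <- as.vector(sqrt(outer(outer((ax[[1]] / spec@axes[1])^2,
                                    (ax[[2]] / spec@axes[2])^2, "+"),
                              (ax[[3]] / spec@axes[3])^2, "+")))
    mask <- as.integer(s <= 1)
    haloAxes <- spec@axes + spec@haloWidth
    sh <- as.vector(outer(outer((ax[[1]] / haloAxes[1])^2,
                                (ax[[2]] / haloAxes[2])^2, "+"),
                          (ax[[3]] / haloAxes[3])^2, "+"))
    halo <- as.integer(sh <= 1)
    rbar <- prod(spec@axes)^(1 / 3)
    dist <- (s - 1) * rbar   # approximate signed distance to surface (mm)
    rim <- if (spec@rimWidth > 0) {
        spec@rimAmplitude * exp(-dist^2 / (2 * spec@rimWidth^2))
    } else {
        spec@rimAmplitude * (abs(dist) <= 0.5)
    }
    tex <- lapply(1:3, function(k)
        textureField(d, sp, spec@textureLength, spec@textureSd))
    noise <- function() rnorm(prod(d), sd = spec@noiseSd)
    base <- spec@intensityBase + spec@tumorContrast * mask
    t1 <- base + tex[[1]] * mask + noise()
    t1ce <- base + tex[[2]] * mask + rim + noise()
    flair <- spec@intensityBase + spec@haloContrast * halo +
        tex[[3]] * mask + noise()
    dim(t1) <- dim(t1ce) <- dim(flair) <- d
    maskArr <- mask
    dim(maskArr) <- d
    MRIStudy(patientId = patientId, t1 = t1, t1ce = t1ce, flair = flair,
             mask = maskArr, spacing = sp)
}

# Deterministic per-patient sub-seed derived from the cohort seed.
subSeed <- function(seed, i) {
    as.integer((as.numeric(seed) * 10007 + i * 101) %% 2147483647)
}

#' Simulate cohort ground truth and survival outcomes
#'
#' Per patient: MGMT ~ Bernoulli(pMethylated); the hazard-linked phantom
#' parameter ~ Uniform(paramRange); ellipsoid semi-axes and texture length
#' ~ Uniform over their ranges. Event time T is exponential with rate
#' `exp(beta0 + betaMgmt*MGMT + betaImg*param + betaInteraction*I(MGMT &
#' param > intThreshold))`; censoring C ~ Uniform(0, censorTmax);
#' observed time = min(T, C), event = (T <= C).
#'
#' @param cspec a [CohortSpec-class].
#' @return data.frame ground-truth table: patient_id, mgmt, param, per-axis
#'   semi-axes, textureLength, seed, loghazard, time, event.
#' @export
simulateOutcomes <- function(cspec) {
    stopifnot(is(cspec, "CohortSpec"))
    validObject(cspec)
    set.seed(cspec@seed)
    n <- cspec@n
    mgmt <- rbinom(n, 1L, cspec@pMethylated)
    param <- runif(n, cspec@paramRange[1], cspec@paramRange[2])
    a <- runif(n, cspec@axesRange[1], cspec@axesRange[2])
    b <- runif(n, cspec@axesRange[1], cspec@axesRange[2])
    cc <- runif(n, cspec@axesRange[1], cspec@axesRange[2])
    tl <- runif(n, cspec@textureRange[1], cspec@textureRange[2])
    thr <- if (is.null(cspec@intThreshold)) mean(cspec@paramRange)
           else cspec@intThreshold
    lp <- cspec@beta0 + cspec@betaMgmt * mgmt + cspec@betaImg * param +
        cspec@betaInteraction * as.numeric(mgmt == 1L & param > thr)
    tt <- rexp(n, rate = exp(lp))
    cens <- runif(n, 0, cspec@censorTmax)
    data.frame(patient_id = sprintf("P%03d", seq_len(n)),
               mgmt = factor(ifelse(mgmt == 1L, "methylated",
                                    "unmethylated"),
                             levels = c("methylated", "unmethylated",
                                        "unknown")),
               param = param, axis_a = a, axis_b = b, axis_c = cc,
               textureLength = tl,
               seed = vapply(seq_len(n), function(i)
                   subSeed(cspec@seed, i), 1L),
               loghazard = lp,
               time = pmin(tt, cens),
               event = tt <= cens,
               stringsAsFactors = FALSE)
}

# PhantomSpec for one row of a ground-truth table.
phantomSpecFor <- function(cspec, row) {
    tpl <- cspec@template
    args <- list(gridSize = tpl@gridSize, spacing = tpl@spacing,
                 axes = c(row$axis_a, row$axis_b, row$axis_c),
                 rimAmplitude = tpl@rimAmplitude, rimWidth = tpl@rimWidth,
                 textureLength = row$textureLength,
                 textureSd = tpl@textureSd, haloWidth = tpl@haloWidth,
                 intensityBase = tpl@intensityBase,
                 tumorContrast = tpl@tumorContrast,
                 haloContrast = tpl@haloContrast, noiseSd = tpl@noiseSd,
                 seed = row$seed)
    args[[cspec@hazardParam]] <- row$param
    do.call(PhantomSpec, args)
}

#' Generate a full synthetic cohort
#'
#' Draws the ground truth with [simulateOutcomes()], builds one phantom
#' study per patient, and optionally writes the cohort through the real
#' I/O path (NIfTI volumes, clinical CSV, ground-truth JSON-like CSV).
#'
#' @param cspec a [CohortSpec-class].
#' @param dir optional output directory; when given, studies and the
#'   clinical table are written there.
#' @param keepStudies logical; return the list of [MRIStudy-class] objects
#'   (set FALSE for large cohorts written to disk).
#' @return list with `truth` (data.frame), `clinical` (data.frame) and
#'   `studies` (list or NULL).
#' @export
makeCohort <- function(cspec, dir = NULL, keepStudies = is.null(dir)) {
    truth <- simulateOutcomes(cspec)
    clinical <- data.frame(patient_id = truth$patient_id,
                           time = truth$time, event = truth$event,
                           mgmt = truth$mgmt, stringsAsFactors = FALSE)
    studies <- if (keepStudies) vector("list", nrow(truth)) else NULL
    for (i in seq_len(nrow(truth))) {
        st <- makePhantom(phantomSpecFor(cspec, truth[i, ]),
                          patientId = truth$patient_id[i])
        if (keepStudies) studies[[i]] <- st
        if (!is.null(dir)) writeStudy(st, dir)
    }
    if (!is.null(dir)) {
        writeClinical(clinical, file.path(dir, "clinical.csv"))
        write.csv(truth, file.path(dir, "ground_truth.csv"),
                  row.names = FALSE)
    }
    if (keepStudies) names(studies) <- truth$patient_id
    list(truth = truth, clinical = clinical, studies = studies)
}

#' Extract features for a whole synthetic cohort
#'
#' Memory-light loop: each phantom is generated, its features extracted,
#' and the volumes discarded. Returns a [RadiomicsExperiment-class] ready
#' for [runTraining()].
#'
#' @param cspec a [CohortSpec-class].
#' @param Q gray levels for the texture matrices (default 128).
#' @param families feature families to extract (default all).
#' @param truth optional precomputed ground-truth table from
#'   [simulateOutcomes()] (must match `cspec`).
#' @return A [RadiomicsExperiment-class] with the ground truth in
#'   `metadata(x)$truth`.
#' @export
extractCohortFeatures <- function(cspec, Q = 128L,
                                  families = radsurvFamilies,
                                  truth = NULL) {
    if (is.null(truth)) truth <- simulateOutcomes(cspec)
    feats <- NULL
    for (i in seq_len(nrow(truth))) {
        st <- makePhantom(phantomSpecFor(cspec, truth[i, ]),
                          patientId = truth$patient_id[i])
        v <- extractFeatures(st, Q = Q, families = families)
        if (is.null(feats))
            feats <- matrix(NA_real_, nrow = length(v),
                            ncol = nrow(truth),
                            dimnames = list(names(v), truth$patient_id))
        feats[, i] <- v
    }
    clinical <- data.frame(patient_id = truth$patient_id,
                           time = truth$time, event = truth$event,
                           mgmt = truth$mgmt, stringsAsFactors = FALSE)
    re <- RadiomicsExperiment(feats, clinical)
    S4Vectors::metadata(re)$truth <- truth
    re
}

#' Redraw survival outcomes for a fixed imaging cohort
#'
#' Conditional-replicate helper: keeps the patients (MGMT status, phantom
#' parameters, hence imaging features) of an existing ground-truth table
#' fixed and redraws only the exponential event times and uniform
#' censoring, optionally under different hazard coefficients. Because the
#' imaging channel is deterministic given the phantom parameters, outcome
#' redraws are the only stochastic ingredient that survival-level
#' replicate studies need.
#'
#' @param truth ground-truth table from [simulateOutcomes()].
#' @param cspec the [CohortSpec-class] supplying the hazard model
#'   (possibly with modified coefficients).
#' @param seed integer seed for the redraw.
#' @return The truth table with recomputed loghazard, time and event.
#' @export
redrawOutcomes <- function(truth, cspec, seed) {
    set.seed(as.integer(seed))
    n <- nrow(truth)
    mgmt <- as.integer(truth$mgmt == "methylated")
    thr <- if (is.null(cspec@intThreshold)) mean(cspec@paramRange)
           else cspec@intThreshold
    lp <- cspec@beta0 + cspec@betaMgmt * mgmt +
        cspec@betaImg * truth$param +
        cspec@betaInteraction * as.numeric(mgmt == 1L & truth$param > thr)
    tt <- rexp(n, rate = exp(lp))
    cens <- runif(n, 0, cspec@censorTmax)
    truth$loghazard <- lp
    truth$time <- pmin(tt, cens)
    truth$event <- tt <= cens
    truth
}
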