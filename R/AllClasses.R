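#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))
setClassUnion("dfOrNULL", c("data.frame", "NULL"))

#' MRIStudy: one patient's co-registered MRI study
#'
#' Container for the three co-registered sequences (T1WI, contrast-enhanced
#' T1WI, FLAIR), the shared binary tumor mask and the voxel spacing in mm.
#' All four volumes must live on an identical grid; the mask must contain at
#' least one foreground voxel and hold only values 0/1.
#'
#' @slot patientId character patient identifier.
#' @slot t1,t1ce,flair 3D numeric arrays (arbitrary intensity units).
#' @slot mask 3D integer array of 0/1, the tumor segmentation shared by all
#'   sequences.
#' @slot spacing numeric length-3 voxel spacing (dx, dy, dz) in mm.
#' @aliases MRIStudy
#' @exportClass MRIStudy
setClass("MRIStudy",
    representation(patientId = "character", t1 = "array", t1ce = "array",
                   flair = "array", mask = "array", spacing = "numeric"))

setValidity("MRIStudy", function(object) {
    d <- dim(object@t1)
    if (length(d) != 3L) return("volumes must be 3D arrays")
    for (nm in c("t1ce", "flair", "mask")) {
        if (!identical(dim(slot(object, nm)), d))
            return(sprintf("volume '%s' does not share the grid of t1", nm))
    }
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
        return("spacing must be three strictly positive values (mm)")
    mv <- unique(as.vector(object@mask))
    if (!all(mv %in% c(0L, 1L, 0, 1)))
        return("mask values must be exactly {0,1}")
    if (sum(object@mask) < 1L)
        return("mask is empty: at least one foreground voxel required")
    TRUE
})

#' Construct an MRIStudy
#'
#' Assembles a study from three sequence volumes and a mask. The mask is
#' binarized at > 0 (idempotent for already-binary masks).
#'
#' @param patientId character identifier.
#' @param t1,t1ce,flair 3D numeric arrays on a common grid.
#' @param mask 3D array; binarized at > 0.
#' @param spacing numeric(3) voxel spacing in mm.
#' @return An [MRIStudy-class] object.
#' @export
MRIStudy <- function(patientId, t1, t1ce, flair, mask, spacing = c(1, 1, 1)) {
    m <- array(as.integer(mask > 0), dim = dim(mask))
    new("MRIStudy", patientId = as.character(patientId),
        t1 = unname(t1), t1ce = unname(t1ce), flair = unname(flair),
        mask = m, spacing = as.numeric(spacing))
}

setMethod("show", "MRIStudy", function(object) {
    d <- dim(object@t1)
    cat("MRIStudy '", object@patientId, "'\n", sep = "")
    cat("  grid: ", paste(d, collapse = " x "),
        " voxels, spacing ", paste(signif(object@spacing, 3), collapse = "/"),
        " mm\n", sep = "")
    cat("  mask: ", sum(object@mask), " voxels (",
        signif(100 * sum(object@mask) / prod(d), 3), "% of grid)\n", sep = "")
})

#' QuantizedVolume: gray-level quantized masked volume
#'
#' Result of rescaling masked intensities to Q discrete gray levels. Inside
#' the mask levels lie in 1..Q; outside the mask levels are NA.
#'
#' @slot levels 3D integer array, NA outside the mask.
#' @slot Q integer number of gray levels.
#' @slot vmin,vmax numeric intensity range inside the mask.
#' @slot mask 3D integer 0/1 array.
#' @exportClass QuantizedVolume
setClass("QuantizedVolume",
    representation(levels = "array", Q = "integer", vmin = "numeric",
                   vmax = "numeric", mask = "array"))

setValidity("QuantizedVolume", function(object) {
    lv <- object@levels[object@mask > 0]
    if (anyNA(lv)) return("levels inside the mask must not be NA")
    if (min(lv) < 1L || max(lv) > object@Q)
        return("levels inside the mask must lie in [1, Q]")
    if (object@vmax <= object@vmin) return("vmax must exceed vmin")
    TRUE
})

setMethod("show", "QuantizedVolume", function(object) {
    cat("QuantizedVolume: Q = ", object@Q, ", masked intensity range [",
        signif(object@vmin, 5), ", ", signif(object@vmax, 5), "]\n", sep = "")
})

#' GaborEdgeMap: magnitude response of one Gabor filter
#'
#' Magnitude (quadrature-pair) response of a 2D Gabor filter applied
#' slice-wise to one MRI sequence. `theta` is the carrier orientation in
#' degrees from the image x-axis; `frequency` is the label "2" or "2sqrt2"
#' (carrier wavelengths of 2 and 2*sqrt(2) pixels).
#'
#' @slot response 3D numeric array of non-negative magnitudes.
#' @slot theta numeric orientation in degrees (0, 30, 45 or 90).
#' @slot frequency character frequency label ("2" or "2sqrt2").
#' @slot wavelength numeric carrier wavelength in pixels.
#' @slot sequence character sequence name ("T1WI", "T1WI_CE" or "FLAIR").
#' @exportClass GaborEdgeMap
setClass("GaborEdgeMap",
    representation(response = "array", theta = "numeric",
                   frequency = "character", wavelength = "numeric",
                   sequence = "character"))

setValidity("GaborEdgeMap", function(object) {
    if (min(object@response) < 0) return("responses must be non-negative")
    if (!object@theta %in% c(0, 30, 45, 90))
        return("theta must be one of 0, 30, 45, 90 degrees")
    if (!object@frequency %in% c("2", "2sqrt2"))
        return("frequency label must be '2' or '2sqrt2'")
    if (!object@sequence %in% c("T1WI", "T1WI_CE", "FLAIR"))
        return("sequence must be T1WI, T1WI_CE or FLAIR")
    TRUE
})

setMethod("show", "GaborEdgeMap", function(object) {
    cat("GaborEdgeMap ", object@sequence, " theta=", object@theta,
        " f=", object@frequency, " (wavelength ",
        signif(object@wavelength, 4), " px)\n", sep = "")
})

#' RadiomicsExperiment: cohort feature table with clinical annotation
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' whose single assay holds the feature-by-patient matrix. `rowData` carries
#' the catalog annotation (sequence, family, feature); `colData` must carry
#' `time` (months, > 0), `event` (logical) and `mgmt`
#' (methylated/unmethylated/unknown).
#'
#' @exportClass RadiomicsExperiment
setClass("RadiomicsExperiment", contains = "SummarizedExperiment")

setValidity("RadiomicsExperiment", function(object) {
    cd <- SummarizedExperiment::colData(object)
    need <- c("time", "event", "mgmt")
    if (!all(need %in% colnames(cd)))
        return("colData must contain 'time', 'event' and 'mgmt'")
    if (any(cd$time <= 0)) return("survival times must be > 0")
    if (!all(as.character(cd$mgmt) %in%
             c("methylated", "unmethylated", "unknown")))
        return("mgmt must be methylated/unmethylated/unknown")
    if (is.null(rownames(object))) return("feature rownames are required")
    TRUE
})

#' SelectionResult: LASSO feature-selection outcome
#'
#' @slot lambdaGrid numeric penalty path.
#' @slot cvDeviance numeric mean cross-validated deviance per lambda.
#' @slot chosenLambda numeric penalty chosen by the tuning rule
#'   (one-SE by default).
#' @slot selected data.frame with columns `feature`, `coefficient`
#'   (non-zero, decreasing absolute value).
#' @exportClass SelectionResult
setClass("SelectionResult",
    representation(lambdaGrid = "numeric", cvDeviance = "numeric",
                   chosenLambda = "numeric", selected = "data.frame"))

setValidity("SelectionResult", function(object) {
    if (nrow(object@selected) > 0 && any(object@selected$coefficient == 0))
        return("selected features must have non-zero coefficients")
    TRUE
})

setMethod("show", "SelectionResult", function(object) {
    cat("SelectionResult: lambda = ", signif(object@chosenLambda, 4),
        ", ", nrow(object@selected), " feature(s) selected\n", sep = "")
    if (nrow(object@selected) > 0)
        print(object@selected, row.names = FALSE)
})

#' StratumResult: one dichotomized survival comparison
#'
#' Holds the cutoff, group assignments (`group1` means value >= cutoff for
#' feature stratifications; for the MGMT combination, `group1` means
#' methylated with feature < cutoff), the fitted Kaplan-Meier curves, the
#' per-group median survivals with 95% CIs, and raw plus
#' Bonferroni-adjusted log-rank p-values.
#'
#' @slot feature character label of the dichotomizing variable.
#' @slot cutoff numeric cutoff value (NA for MGMT-only stratification).
#' @slot orientation character description of group1.
#' @slot groups factor of group labels, one per patient analyzed.
#' @slot fit the `survfit` object for the two groups.
#' @slot medians data.frame: group, n, median, lcl, ucl (months).
#' @slot logrankP numeric raw log-rank p-value.
#' @slot adjustedP numeric Bonferroni-adjusted p-value.
#' @slot survivalAt data.frame of survival probabilities at a requested
#'   horizon, or NULL.
#' @exportClass StratumResult
setClass("StratumResult",
    representation(feature = "character", cutoff = "numeric",
                   orientation = "character", groups = "factor",
                   fit = "ANY", medians = "data.frame",
                   logrankP = "numeric", adjustedP = "numeric",
                   survivalAt = "dfOrNULL"))

setMethod("show", "StratumResult", function(object) {
    cat("StratumResult '", object@feature, "'", sep = "")
    if (!is.na(object@cutoff))
        cat(" cutoff = ", signif(object@cutoff, 4), sep = "")
    cat("\n  groups: ", paste(sprintf("%s (n=%d)",
        levels(object@groups), tabulate(object@groups)), collapse = ", "),
        "\n", sep = "")
    print(object@medians, row.names = FALSE)
    cat("  log-rank p = ", signif(object@logrankP, 3),
        ", Bonferroni-adjusted p = ", signif(object@adjustedP, 3),
        "\n", sep = "")
})

#' PhantomSpec: generative parameters for one synthetic study
#'
#' An ellipsoidal tumor with rim enhancement of controllable edge width on
#' the contrast-enhanced channel, smoothed-noise interior texture of
#' controllable correlation length, an edema-like halo on FLAIR, and
#' additive Gaussian noise.
#'
#' @slot gridSize integer(3) voxels per axis.
#' @slot spacing numeric(3) mm.
#' @slot axes numeric(3) ellipsoid semi-axes (a, b, c) in mm.
#' @slot rimAmplitude numeric intensity of the enhancing rim (T1WI_CE).
#' @slot rimWidth numeric rim edge width sigma_edge in mm (>= 0); small
#'   values give a thin sharp ring, large values a diffuse rim.
#' @slot textureLength numeric interior texture correlation length in mm.
#' @slot textureSd numeric marginal SD of the interior texture field.
#' @slot haloWidth numeric FLAIR halo width in mm added to the semi-axes.
#' @slot intensityBase,tumorContrast,haloContrast numeric intensity offsets.
#' @slot noiseSd numeric additive white-noise SD.
#' @slot seed integer RNG seed.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
    representation(gridSize = "integer", spacing = "numeric",
                   axes = "numeric", rimAmplitude = "numeric",
                   rimWidth = "numeric", textureLength = "numeric",
                   textureSd = "numeric", haloWidth = "numeric",
                   intensityBase = "numeric", tumorContrast = "numeric",
                   haloContrast = "numeric", noiseSd = "numeric",
                   seed = "integer"),
    prototype(gridSize = c(48L, 48L, 48L), spacing = c(1, 1, 1),
              axes = c(12, 10, 9), rimAmplitude = 80, rimWidth = 1,
              textureLength = 1.5, textureSd = 15, haloWidth = 3,
              intensityBase = 100, tumorContrast = 20, haloContrast = 30,
              noiseSd = 5, seed = 1L))

setValidity("PhantomSpec", function(object) {
    if (any(object@axes <= 0)) return("semi-axes must be positive")
    if (object@rimWidth < 0) return("rimWidth must be >= 0")
    if (object@textureLength <= 0) return("textureLength must be > 0")
    half <- object@gridSize * object@spacing / 2
    if (any(object@axes + object@haloWidth >= half))
        return("ellipsoid plus halo exceeds the grid")
    TRUE
})

#' Construct a PhantomSpec
#'
#' @param ... slot values overriding the defaults (48^3 grid, 1 mm
#'   isotropic spacing, semi-axes 12/10/9 mm, rim amplitude 80 with
#'   sigma_edge 1 mm, texture correlation length 1.5 mm with SD 15, 3 mm
#'   FLAIR halo, noise SD 5).
#' @return A [PhantomSpec-class] object.
#' @export
PhantomSpec <- function(...) {
    args <- list(...)
    if (!is.null(args$gridSize)) args$gridSize <- as.integer(args$gridSize)
    if (!is.null(args$seed)) args$seed <- as.integer(args$seed)
    do.call(new, c(list(Class = "PhantomSpec"), args))
}

#' CohortSpec: generative parameters for a synthetic cohort
#'
#' Per patient: MGMT ~ Bernoulli(pMethylated); the hazard-linked image
#' parameter (rim edge width sigma_edge by default) ~ Uniform(paramRange);
#' per-patient ellipsoid semi-axes and texture length are also drawn
#' uniformly so shape and texture features vary across the cohort. Event
#' times are exponential with log-hazard
#' beta0 + betaMgmt*MGMT + betaImg*param + betaInteraction*(MGMT and
#' param on its protective side of intThreshold); censoring is
#' Uniform(0, censorTmax) months.
#'
#' @slot n integer cohort size (>= 2).
#' @slot pMethylated numeric probability of MGMT methylation.
#' @slot beta0 numeric baseline log-hazard (per month).
#' @slot betaMgmt,betaImg numeric log-hazard coefficients.
#' @slot betaInteraction numeric extra log-hazard applied only when MGMT is
#'   methylated and the image parameter exceeds `intThreshold` (0 disables).
#' @slot intThreshold numeric threshold for the interaction term, or NULL
#'   for the midpoint of `paramRange`.
#' @slot hazardParam character phantom slot linked to hazard ("rimWidth" or
#'   "textureLength").
#' @slot paramRange numeric(2) uniform range of the hazard-linked parameter.
#' @slot axesRange numeric(2) uniform range for each semi-axis (mm).
#' @slot textureRange numeric(2) uniform range for texture length (mm).
#' @slot censorTmax numeric upper bound of uniform censoring (months).
#' @slot template a [PhantomSpec-class] supplying all other phantom settings.
#' @slot seed integer RNG seed.
#' @exportClass CohortSpec
setClass("CohortSpec",
    representation(n = "integer", pMethylated = "numeric", beta0 = "numeric",
                   betaMgmt = "numeric", betaImg = "numeric",
                   betaInteraction = "numeric",
                   intThreshold = "numericOrNULL", hazardParam = "character",
                   paramRange = "numeric", axesRange = "numeric",
                   textureRange = "numeric", censorTmax = "numeric",
                   template = "PhantomSpec", seed = "integer"),
    prototype(n = 100L, pMethylated = 0.4, beta0 = -0.6,
              betaMgmt = -0.7, betaImg = -1.8, betaInteraction = 0,
              intThreshold = NULL, hazardParam = "rimWidth",
              paramRange = c(0.4, 2.0), axesRange = c(8, 14),
              textureRange = c(0.8, 2.5), censorTmax = 60,
              template = new("PhantomSpec"), seed = 1L))

setValidity("CohortSpec", function(object) {
    if (object@n < 2L) return("cohort size must be >= 2")
    if (object@pMethylated < 0 || object@pMethylated > 1)
        return("pMethylated must be in [0,1]")
    if (object@censorTmax <= 0) return("censorTmax must be > 0")
    if (!object@hazardParam %in% c("rimWidth", "textureLength"))
        return("hazardParam must be 'rimWidth' or 'textureLength'")
    if (diff(object@paramRange) < 0) return("paramRange must be increasing")
    TRUE
})

#' Construct a CohortSpec
#'
#' @param ... slot values overriding the defaults (n = 100, 40% methylated,
#'   baseline log-hazard -0.6, log hazard ratios -0.7 for MGMT and
#'   -1.8 per mm of rim edge width, uniform censoring on 0-60 months).
#' @return A [CohortSpec-class] object.
#' @export
CohortSpec <- function(...) {
    args <- list(...)
    if (!is.null(args$n)) args$n <- as.integer(args$n)
    if (!is.null(args$seed)) args$seed <- as.integer(args$seed)
    do.call(new, c(list(Class = "CohortSpec"), args))
}
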