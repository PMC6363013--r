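radsurvSequences <- c("T1WI", "T1WI_CE", "FLAIR")
radsurvFamilies <- c("histogram", "glcm", "glszm", "gabor", "shape")

#' The canonical 286-feature catalog
#'
#' Fixed, ordered catalog of the features computed per study: 20 intensity
#' histogram features per sequence (unscaled volumes), 26 GLCM and 16 GLSZM
#' features per sequence (quantized volumes), 4 statistics for each of the
#' 24 Gabor edge maps, and 4 shape features -- 3x20 + 3x26 + 3x16 + 96 + 4
#' = 286 named features. Names follow
#' `<sequence|shape>.<family>.<feature>`.
#'
#' @param families subset of feature families to include.
#' @return data.frame with columns name, sequence, family, feature.
#' @examples
#' nrow(featureCatalog())  # 286
#' @export
featureCatalog <- function(families = radsurvFamilies) {
    families <- match.arg(families, radsurvFamilies, several.ok = TRUE)
    rows <- list()
    if ("histogram" %in% families)
        for (sq in radsurvSequences)
            rows[[length(rows) + 1L]] <- data.frame(
                sequence = sq, family = "histogram",
                feature = histogramFeatureNames)
    if ("glcm" %in% families)
        for (sq in radsurvSequences)
            rows[[length(rows) + 1L]] <- data.frame(
                sequence = sq, family = "glcm", feature = glcmFeatureNames)
    if ("glszm" %in% families)
        for (sq in radsurvSequences)
            rows[[length(rows) + 1L]] <- data.frame(
                sequence = sq, family = "glszm", feature = glszmFeatureNames)
    if ("gabor" %in% families)
        for (sq in radsurvSequences)
            for (f in c("2", "2sqrt2"))
                for (th in c(0, 30, 45, 90))
                    rows[[length(rows) + 1L]] <- data.frame(
                        sequence = sq, family = "gabor",
                        feature = sprintf("theta%d_f%s_%s", th, f,
                                          gaborStatNames))
    if ("shape" %in% families)
        rows[[length(rows) + 1L]] <- data.frame(
            sequence = "shape", family = "morphology",
            feature = shapeFeatureNames)
    cat <- do.call(rbind, rows)
    cat$name <- paste(cat$sequence, cat$family, cat$feature, sep = ".")
    cat[, c("name", "sequence", "family", "feature")]
}

#' Extract the radiomic feature vector of one study
#'
#' Computes the full 286-feature catalog (or a family subset): histogram
#' features from the unscaled sequences, GLCM and GLSZM features from the
#' Q-level quantized sequences, the four moment statistics of each of the
#' 24 Gabor edge maps, and the mask shape features. Output order and names
#' match [featureCatalog()]. Degenerate values (zero-variance
#' denominators) are NA.
#'
#' @param study an [MRIStudy-class].
#' @param Q gray levels for quantization (default 128).
#' @param families subset of feature families (default all).
#' @return Named numeric vector (length 286 for the full catalog).
#' @export
extractFeatures <- function(study, Q = 128L, families = radsurvFamilies) {
    stopifnot(is(study, "MRIStudy"))
    families <- match.arg(families, radsurvFamilies, several.ok = TRUE)
    mask <- study@mask
    vals <- list()
    if ("histogram" %in% families)
        for (sq in radsurvSequences) {
            v <- histogramFeatures(getSequence(study, sq), mask)
            names(v) <- paste(sq, "histogram", names(v), sep = ".")
            vals[[length(vals) + 1L]] <- v
        }
    if (any(c("glcm", "glszm") %in% families))
        for (sq in radsurvSequences) {
            q <- quantizeVolume(getSequence(study, sq), mask, Q)
            if ("glcm" %in% families) {
                v <- glcmFeatures(glcmMatrix(q))
                names(v) <- paste(sq, "glcm", names(v), sep = ".")
                vals[[length(vals) + 1L]] <- v
            }
            if ("glszm" %in% families) {
                v <- glszmFeatures(glszmMatrix(q))
                names(v) <- paste(sq, "glszm", names(v), sep = ".")
                vals[[length(vals) + 1L]] <- v
            }
        }
    if ("gabor" %in% families) {
        raw <- gaborRaw(study, radsurvSequences, c(0, 30, 45, 90),
                        c("2", "2sqrt2"), pad = 2L, restrict = "mask")
        maskIdx <- which(mask > 0)
        v <- unlist(lapply(raw, function(r) {
            mo <- popMoments(r$response[maskIdx])
            c(mean = mo$mean, sd = sqrt(mo$m2), skewness = mo$skewness,
              kurtosis = mo$kurtosis)
        }))
        # list names are '<seq>.gabor.theta<t>_f<f>'; stat appended by unlist
        names(v) <- sub("\\.(mean|sd|skewness|kurtosis)$", "_\\1", names(v))
        vals[[length(vals) + 1L]] <- v
    }
    if ("shape" %in% families) {
        v <- shapeFeatures(mask, study@spacing)
        names(v) <- paste("shape", "morphology", names(v), sep = ".")
        vals[[length(vals) + 1L]] <- v
    }
    out <- unlist(vals)
    cat <- featureCatalog(families)
    if (!setequal(names(out), cat$name))
        stop("internal error: extracted names do not match the catalog")
    out[cat$name]
}
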