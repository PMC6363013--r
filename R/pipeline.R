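allowedQ <- c(16L, 32L, 64L, 128L)

#' Training-cohort analysis: select, dichotomize, stratify, combine
#'
#' Runs the discovery workflow on a cohort feature table: standardize the
#' features, select outcome-relevant features by 10-fold cross-validated
#' LASSO on vital status, find each selected feature's Youden-index
#' cutoff, compare survival between the resulting groups (log-rank,
#' Bonferroni-adjusted over the selected features), stratify by MGMT
#' alone, and combine MGMT with each feature significant after adjustment.
#' Cutoffs (optimal and cohort median) are frozen for external validation.
#'
#' @param re a [RadiomicsExperiment-class] for the training cohort.
#' @param folds LASSO cross-validation folds (default 10).
#' @param seed integer seed for fold assignment.
#' @param lambdaRule penalty tuning rule passed to [lassoSelect()].
#' @param alpha significance level on adjusted p-values (default 0.05).
#' @param horizon reporting horizon in months for combined analyses
#'   (default 43).
#' @param outputDir optional directory; when given, the feature table,
#'   the stratification report and the frozen cutoffs are written as CSV.
#' @return list (class `radsurvTraining`) with elements `selection`
#'   ([SelectionResult-class]), `strata` (list of [StratumResult-class]),
#'   `mgmt`, `combined`, `cutoffs` (data.frame feature/optimal/median/
#'   orientation), `significant` (character), `table` (report
#'   data.frame), and `config`.
#' @export
runTraining <- function(re, folds = 10L, seed = 1L,
                        lambdaRule = c("1se", "min"), alpha = 0.05,
                        horizon = 43, outputDir = NULL) {
    lambdaRule <- match.arg(lambdaRule)
    stopifnot(is(re, "RadiomicsExperiment"))
    if (ncol(re) < 2L) stop("cohort must contain at least 2 patients")
    clinical <- clinicalTable(re)
    x <- featureMatrix(re)
    std <- standardizeFeatures(x)
    status <- clinical$event
    sel <- lassoSelect(std$x, status, folds = folds, seed = seed,
                       lambdaRule = lambdaRule)
    feats <- selectedFeatures(sel)$feature
    m <- length(feats)
    strata <- list()
    cutoffs <- data.frame(feature = character(), optimal = numeric(),
                          median = numeric(), orientation = character(),
                          stringsAsFactors = FALSE)
    for (ft in feats) {
        yj <- youdenCutoff(x[, ft], status)
        strata[[ft]] <- stratifyCohort(clinical, x[, ft], yj$cutoff,
                                       feature = ft, nTests = m)
        cutoffs <- rbind(cutoffs, data.frame(
            feature = ft, optimal = yj$cutoff,
            median = median(x[, ft]), orientation = yj$orientation,
            stringsAsFactors = FALSE))
    }
    mgmtRes <- tryCatch(stratifyMgmt(clinical), error = function(e) NULL)
    signif <- feats[vapply(strata, function(s) s@adjustedP, 1) < alpha]
    combined <- list()
    for (ft in signif) {
        ct <- cutoffs$optimal[cutoffs$feature == ft]
        combined[[ft]] <- tryCatch(
            combineMgmt(clinical, x[, ft], ct, feature = ft,
                        horizon = horizon),
            error = function(e) {
                warning("combined MGMT analysis skipped for ", ft, ": ",
                        conditionMessage(e))
                NULL
            })
    }
    combined <- Filter(Negate(is.null), combined)
    out <- list(selection = sel, strata = strata, mgmt = mgmtRes,
                combined = combined, cutoffs = cutoffs,
                significant = signif,
                table = if (length(strata)) strataTable(strata) else NULL,
                config = list(folds = folds, seed = seed,
                              lambdaRule = lambdaRule, alpha = alpha,
                              horizon = horizon,
                              standardization = std[c("center", "scale")]))
    class(out) <- "radsurvTraining"
    if (!is.null(outputDir)) {
        if (!dir.exists(outputDir)) dir.create(outputDir, recursive = TRUE)
        write.csv(data.frame(patient_id = rownames(x), x,
                             check.names = FALSE),
                  file.path(outputDir, "features.csv"), row.names = FALSE)
        if (!is.null(out$table))
            write.csv(out$table, file.path(outputDir, "training_strata.csv"),
                      row.names = FALSE)
        write.csv(cutoffs, file.path(outputDir, "frozen_cutoffs.csv"),
                  row.names = FALSE)
    }
    out
}

#' Frozen-cutoff validation-cohort analysis
#'
#' Applies cutoffs frozen on the training cohort to an independent
#' validation cohort with no re-estimation, restricted to the carried
#' features (by default the training-significant ones); Bonferroni
#' multiplicity equals the number of carried features. MGMT-alone and
#' combined MGMT + feature analyses are repeated with the frozen cutoff.
#'
#' @param re a [RadiomicsExperiment-class] for the validation cohort.
#' @param training result of [runTraining()], or a cutoffs data.frame.
#' @param features character features to carry forward (default: the
#'   training-significant set, else all cutoff rows).
#' @param mode "training_optimal" (default) or "training_median".
#' @param horizon reporting horizon in months (default 43).
#' @param combineFeature feature used for the MGMT combination (default:
#'   first carried feature).
#' @return list (class `radsurvValidation`) with `strata`, `mgmt`,
#'   `combined`, `table`, `mode`.
#' @export
runValidation <- function(re, training, features = NULL,
                          mode = c("training_optimal", "training_median"),
                          horizon = 43, combineFeature = NULL) {
    mode <- match.arg(mode)
    stopifnot(is(re, "RadiomicsExperiment"))
    cutoffs <- if (is.data.frame(training)) training else training$cutoffs
    if (is.null(cutoffs) || nrow(cutoffs) == 0)
        stop("configuration error: no frozen cutoffs supplied")
    if (is.null(features))
        features <- if (!is.data.frame(training) &&
                        length(training$significant) > 0)
            training$significant else cutoffs$feature
    missingFt <- setdiff(features, cutoffs$feature)
    if (length(missingFt) > 0)
        stop("configuration error: no frozen cutoff for ",
             paste(missingFt, collapse = ", "))
    cutoffs <- cutoffs[cutoffs$feature %in% features, , drop = FALSE]
    clinical <- clinicalTable(re)
    x <- featureMatrix(re)
    strata <- validateExternal(clinical, x, cutoffs, mode = mode)
    mgmtRes <- tryCatch(stratifyMgmt(clinical), error = function(e) NULL)
    if (is.null(combineFeature)) combineFeature <- cutoffs$feature[1]
    col <- if (mode == "training_optimal") "optimal" else "median"
    combined <- tryCatch(
        combineMgmt(clinical, x[, combineFeature],
                    cutoffs[[col]][cutoffs$feature == combineFeature],
                    feature = combineFeature, horizon = horizon),
        error = function(e) {
            warning("combined MGMT analysis skipped: ",
                    conditionMessage(e))
            NULL
        })
    out <- list(strata = strata, mgmt = mgmtRes, combined = combined,
                table = strataTable(strata), mode = mode)
    class(out) <- "radsurvValidation"
    out
}

#' Sensitivity of feature selection to the number of gray levels
#'
#' Re-runs extraction and LASSO selection at several quantization settings
#' Q and reports the pairwise Jaccard overlap of the selected feature
#' sets. Only the GLCM/GLSZM blocks depend on Q; histogram, Gabor and
#' shape features are recomputed identically, so their selection status
#' can differ only through the penalty path.
#'
#' @param cspec a [CohortSpec-class] describing the cohort.
#' @param Qs integer vector of gray-level settings, each in
#'   {16, 32, 64, 128}.
#' @param folds,seed,lambdaRule passed to [lassoSelect()].
#' @return list with `selected` (named list of character vectors per Q)
#'   and `jaccard` (matrix of pairwise overlaps).
#' @export
binSensitivity <- function(cspec, Qs = c(32L, 64L, 128L), folds = 10L,
                           seed = 1L, lambdaRule = c("1se", "min")) {
    lambdaRule <- match.arg(lambdaRule)
    Qs <- as.integer(Qs)
    if (length(Qs) < 2L) stop("need at least two Q settings")
    if (!all(Qs %in% allowedQ))
        stop("Q must be one of ", paste(allowedQ, collapse = ", "))
    truth <- simulateOutcomes(cspec)
    common <- extractCohortFeatures(cspec, truth = truth,
                                    families = c("histogram", "gabor",
                                                 "shape"))
    status <- clinicalTable(common)$event
    commonX <- featureMatrix(common)
    selected <- vector("list", length(Qs))
    names(selected) <- paste0("Q", Qs)
    for (i in seq_along(Qs)) {
        tex <- extractCohortFeatures(cspec, Q = Qs[i], truth = truth,
                                     families = c("glcm", "glszm"))
        x <- cbind(commonX, featureMatrix(tex))
        cat <- featureCatalog()
        x <- x[, cat$name[cat$name %in% colnames(x)], drop = FALSE]
        std <- standardizeFeatures(x)
        sel <- lassoSelect(std$x, status, folds = folds, seed = seed,
                           lambdaRule = lambdaRule)
        selected[[i]] <- selectedFeatures(sel)$feature
    }
    k <- length(Qs)
    jac <- matrix(NA_real_, k, k,
                  dimnames = list(names(selected), names(selected)))
    for (i in seq_len(k))
        for (j in seq_len(k)) {
            a <- selected[[i]]
            b <- selected[[j]]
            u <- length(union(a, b))
            jac[i, j] <- if (u == 0) 1 else length(intersect(a, b)) / u
        }
    list(selected = selected, jaccard = jac)
}
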