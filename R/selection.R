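#' Standardize a feature table
#'
#' Centers and scales each feature to mean 0 and population SD 1 (divisor
#' n). Constant features and features with any missing value are excluded
#' from the standardized matrix and reported, not imputed; the retained
#' centers and scales can be applied unchanged to a validation cohort with
#' [applyStandardization()].
#'
#' @param x patients-by-features matrix or [RadiomicsExperiment-class].
#' @return list with `x` (standardized matrix of usable features),
#'   `center`, `scale` (named numeric), `dropped` (character: excluded
#'   feature names).
#' @examples
#' standardizeFeatures(cbind(f = c(1, 2, 3)))$x  # -1.225 0 1.225
#' @export
standardizeFeatures <- function(x) {
    x <- featureMatrix(x)
    hasNA <- apply(x, 2, anyNA)
    ctr <- colMeans(x)
    scl <- sqrt(colMeans(sweep(x, 2, ctr)^2))
    usable <- !hasNA & is.finite(scl) & scl > 0
    if (any(!usable))
        warning("excluding ", sum(!usable),
                " constant or incomplete feature(s) from selection")
    xs <- sweep(sweep(x[, usable, drop = FALSE], 2, ctr[usable]), 2,
                scl[usable], "/")
    list(x = xs, center = ctr[usable], scale = scl[usable],
         dropped = colnames(x)[!usable])
}

#' Apply frozen standardization parameters
#'
#' @param x patients-by-features matrix or [RadiomicsExperiment-class].
#' @param center,scale named numerics from [standardizeFeatures()].
#' @return Standardized matrix restricted to the frozen features.
#' @export
applyStandardization <- function(x, center, scale) {
    x <- featureMatrix(x)
    feats <- names(center)
    if (!all(feats %in% colnames(x)))
        stop("validation matrix lacks frozen feature(s)")
    sweep(sweep(x[, feats, drop = FALSE], 2, center), 2, scale, "/")
}

#' LASSO feature selection on vital status
#'
#' Fits an L1-penalized (elastic net with mixing parameter 1) logistic
#' regression of end-of-follow-up vital status on the standardized
#' features, tunes the penalty by 10-fold cross-validated deviance, and
#' returns the features with non-zero coefficients at the chosen lambda,
#' ordered by decreasing absolute coefficient. By default the penalty is
#' the largest lambda within one standard error of the cross-validated
#' deviance minimum ("1se"): it yields small, stable selected sets whose
#' identity is robust to irrelevant perturbations such as the gray-level
#' setting of the texture blocks, whereas the raw deviance minimizer
#' ("min", also available) admits many near-zero stragglers.
#'
#' @param x standardized patients-by-features matrix (no missing values),
#'   or a [RadiomicsExperiment-class] (standardized internally).
#' @param status binary outcome, TRUE/1 = dead; taken from `colData` for a
#'   RadiomicsExperiment.
#' @param folds number of cross-validation folds (default 10).
#' @param seed integer seed for fold assignment.
#' @param lambdaRule "1se" (default) or "min".
#' @return A [SelectionResult-class].
#' @export
lassoSelect <- function(x, status = NULL, folds = 10L, seed = 1L,
                        lambdaRule = c("1se", "min")) {
    lambdaRule <- match.arg(lambdaRule)
    if (is(x, "RadiomicsExperiment")) {
        if (is.null(status))
            status <- SummarizedExperiment::colData(x)$event
        x <- standardizeFeatures(x)$x
    }
    status <- as.integer(as.logical(status))
    if (length(unique(status)) < 2L)
        stop("both vital-status classes must be present")
    if (anyNA(x)) stop("missing values in feature matrix")
    set.seed(as.integer(seed))
    cv <- glmnet::cv.glmnet(x, status, family = "binomial", alpha = 1,
                            nfolds = folds, type.measure = "deviance",
                            standardize = FALSE)
    s <- if (lambdaRule == "1se") "lambda.1se" else "lambda.min"
    co <- as.matrix(stats::coef(cv, s = s))[-1, 1]
    # coefficients below the solver's convergence scale are numerical zeros
    nz <- co[abs(co) > 1e-10]
    sel <- data.frame(feature = names(nz), coefficient = unname(nz),
                      stringsAsFactors = FALSE)
    sel <- sel[order(-abs(sel$coefficient)), , drop = FALSE]
    rownames(sel) <- NULL
    new("SelectionResult", lambdaGrid = cv$lambda, cvDeviance = cv$cvm,
        chosenLambda = cv[[s]], selected = sel)
}

#' Youden-index optimal cutpoint
#'
#' Maximizes J = sensitivity + specificity - 1 over all midpoints between
#' consecutive sorted unique feature values, considering both orientations
#' (high values predict status 1, or low values do). Ties are broken
#' toward the smaller cutoff.
#'
#' @param values numeric feature values.
#' @param status binary outcome (TRUE/1 = positive class).
#' @return list with `cutoff`, `orientation` ("ge" if values >= cutoff
#'   predict the positive class, else "lt"), and `J`.
#' @examples
#' youdenCutoff(c(1, 2, 3, 4), c(0, 0, 1, 1))  # cutoff 2.5, J = 1
#' @export
youdenCutoff <- function(values, status) {
    status <- as.logical(status)
    if (length(unique(status)) < 2L)
        stop("both classes must be present")
    u <- sort(unique(values))
    if (length(u) < 2L) stop("constant feature: no cutpoint exists")
    cand <- (u[-1] + u[-length(u)]) / 2
    n1 <- sum(status)
    n0 <- sum(!status)
    best <- list(cutoff = NA_real_, orientation = "ge", J = -Inf)
    for (ct in cand) {
        sens <- sum(values >= ct & status) / n1
        spec <- sum(values < ct & !status) / n0
        jge <- sens + spec - 1
        j <- abs(jge)
        if (j > best$J + 1e-12) {
            best <- list(cutoff = ct,
                         orientation = if (jge >= 0) "ge" else "lt",
                         J = j)
        }
    }
    best
}
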