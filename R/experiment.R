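#' Construct a RadiomicsExperiment
#'
#' Bundles a feature-by-patient matrix with the clinical table into a
#' [RadiomicsExperiment-class]. Columns of `features` are matched to
#' `clinical$patient_id`.
#'
#' @param features numeric matrix, features in rows, patients in columns
#'   (rownames = catalog names, colnames = patient ids).
#' @param clinical data.frame with patient_id, time, event, mgmt (see
#'   [loadClinical()]).
#' @param catalog optional catalog data.frame used for `rowData`; matched
#'   by feature name against [featureCatalog()] when NULL.
#' @return A [RadiomicsExperiment-class].
#' @export
RadiomicsExperiment <- function(features, clinical, catalog = NULL) {
    stopifnot(is.matrix(features), !is.null(rownames(features)))
    if (is.null(colnames(features)))
        colnames(features) <- clinical$patient_id
    m <- match(colnames(features), clinical$patient_id)
    if (anyNA(m)) stop("patients in feature matrix missing from clinical")
    cl <- clinical[m, , drop = FALSE]
    if (is.null(catalog)) {
        full <- featureCatalog()
        catalog <- full[match(rownames(features), full$name), , drop = FALSE]
    }
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(features = features),
        rowData = S4Vectors::DataFrame(catalog, row.names = rownames(features)),
        colData = S4Vectors::DataFrame(
            time = cl$time, event = as.logical(cl$event),
            mgmt = factor(as.character(cl$mgmt),
                          levels = c("methylated", "unmethylated", "unknown")),
            row.names = cl$patient_id))
    new("RadiomicsExperiment", se)
}

#' Feature matrix in patients-by-features orientation
#'
#' @param x a [RadiomicsExperiment-class] or a matrix already in
#'   patients-by-features orientation.
#' @return Numeric matrix, one row per patient.
#' @export
featureMatrix <- function(x) {
    if (is(x, "RadiomicsExperiment"))
        return(t(SummarizedExperiment::assay(x, "features")))
    stopifnot(is.matrix(x))
    x
}

#' Clinical table of a RadiomicsExperiment
#'
#' @param x a [RadiomicsExperiment-class].
#' @return data.frame with patient_id, time, event, mgmt.
#' @export
clinicalTable <- function(x) {
    stopifnot(is(x, "RadiomicsExperiment"))
    cd <- SummarizedExperiment::colData(x)
    data.frame(patient_id = rownames(cd), time = cd$time,
               event = cd$event, mgmt = cd$mgmt,
               stringsAsFactors = FALSE)
}
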