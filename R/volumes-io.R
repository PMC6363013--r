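#' Load a co-registered MRI study from NIfTI files
#'
#' Reads the three sequences and the shared tumor mask, binarizes the mask
#' at > 0, and verifies the geometric contract: all four volumes must share
#' identical dimensions and voxel spacing. Inputs are assumed already
#' co-registered; only grid identity is verified here.
#'
#' @param t1,t1ce,flair,mask paths to NIfTI (.nii/.nii.gz) volumes.
#' @param id character patient identifier.
#' @return An [MRIStudy-class] object.
#' @examples
#' spec <- PhantomSpec(gridSize = c(24, 24, 24), axes = c(6, 5, 5))
#' study <- makePhantom(spec)
#' dir <- tempfile(); dir.create(dir)
#' paths <- writeStudy(study, dir)
#' study2 <- loadStudy(paths["t1"], paths["t1ce"], paths["flair"],
#'                     paths["mask"], id = "demo")
#' @export
loadStudy <- function(t1, t1ce, flair, mask, id) {
    paths <- c(t1 = unname(t1), t1ce = unname(t1ce),
               flair = unname(flair), mask = unname(mask))
    vols <- lapply(paths, function(p) {
        if (!file.exists(p)) stop("file not found: ", p)
        RNifti::readNifti(p)
    })
    refDim <- dim(vols$t1)
    refSp <- RNifti::pixdim(vols$t1)
    for (nm in names(vols)) {
        if (!identical(dim(vols[[nm]]), refDim))
            stop("geometry error: volume '", nm, "' has dimensions ",
                 paste(dim(vols[[nm]]), collapse = "x"),
                 " but t1 has ", paste(refDim, collapse = "x"))
        if (max(abs(RNifti::pixdim(vols[[nm]]) - refSp)) > 1e-4)
            stop("geometry error: volume '", nm,
                 "' has voxel spacing differing from t1")
    }
    m <- array(as.vector(vols$mask), dim = refDim)
    if (!any(m > 0)) stop("empty-mask error: mask '", mask,
                          "' contains no foreground voxels")
    MRIStudy(patientId = id,
             t1 = array(as.vector(vols$t1), dim = refDim),
             t1ce = array(as.vector(vols$t1ce), dim = refDim),
             flair = array(as.vector(vols$flair), dim = refDim),
             mask = m, spacing = as.numeric(refSp[1:3]))
}

#' Write a study's volumes to NIfTI files
#'
#' @param study an [MRIStudy-class].
#' @param dir output directory (created if needed).
#' @return Named character vector of the four file paths written.
#' @export
writeStudy <- function(study, dir) {
    stopifnot(is(study, "MRIStudy"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    sp <- study@spacing
    out <- c(t1 = "t1", t1ce = "t1ce", flair = "flair", mask = "mask")
    paths <- file.path(dir, paste0(study@patientId, "_", out, ".nii.gz"))
    names(paths) <- names(out)
    vols <- list(t1 = study@t1, t1ce = study@t1ce, flair = study@flair,
                 mask = study@mask)
    for (nm in names(vols)) {
        img <- RNifti::asNifti(vols[[nm]], pixdim = sp)
        RNifti::writeNifti(img, paths[[nm]])
    }
    paths
}

#' Load a clinical survival table from CSV
#'
#' Expects columns `patient_id`, `time`, `event`, `mgmt` (header row
#' required). Survival times are months; `event` is 1/0 or TRUE/FALSE
#' (TRUE = death observed); blank or unrecognized MGMT entries map to
#' "unknown". With `daysToMonths = TRUE`, times are divided by 30.44.
#'
#' @param path CSV file path.
#' @param daysToMonths logical; convert day-scale times to months.
#' @return data.frame with columns patient_id (character), time (numeric,
#'   months), event (logical), mgmt (factor
#'   methylated/unmethylated/unknown).
#' @export
loadClinical <- function(path, daysToMonths = FALSE) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("patient_id", "time", "event", "mgmt")
    missingCols <- setdiff(need, names(df))
    if (length(missingCols) > 0)
        stop("clinical CSV lacks column(s): ",
             paste(missingCols, collapse = ", "))
    time <- as.numeric(df$time)
    if (daysToMonths) time <- time / 30.44
    bad <- which(!is.finite(time) | time <= 0)
    if (length(bad) > 0)
        stop("validation error: non-positive or missing survival time in ",
             "row(s) ", paste(bad, collapse = ", "))
    mg <- tolower(trimws(as.character(df$mgmt)))
    mg[is.na(mg) | !(mg %in% c("methylated", "unmethylated"))] <- "unknown"
    ev <- df$event
    if (is.character(ev)) {
        ev <- tolower(trimws(ev)) %in% c("1", "true", "t", "yes", "dead")
    } else {
        ev <- as.numeric(ev) != 0
    }
    data.frame(patient_id = as.character(df$patient_id),
               time = time,
               event = ev,
               mgmt = factor(mg, levels = c("methylated", "unmethylated",
                                            "unknown")),
               stringsAsFactors = FALSE)
}

#' Write a clinical survival table to CSV
#'
#' @param clinical data.frame as returned by [loadClinical()].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeClinical <- function(clinical, path) {
    out <- data.frame(patient_id = clinical$patient_id,
                      time = clinical$time,
                      event = as.integer(clinical$event),
                      mgmt = as.character(clinical$mgmt))
    write.csv(out, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
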