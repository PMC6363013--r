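#' @name accessors
#' @title Accessors for RadSurv objects
#' @description Small accessor generics for the S4 containers: patient
#'   identifier, voxel spacing, tumor mask, a named sequence volume, the
#'   quantized gray levels, and the table of LASSO-selected features.
#' @param x an object.
#' @param sequence one of "T1WI", "T1WI_CE", "FLAIR".
#' @return `patientId`: character; `voxelSpacing`: numeric(3);
#'   `tumorMask`: 3D 0/1 integer array; `getSequence`: 3D numeric array;
#'   `grayLevels`: 3D integer array (NA outside mask); `selectedFeatures`:
#'   data.frame of features and coefficients.
NULL

#' @rdname accessors
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("tumorMask", function(x) standardGeneric("tumorMask"))
#' @rdname accessors
#' @export
setGeneric("getSequence", function(x, sequence) standardGeneric("getSequence"))
#' @rdname accessors
#' @export
setGeneric("grayLevels", function(x) standardGeneric("grayLevels"))
#' @rdname accessors
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' @rdname accessors
setMethod("patientId", "MRIStudy", function(x) x@patientId)
#' @rdname accessors
setMethod("voxelSpacing", "MRIStudy", function(x) x@spacing)
#' @rdname accessors
setMethod("tumorMask", "MRIStudy", function(x) x@mask)
#' @rdname accessors
setMethod("getSequence", "MRIStudy", function(x, sequence) {
    sequence <- match.arg(sequence, c("T1WI", "T1WI_CE", "FLAIR"))
    switch(sequence, T1WI = x@t1, T1WI_CE = x@t1ce, FLAIR = x@flair)
})
#' @rdname accessors
setMethod("grayLevels", "QuantizedVolume", function(x) x@levels)
#' @rdname accessors
setMethod("selectedFeatures", "SelectionResult", function(x) x@selected)
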