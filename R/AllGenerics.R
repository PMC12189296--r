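#' @include AllClasses.R
NULL

#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))

#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))

#' @export
setGeneric("getSlice", function(x, i) standardGeneric("getSlice"))

#' @export
setGeneric("stackSlices", function(x) standardGeneric("stackSlices"))

#' @export
setGeneric("pixelSpacing", function(x) standardGeneric("pixelSpacing"))

#' @export
setGeneric("sliceIds", function(x) standardGeneric("sliceIds"))

#' @export
setGeneric("fgSeed", function(x) standardGeneric("fgSeed"))

#' @export
setGeneric("bgSeed", function(x) standardGeneric("bgSeed"))

#' @export
setGeneric("probValues", function(x) standardGeneric("probValues"))

#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @export
setGeneric("nPasses", function(x) standardGeneric("nPasses"))

#' @export
setGeneric("diceTrace", function(x) standardGeneric("diceTrace"))

#' @export
setGeneric("ensembleMask", function(x) standardGeneric("ensembleMask"))

#' @export
setGeneric("perSliceMasks", function(x) standardGeneric("perSliceMasks"))
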