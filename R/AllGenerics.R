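#' @include AllClasses.R
NULL

#' @export
setGeneric("frameImage", function(x) standardGeneric("frameImage"))
#' @export
setGeneric("frameMask", function(x) standardGeneric("frameMask"))
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))
#' @export
setGeneric("originalMask", function(x) standardGeneric("originalMask"))
#' @export
setGeneric("degradedMask", function(x) standardGeneric("degradedMask"))
#' @export
setGeneric("trueIoU", function(x) standardGeneric("trueIoU"))
#' @export
setGeneric("appliedSteps", function(x) standardGeneric("appliedSteps"))
#' @export
setGeneric("nRaters", function(x) standardGeneric("nRaters"))
#' @export
setGeneric("nImages", function(x) standardGeneric("nImages"))
#' @export
setGeneric("nRounds", function(x) standardGeneric("nRounds"))
#' @export
setGeneric("raterMask", function(x, i, k, r) standardGeneric("raterMask"))
#' @export
setGeneric("predictedIoU", function(x) standardGeneric("predictedIoU"))
#' @export
setGeneric("frameClass", function(x) standardGeneric("frameClass"))
#' @export
setGeneric("modelLayers", function(x) standardGeneric("modelLayers"))
#' @export
setGeneric("headLayers", function(x) standardGeneric("headLayers"))
#' @export
setGeneric("trainHistory", function(x) standardGeneric("trainHistory"))
#' @export
setGeneric("nParameters", function(x) standardGeneric("nParameters"))
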