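## Accessor generics. Kept to the slots users actually consume downstream;
## everything else is reachable through the class documentation.

#' @rdname OpticalConfig
#' @param object,x An object.
#' @export
setGeneric("wavelength", function(object) standardGeneric("wavelength"))

#' @rdname OpticalConfig
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' @rdname OpticalConfig
#' @export
setGeneric("dopplerWindow", function(object) standardGeneric("dopplerWindow"))

#' @rdname OpticalConfig
#' @export
setGeneric("framesPerAcquisition",
           function(object) standardGeneric("framesPerAcquisition"))

#' @rdname PowerSpectrum-accessors
#' @param object An object.
#' @export
setGeneric("frequencies", function(object) standardGeneric("frequencies"))

#' @rdname PowerSpectrum-accessors
#' @export
setGeneric("spectralPower", function(object) standardGeneric("spectralPower"))

#' @rdname PowerSpectrum-accessors
#' @export
setGeneric("channelLabel", function(object) standardGeneric("channelLabel"))

#' @rdname CutoffResult-accessors
#' @param object An object.
#' @export
setGeneric("cutoffHz", function(object) standardGeneric("cutoffHz"))

#' @rdname CutoffResult-accessors
#' @export
setGeneric("qualityFlag", function(object) standardGeneric("qualityFlag"))

#' @rdname velocity-accessors
#' @param object An object.
#' @export
setGeneric("vmax", function(object) standardGeneric("vmax"))

#' @rdname flow-accessors
#' @param object An object.
#' @export
setGeneric("meanFlowUlMin", function(object) standardGeneric("meanFlowUlMin"))

#' @rdname flow-accessors
#' @export
setGeneric("perFrame", function(object) standardGeneric("perFrame"))

#' @rdname diameter-accessors
#' @param object An object.
#' @export
setGeneric("diameterPx", function(object) standardGeneric("diameterPx"))

#' @rdname diameter-accessors
#' @export
setGeneric("diameterUm", function(object) standardGeneric("diameterUm"))

#' @rdname diameter-accessors
#' @export
setGeneric("qcStatus", function(object) standardGeneric("qcStatus"))

#' @rdname BifurcationResult-accessors
#' @param object An object.
#' @export
setGeneric("deltaFRel", function(object) standardGeneric("deltaFRel"))
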