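#' @rdname MicroscopyImage-class
#' @param object,x a \linkS4class{MicroscopyImage}
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @rdname MicroscopyImage-class
#' @export
setGeneric("sourceDtype", function(object) standardGeneric("sourceDtype"))

#' @rdname MicroscopyImage-class
#' @export
setGeneric("sourceRange", function(object) standardGeneric("sourceRange"))

#' @rdname MicroscopyImage-class
#' @export
setGeneric("isNormalized", function(object) standardGeneric("isNormalized"))

#' @rdname NoisePair-class
#' @param object a \linkS4class{NoisePair}
#' @export
setGeneric("pairA", function(object) standardGeneric("pairA"))

#' @rdname NoisePair-class
#' @export
setGeneric("pairB", function(object) standardGeneric("pairB"))

#' @rdname NoisePair-class
#' @export
setGeneric("noiseField", function(object) standardGeneric("noiseField"))

#' @rdname NoisePair-class
#' @export
setGeneric("isFiltered", function(object) standardGeneric("isFiltered"))

#' @rdname DenoiserModel-class
#' @param object a \linkS4class{DenoiserModel}
#' @export
setGeneric("modelWeights", function(object) standardGeneric("modelWeights"))

#' @rdname DenoiserModel-class
#' @export
setGeneric("modelDepth", function(object) standardGeneric("modelDepth"))

#' @rdname DenoiserModel-class
#' @export
setGeneric("baseChannels", function(object) standardGeneric("baseChannels"))

#' @rdname DenoiserModel-class
#' @export
setGeneric("nParameters", function(object) standardGeneric("nParameters"))

#' Apply a trained denoiser to a frame
#'
#' @param model a \linkS4class{DenoiserModel}
#' @param img a normalized \linkS4class{MicroscopyImage} (or numeric matrix in
#'   \eqn{[0, 1]})
#' @return a \linkS4class{MicroscopyImage} of the same shape with pixels in
#'   (0, 1)
#' @export
setGeneric("denoise", function(model, img) standardGeneric("denoise"))

#' @rdname TrainingHistory-class
#' @param object a \linkS4class{TrainingHistory}
#' @export
setGeneric("lossTrace", function(object) standardGeneric("lossTrace"))

#' @rdname FRCCurve-class
#' @param object an \linkS4class{FRCCurve}
#' @export
setGeneric("frcCutoff", function(object) standardGeneric("frcCutoff"))

#' @rdname QualityReport-class
#' @param object a \linkS4class{QualityReport}
#' @export
setGeneric("reportMetrics", function(object) standardGeneric("reportMetrics"))
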