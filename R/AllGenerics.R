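#' @rdname MCTDataset-accessors
#' @export
setGeneric("mctVolumes", function(x) standardGeneric("mctVolumes"))

#' @rdname MCTDataset-accessors
#' @export
setGeneric("modelCovariates", function(x) standardGeneric("modelCovariates"))

#' @rdname MCTDataset-accessors
#' @export
setGeneric("expressionMatrix", function(x) standardGeneric("expressionMatrix"))

#' @rdname MCTDataset-accessors
#' @export
setGeneric("modelIds", function(x) standardGeneric("modelIds"))

#' @rdname MCTDataset-accessors
#' @export
setGeneric("growthCurves",
           function(x, arm = NULL, model = NULL) standardGeneric("growthCurves"))

#' @rdname fit-accessors
#' @export
setGeneric("fixedEffects", function(x) standardGeneric("fixedEffects"))

#' @rdname fit-accessors
#' @export
setGeneric("hazardRatio", function(x) standardGeneric("hazardRatio"))

#' @rdname fit-accessors
#' @export
setGeneric("frailtyEstimates", function(x) standardGeneric("frailtyEstimates"))
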