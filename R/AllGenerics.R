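#' @rdname ensembleModels
#' @export
setGeneric("ensembleModels", function(x) standardGeneric("ensembleModels"))

#' @rdname modelWeights
#' @export
setGeneric("modelWeights", function(x) standardGeneric("modelWeights"))

#' @rdname trainingAUC
#' @export
setGeneric("trainingAUC", function(x) standardGeneric("trainingAUC"))

#' @rdname frameTimes
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' @rdname foldChanges
#' @export
setGeneric("foldChanges", function(x) standardGeneric("foldChanges"))

#' @rdname clusterLabels
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname predictProb
#' @export
setGeneric("predictProb", function(model, x) standardGeneric("predictProb"))
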