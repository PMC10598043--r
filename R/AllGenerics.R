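#' @rdname otuCounts
#' @export
setGeneric("otuCounts", function(x, ...) standardGeneric("otuCounts"))

#' @rdname relativeAbundance
#' @export
setGeneric("relativeAbundance", function(x, ...) standardGeneric("relativeAbundance"))

#' @rdname sampleData
#' @export
setGeneric("sampleData", function(x, ...) standardGeneric("sampleData"))

#' @rdname classificationTable
#' @export
setGeneric("classificationTable", function(x, ...) standardGeneric("classificationTable"))

#' @rdname subgroupLabels
#' @export
setGeneric("subgroupLabels", function(x, ...) standardGeneric("subgroupLabels"))

#' @rdname pValue
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname statistic
#' @export
setGeneric("statistic", function(x) standardGeneric("statistic"))

#' @rdname ordinationScores
#' @export
setGeneric("ordinationScores", function(x, ...) standardGeneric("ordinationScores"))
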