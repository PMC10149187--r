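#' @export
setGeneric("nRows", function(x) standardGeneric("nRows"))

#' @export
setGeneric("columnNames", function(x) standardGeneric("columnNames"))

#' @export
setGeneric("markerColumn", function(x, name) standardGeneric("markerColumn"))

#' @export
setGeneric("columnRoles", function(x) standardGeneric("columnRoles"))

#' @export
setGeneric("columnRoles<-", function(x, value) standardGeneric("columnRoles<-"))

#' @export
setGeneric("selectRows", function(x, i) standardGeneric("selectRows"))

#' @export
setGeneric("memoryFootprint", function(x) standardGeneric("memoryFootprint"))

#' @export
setGeneric("maxLevel", function(x, ...) standardGeneric("maxLevel"))

#' @export
setGeneric("levelDimensions", function(x, level) standardGeneric("levelDimensions"))

#' @export
setGeneric("tileGrid", function(x, level) standardGeneric("tileGrid"))

#' @export
setGeneric("nRecords", function(x) standardGeneric("nRecords"))

#' @export
setGeneric("packedBytes", function(x) standardGeneric("packedBytes"))

#' @export
setGeneric("uploadLog", function(x) standardGeneric("uploadLog"))

#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' @export
setGeneric("featureProperties", function(x, i) standardGeneric("featureProperties"))

#' @export
setGeneric("featureGeometry", function(x, i) standardGeneric("featureGeometry"))

#' @export
setGeneric("graphEdges", function(x) standardGeneric("graphEdges"))

#' @export
setGeneric("categories", function(x) standardGeneric("categories"))

#' @export
setGeneric("enrichmentZ", function(x) standardGeneric("enrichmentZ"))

#' @export
setGeneric("observedCounts", function(x) standardGeneric("observedCounts"))

#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' @export
setGeneric("regionPolygons", function(x) standardGeneric("regionPolygons"))

#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))

#' @export
setGeneric("cellIndices", function(x, a, b) standardGeneric("cellIndices"))
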