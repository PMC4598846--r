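#' @rdname DrugLibrary-class
#' @param object,x A package object.
#' @export
setGeneric("drugIds", function(x) standardGeneric("drugIds"))

#' @rdname DrugLibrary-class
#' @param drug A single drug identifier.
#' @export
setGeneric("targetsOf", function(x, drug) standardGeneric("targetsOf"))

#' @rdname DrugLibrary-class
#' @export
setGeneric("pathwaysOf", function(x, drug) standardGeneric("pathwaysOf"))

#' @rdname DrugLibrary-class
#' @export
setGeneric("degSetOf", function(x, drug) standardGeneric("degSetOf"))

#' @rdname DrugLibrary-class
#' @export
setGeneric("goFingerprints", function(x) standardGeneric("goFingerprints"))

#' @rdname NetworkBundle-class
#' @export
setGeneric("backgroundGraph", function(x) standardGeneric("backgroundGraph"))

#' @rdname NetworkBundle-class
#' @export
setGeneric("cnNodes", function(x) standardGeneric("cnNodes"))

#' @rdname NetworkBundle-class
#' @export
setGeneric("ncnNodes", function(x) standardGeneric("ncnNodes"))

#' @rdname NetworkBundle-class
#' @export
setGeneric("cnGraph", function(x) standardGeneric("cnGraph"))

#' @rdname PairFeatureMatrix-class
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname PairFeatureMatrix-class
#' @export
setGeneric("pairLabels", function(x) standardGeneric("pairLabels"))

#' @rdname PairFeatureMatrix-class
#' @export
setGeneric("pairIds", function(x) standardGeneric("pairIds"))

#' @rdname RankedList-class
#' @export
setGeneric("rankedEntries", function(x) standardGeneric("rankedEntries"))

#' @rdname RankedList-class
#' @export
setGeneric("rankingStage", function(x) standardGeneric("rankingStage"))
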