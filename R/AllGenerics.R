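#' @rdname RegionAtlas-class
#' @param x,object a package object.
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' @rdname RegionAtlas-class
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))

#' @rdname MetabolicCohort-class
#' @export
setGeneric("atlas", function(x) standardGeneric("atlas"))

#' @rdname MetabolicCohort-class
#' @export
setGeneric("suvrValues", function(x) standardGeneric("suvrValues"))

#' @rdname MetabolicCohort-class
#' @export
setGeneric("groupLabels", function(x) standardGeneric("groupLabels"))

#' @rdname MetabolicCohort-class
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))

#' @rdname CorrelationMatrix-class
#' @export
setGeneric("corValues", function(x) standardGeneric("corValues"))

#' @rdname ConnectivityGraph-class
#' @export
setGeneric("graphWeights", function(x) standardGeneric("graphWeights"))
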