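#' @rdname RegionAtlas-class
#' @export
setMethod("regionLabels", "RegionAtlas", function(x) x@regions$label)

#' @rdname RegionAtlas-class
#' @export
setMethod("nRegions", "RegionAtlas", function(x) nrow(x@regions))

#' @rdname RegionAtlas-class
#' @export
setMethod("regionLabels", "ConnectivityGraph", function(x) regionLabels(x@atlas))

#' @rdname MetabolicCohort-class
#' @export
setMethod("atlas", "MetabolicCohort",
    function(x) S4Vectors::metadata(x)$atlas)

#' @rdname ConnectivityGraph-class
#' @export
setMethod("atlas", "ConnectivityGraph", function(x) x@atlas)

#' SUVR value matrix of a cohort (regions x subjects)
#' @rdname MetabolicCohort-class
#' @export
setMethod("suvrValues", "MetabolicCohort",
    function(x) SummarizedExperiment::assay(x, "suvr"))

#' @rdname MetabolicCohort-class
#' @export
setMethod("groupLabels", "MetabolicCohort",
    function(x) as.character(SummarizedExperiment::colData(x)$group))

#' @rdname MetabolicCohort-class
#' @export
setMethod("subjectIds", "MetabolicCohort", function(x) colnames(x))

#' @rdname MetabolicCohort-class
#' @export
setMethod("regionLabels", "MetabolicCohort", function(x) rownames(x))

#' @rdname CorrelationMatrix-class
#' @export
setMethod("corValues", "CorrelationMatrix", function(x) x@values)

#' @rdname ConnectivityGraph-class
#' @export
setMethod("graphWeights", "ConnectivityGraph", function(x) x@weights)

setMethod("show", "RegionAtlas", function(object) {
    r <- object@regions
    cat("RegionAtlas with", nrow(r), "regions",
        sprintf("(%d left, %d right)\n",
            sum(r$hemisphere == "left"), sum(r$hemisphere == "right")))
    cat("  labels:", paste(head(r$label, 6), collapse = ", "),
        if (nrow(r) > 6) "..." else "", "\n")
})

setMethod("show", "MetabolicCohort", function(object) {
    g <- table(groupLabels(object))
    cat("MetabolicCohort:", ncol(object), "subjects x", nrow(object),
        "regions\n")
    cat("  groups:", paste(sprintf("%s (n=%d)", names(g), as.integer(g)),
        collapse = ", "), "\n")
})

setMethod("show", "CorrelationMatrix", function(object) {
    v <- object@values
    off <- v[upper.tri(v)]
    cat(sprintf(
        "CorrelationMatrix for group '%s': %d regions, %d subjects\n",
        object@group, nrow(v), object@nSubjects))
    cat(sprintf("  off-diagonal r: mean %.3f, range [%.3f, %.3f]\n",
        mean(off), min(off), max(off)))
})

setMethod("show", "ConnectivityGraph", function(object) {
    w <- object@weights
    cat(sprintf("ConnectivityGraph: %d nodes, %d edges (density %.3f)\n",
        nrow(w), sum(w[upper.tri(w)] > 0), graphDensity(object)))
})

setMethod("show", "PermutationResult", function(object) {
    cat(sprintf(
        "PermutationResult: %s vs %s (difference = %s - %s), %d permutations\n",
        object@groupA, object@groupB, object@groupB, object@groupA,
        object@nPermutations))
    cat(sprintf("  alpha = %g (%s FWE); significant: %d global, %d nodal\n",
        object@alpha, object@fweMethod,
        sum(object@global$significant), sum(object@nodal$significant)))
})
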