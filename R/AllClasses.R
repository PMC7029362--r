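#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats cor sd setNames quantile rnorm
#' @importFrom utils read.delim write.table head modifyList
NULL

#' Cortical parcellation atlas
#'
#' An ordered set of named cortical parcels with MNI coordinates. The atlas
#' defines the node set of every metabolic connectivity graph: region order is
#' the row/column order of all matrices, and the short \code{label} (e.g.
#' \code{"rPCG"}) is the region's identity. The bundled default reproduces the
#' 68-parcel FreeSurfer (Desikan-Killiany) cortical table used for FDG-PET
#' network analyses; see \code{\link{dk68AtlasFile}}.
#'
#' @slot regions data.frame with columns \code{index} (1-based, consecutive),
#'   \code{name}, \code{x}, \code{y}, \code{z} (MNI mm), \code{hemisphere}
#'   (\code{"left"}/\code{"right"}), \code{label} (unique short code).
#' @export
setClass("RegionAtlas", slots = c(regions = "data.frame"))

setValidity("RegionAtlas", function(object) {
    r <- object@regions
    need <- c("index", "name", "x", "y", "z", "hemisphere", "label")
    miss <- setdiff(need, names(r))
    if (length(miss) > 0)
        return(paste0("missing atlas column(s): ", paste(miss, collapse = ", ")))
    if (nrow(r) < 3)
        return("an atlas needs at least 3 regions (graph measures need a triangle)")
    if (!identical(as.integer(r$index), seq_len(nrow(r))))
        return("region indices must be consecutive 1..N in row order")
    dup <- unique(r$label[duplicated(r$label)])
    if (length(dup) > 0)
        return(paste0("duplicate region label(s): ", paste(dup, collapse = ", ")))
    if (any(!nzchar(r$label)))
        return("empty region label")
    if (!all(is.finite(r$x) & is.finite(r$y) & is.finite(r$z)))
        return("non-finite MNI coordinate")
    if (!all(r$hemisphere %in% c("left", "right")))
        return("hemisphere must be 'left' or 'right'")
    TRUE
})

#' Subject-level SUVR cohort
#'
#' A \linkS4class{SummarizedExperiment} subclass holding one SUVR value per
#' region (rows) and subject (columns), with the group label of each subject
#' in \code{colData()$group} and the \linkS4class{RegionAtlas} the rows are
#' keyed to. SUVR values are unitless positive ratios (regional uptake over a
#' per-subject cerebellar reference).
#'
#' @seealso \code{\link{readCohort}}, \code{\link{simulateGroup}},
#'   \code{\link{splitByGroup}}
#' @export
setClass("MetabolicCohort", contains = "SummarizedExperiment")

setValidity("MetabolicCohort", function(object) {
    if (!"suvr" %in% SummarizedExperiment::assayNames(object))
        return("assay 'suvr' is required")
    v <- SummarizedExperiment::assay(object, "suvr")
    if (!all(is.finite(v)))
        return("SUVR values must all be finite")
    if (any(v <= 0))
        return("SUVR values must all be positive")
    if (!"group" %in% names(SummarizedExperiment::colData(object)))
        return("colData column 'group' is required")
    at <- S4Vectors::metadata(object)$atlas
    if (!is(at, "RegionAtlas"))
        return("metadata(.)$atlas must be a RegionAtlas")
    if (!identical(rownames(object), regionLabels(at)))
        return("row order must equal atlas region order")
    if (anyDuplicated(colnames(object)))
        return("subject ids must be unique")
    TRUE
})

#' Group-level inter-regional correlation matrix
#'
#' Pearson correlation of SUVR between every pair of regions, computed across
#' the subjects of one group. Symmetric with unit diagonal; entries in
#' [-1, 1].
#'
#' @slot values numeric region x region matrix, dimnames = region labels.
#' @slot group group name the matrix was computed for.
#' @slot nSubjects number of subjects used.
#' @slot atlas the \linkS4class{RegionAtlas} the rows/columns are keyed to.
#' @export
setClass("CorrelationMatrix",
    slots = c(values = "matrix", group = "character", nSubjects = "integer",
        atlas = "RegionAtlas"))

setValidity("CorrelationMatrix", function(object) {
    v <- object@values
    if (nrow(v) != ncol(v)) return("matrix must be square")
    if (nrow(v) != nRegions(object@atlas))
        return("matrix size must match the atlas")
    if (!isTRUE(all.equal(v, t(v), tolerance = 1e-12, check.attributes = FALSE)))
        return("matrix must be symmetric")
    if (max(abs(diag(v) - 1)) > 1e-12) return("diagonal must be 1")
    if (any(v < -1 - 1e-12 | v > 1 + 1e-12))
        return("entries must lie in [-1, 1]")
    TRUE
})

#' Weighted metabolic connectivity graph
#'
#' Symmetric nonnegative weighted adjacency over the atlas regions, derived
#' from a \linkS4class{CorrelationMatrix} by \code{\link{toGraph}}. Zero
#' diagonal; an edge exists iff its weight is strictly positive.
#'
#' @slot weights numeric region x region adjacency in [0, 1].
#' @slot atlas the \linkS4class{RegionAtlas} giving node identity and order.
#' @export
setClass("ConnectivityGraph",
    slots = c(weights = "matrix", atlas = "RegionAtlas"))

setValidity("ConnectivityGraph", function(object) {
    w <- object@weights
    if (nrow(w) != ncol(w)) return("weight matrix must be square")
    if (nrow(w) != nRegions(object@atlas))
        return("weight matrix size must match the atlas")
    if (!isTRUE(all.equal(w, t(w), tolerance = 1e-12, check.attributes = FALSE)))
        return("weight matrix must be symmetric")
    if (any(diag(w) != 0)) return("diagonal must be exactly 0")
    if (any(w < 0)) return("weights must be nonnegative")
    if (any(w > 1 + 1e-12)) return("weights must be <= 1")
    TRUE
})

#' Result of a two-group permutation comparison
#'
#' Observed measures per group, their differences (group B minus group A),
#' two-tailed permutation p-values, and max-statistic family-wise corrected
#' p-values, for the requested global and nodal measures.
#'
#' @slot groupA,groupB compared group names; differences are B - A.
#' @slot nPermutations,alpha,seed,fweMethod test configuration.
#' @slot global data.frame: one row per global measure.
#' @slot nodal data.frame: one row per (measure, region).
#' @slot flaggedRate fraction of permutations in which a zero-variance region
#'   had to be flagged (its correlations set to 0).
#' @export
setClass("PermutationResult",
    slots = c(groupA = "character", groupB = "character",
        nPermutations = "integer", alpha = "numeric", seed = "integer",
        fweMethod = "character", global = "data.frame", nodal = "data.frame",
        flaggedRate = "numeric"))
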