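#' Cross-subject inter-regional correlation matrix
#'
#' Computes the Pearson correlation between every pair of regions' SUVR
#' values across the subjects of one group — the group-level metabolic
#' connectivity matrix. The cohort must contain a single group (split a
#' multi-group cohort with \code{\link{splitByGroup}} first).
#'
#' @param cohort a single-group \linkS4class{MetabolicCohort} with at least
#'   3 subjects.
#' @return a \linkS4class{CorrelationMatrix}.
#' @examples
#' at <- readAtlas(dk68AtlasFile())
#' cn <- simulateGroup(groupProfile("CN", 30, lambda = 0.85, seed = 3), at)
#' correlationMatrix(cn)
#' @export
correlationMatrix <- function(cohort) {
    stopifnot(is(cohort, "MetabolicCohort"))
    g <- unique(groupLabels(cohort))
    if (length(g) != 1)
        stop("cohort contains ", length(g),
            " groups; correlationMatrix() expects one (use splitByGroup)")
    x <- t(suvrValues(cohort))  # subjects x regions
    if (nrow(x) < 3)
        stop("group '", g, "' has ", nrow(x),
            " subjects; Pearson correlation needs at least 3")
    s <- apply(x, 2, stats::sd)
    if (any(s == 0))
        stop("zero-variance region(s): ",
            paste(colnames(x)[s == 0], collapse = ", "),
            " (correlation undefined)")
    v <- stats::cor(x)
    v <- (v + t(v)) / 2
    diag(v) <- 1
    new("CorrelationMatrix", values = v, group = g,
        nSubjects = nrow(x), atlas = atlas(cohort))
}

# permutation-loop variant: zero-variance regions get their correlations set
# to 0 and are reported as flagged instead of erroring
cor_tolerant <- function(x) {
    s <- apply(x, 2, stats::sd)
    flagged <- colnames(x)[s == 0]
    if (length(flagged) > 0) x[1, s == 0] <- x[1, s == 0] + 1e-12
    v <- suppressWarnings(stats::cor(x))
    v[!is.finite(v)] <- 0
    if (length(flagged) > 0) {
        v[, s == 0] <- 0
        v[s == 0, ] <- 0
    }
    v <- (v + t(v)) / 2
    diag(v) <- 1
    list(values = v, flagged = flagged)
}

#' Convert a correlation matrix to a connectivity graph
#'
#' Builds the weighted undirected adjacency: the diagonal is zeroed and
#' negative correlations are handled by \code{negativeRule} — \code{"zero"}
#' (default) removes them, \code{"absolute"} keeps their magnitude. An
#' optional correlation threshold removes weaker edges (default 0: every
#' positive correlation is an edge). Setting \code{fisherZ = TRUE} replaces
#' each surviving weight by its Fisher z-transform rescaled to [0, 1] by the
#' largest finite z — a sensitivity option, off by default.
#'
#' @param corr a \linkS4class{CorrelationMatrix}.
#' @param negativeRule \code{"zero"} or \code{"absolute"}.
#' @param threshold minimum weight for an edge to be kept (default 0).
#' @param fisherZ logical; rescaled z-transform of the weights.
#' @return a \linkS4class{ConnectivityGraph}.
#' @export
toGraph <- function(corr, negativeRule = c("zero", "absolute"),
                    threshold = 0, fisherZ = FALSE) {
    stopifnot(is(corr, "CorrelationMatrix"))
    negativeRule <- match.arg(negativeRule)
    w <- corr@values
    w <- switch(negativeRule, zero = pmax(w, 0), absolute = abs(w))
    diag(w) <- 0
    if (threshold > 0) w[w < threshold] <- 0
    if (fisherZ) {
        z <- atanh(pmin(w, 1 - 1e-12))
        mx <- max(z)
        if (mx > 0) w <- z / mx
    }
    new("ConnectivityGraph", weights = w, atlas = corr@atlas)
}

#' Construct a graph directly from a weight matrix
#'
#' Low-level constructor used by tests and file import; validates the
#' adjacency invariants (symmetry, zero diagonal, weights in [0, 1]).
#'
#' @param weights numeric square matrix.
#' @param atlas matching \linkS4class{RegionAtlas}.
#' @return a \linkS4class{ConnectivityGraph}.
#' @export
connectivityGraph <- function(weights, atlas) {
    weights <- as.matrix(weights)
    dimnames(weights) <- list(regionLabels(atlas), regionLabels(atlas))
    new("ConnectivityGraph", weights = weights, atlas = atlas)
}

#' Edge density of a connectivity graph
#'
#' Number of existing edges (weight > 0) over the number of possible
#' undirected pairs N(N-1)/2.
#'
#' @param graph a \linkS4class{ConnectivityGraph}.
#' @return fraction in [0, 1].
#' @export
graphDensity <- function(graph) {
    stopifnot(is(graph, "ConnectivityGraph"))
    w <- graph@weights
    n <- nrow(w)
    sum(w[upper.tri(w)] > 0) / (n * (n - 1) / 2)
}
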