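#' @useDynLib FDGnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

as_weights <- function(graph) {
    if (is(graph, "ConnectivityGraph")) graph@weights else as.matrix(graph)
}

#' Nodal degree
#'
#' Number of edges (strictly positive weights) attached to each node.
#'
#' @param graph a \linkS4class{ConnectivityGraph} (or plain weight matrix).
#' @return named integer vector, one value per region.
#' @export
nodalDegree <- function(graph) {
    w <- as_weights(graph)
    rowSums(w > 0)
}

#' Nodal strength
#'
#' Sum of the weights of all connections of each node.
#'
#' @inheritParams nodalDegree
#' @return named numeric vector.
#' @export
nodalStrength <- function(graph) {
    rowSums(as_weights(graph))
}

#' Weighted nodal triangle count
#'
#' Geometric-mean weighted triangle count
#' \code{t_i = (1/2) * sum_jh (w_ij w_ih w_jh)^(1/3)}, which reduces to the
#' plain triangle count on 0/1 weights.
#'
#' @inheritParams nodalDegree
#' @return named numeric vector.
#' @export
nodalTriangles <- function(graph) {
    w <- as_weights(graph)^(1 / 3)
    diag(w %*% w %*% w) / 2
}

#' Weighted nodal clustering coefficient
#'
#' \code{C_i = 2 t_i / (k_i (k_i - 1))} with the weighted triangle count
#' \code{t_i}; 0 by convention when the degree is below 2.
#'
#' @inheritParams nodalDegree
#' @return named numeric vector in [0, 1].
#' @export
nodalClustering <- function(graph) {
    k <- nodalDegree(graph)
    t <- nodalTriangles(graph)
    cc <- ifelse(k < 2, 0, 2 * t / (k * (k - 1)))
    cc[k < 2] <- 0
    cc
}

#' Weighted transitivity
#'
#' Network-wide triangle-to-triplet ratio
#' \code{T = sum(2 t_i) / sum(k_i (k_i - 1))}; 0 when no node has two
#' neighbors.
#'
#' @inheritParams nodalDegree
#' @return scalar in [0, 1].
#' @export
graphTransitivity <- function(graph) {
    k <- nodalDegree(graph)
    denom <- sum(k * (k - 1))
    if (denom == 0) return(0)
    sum(2 * nodalTriangles(graph)) / denom
}

#' Shortest-path distance matrix
#'
#' All-pairs shortest paths with edge length \code{1/weight} (the standard
#' mapping from connection strength to distance); absent edges (weight 0)
#' are not traversable and unreachable pairs are \code{Inf}.
#'
#' @inheritParams nodalDegree
#' @return region x region numeric matrix, zero diagonal.
#' @export
distanceMatrix <- function(graph) {
    w <- as_weights(graph)
    d <- cpp_shortest_paths(w)
    dimnames(d) <- dimnames(w)
    d
}

#' Nodal characteristic path length
#'
#' Mean of each node's finite off-diagonal shortest-path distances;
#' unreachable pairs are excluded from the mean, and a fully isolated node
#' gets \code{Inf}.
#'
#' @param dist a distance matrix from \code{\link{distanceMatrix}}.
#' @return named numeric vector.
#' @export
nodalPathLength <- function(dist) {
    n <- nrow(dist)
    out <- vapply(seq_len(n), function(i) {
        v <- dist[i, -i]
        v <- v[is.finite(v)]
        if (length(v) == 0) Inf else mean(v)
    }, numeric(1))
    names(out) <- rownames(dist)
    out
}

#' Nodal eccentricity
#'
#' Maximum finite shortest-path distance from each node to any other;
#' \code{Inf} for a node with no finite distances.
#'
#' @inheritParams nodalPathLength
#' @return named numeric vector.
#' @export
nodalEccentricity <- function(dist) {
    n <- nrow(dist)
    out <- vapply(seq_len(n), function(i) {
        v <- dist[i, -i]
        v <- v[is.finite(v)]
        if (length(v) == 0) Inf else max(v)
    }, numeric(1))
    names(out) <- rownames(dist)
    out
}

#' Nodal global efficiency
#'
#' Mean inverse shortest-path distance from each node to all others;
#' unreachable pairs contribute 0 (denominator N - 1).
#'
#' @inheritParams nodalPathLength
#' @return named numeric vector in [0, 1] for weights in [0, 1].
#' @export
nodalGlobalEfficiency <- function(dist) {
    n <- nrow(dist)
    inv <- 1 / dist
    diag(inv) <- 0
    inv[!is.finite(inv)] <- 0
    rowSums(inv) / (n - 1)
}

#' Nodal closeness centrality
#'
#' Reciprocal of the nodal path length; 0 when the path length is infinite.
#'
#' @inheritParams nodalPathLength
#' @return named numeric vector.
#' @export
nodalCloseness <- function(dist) {
    pl <- nodalPathLength(dist)
    ifelse(is.finite(pl), 1 / pl, 0)
}

#' Nodal local efficiency
#'
#' Global efficiency of the weighted subgraph induced on each node's
#' neighbors; 0 by convention for nodes with fewer than 2 neighbors.
#'
#' @inheritParams nodalDegree
#' @return named numeric vector.
#' @export
nodalLocalEfficiency <- function(graph) {
    w <- as_weights(graph)
    out <- as.numeric(cpp_local_efficiency(w))
    names(out) <- rownames(w)
    out
}

nodal_measure_names <- c("degree", "strength", "triangles", "eccentricity",
    "path_length", "clustering", "global_efficiency", "closeness")
global_measure_names <- c("average_strength", "average_eccentricity",
    "characteristic_path_length", "global_efficiency", "local_efficiency",
    "clustering_coefficient", "transitivity", "modularity")

#' All eight nodal measures of a connectivity graph
#'
#' @inheritParams nodalDegree
#' @return data.frame with one row per region: \code{region}, \code{degree},
#'   \code{strength}, \code{triangles}, \code{eccentricity},
#'   \code{path_length}, \code{clustering}, \code{global_efficiency},
#'   \code{closeness}.
#' @examples
#' at <- readAtlas(dk68AtlasFile())
#' g <- toGraph(correlationMatrix(
#'     simulateGroup(groupProfile("CN", 40, lambda = 0.8, seed = 5), at)))
#' head(nodalMeasures(g))
#' @export
nodalMeasures <- function(graph) {
    w <- as_weights(graph)
    d <- distanceMatrix(w)
    data.frame(
        region = rownames(w),
        degree = nodalDegree(w),
        strength = nodalStrength(w),
        triangles = nodalTriangles(w),
        eccentricity = nodalEccentricity(d),
        path_length = nodalPathLength(d),
        clustering = nodalClustering(w),
        global_efficiency = nodalGlobalEfficiency(d),
        closeness = nodalCloseness(d),
        row.names = NULL, stringsAsFactors = FALSE)
}

mean_finite <- function(x) {
    v <- x[is.finite(x)]
    if (length(v) == 0) NaN else mean(v)
}

#' All eight global measures of a connectivity graph
#'
#' Average strength, average eccentricity, characteristic path length,
#' global efficiency, local efficiency and clustering coefficient are
#' arithmetic means of the corresponding finite nodal values; transitivity
#' is the network-wide triangle/triplet ratio; modularity is the seeded
#' Louvain optimum Q.
#'
#' @inheritParams graphModularity
#' @return named numeric vector of the 8 global measures.
#' @export
globalMeasures <- function(graph, gamma = 1, seed = 1L, restarts = 100L) {
    w <- as_weights(graph)
    d <- distanceMatrix(w)
    stats::setNames(c(
        mean(nodalStrength(w)),
        mean_finite(nodalEccentricity(d)),
        mean_finite(nodalPathLength(d)),
        mean(nodalGlobalEfficiency(d)),
        mean(nodalLocalEfficiency(w)),
        mean(nodalClustering(w)),
        graphTransitivity(w),
        graphModularity(w, gamma = gamma, seed = seed,
            restarts = restarts)$Q),
        global_measure_names)
}
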