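# Modularity: weighted Newman quality with resolution gamma,
#   Q = (1/2m) * sum_ij [w_ij - gamma * s_i * s_j / (2m)] * delta(c_i, c_j)
# where s is nodal strength and 2m the total weight. Optimized by a seeded
# Louvain heuristic implemented in src/louvain.cpp.

#' Modularity of a given partition
#'
#' Evaluates weighted Newman modularity Q for an explicit community
#' membership vector, without any optimization.
#'
#' @param graph a \linkS4class{ConnectivityGraph} or plain symmetric
#'   nonnegative zero-diagonal weight matrix.
#' @param membership integer community id per node.
#' @param gamma resolution parameter (default 1).
#' @return scalar Q.
#' @export
modularityValue <- function(graph, membership, gamma = 1) {
    W <- if (is(graph, "ConnectivityGraph")) graph@weights else
        as.matrix(graph)
    m2 <- sum(W)
    if (m2 <= 0)
        stop("modularity is undefined for an edgeless graph (2m = 0)")
    s <- rowSums(W)
    same <- outer(membership, membership, "==")
    sum((W - gamma * outer(s, s) / m2) * same) / m2
}

#' Modularity and community partition of a connectivity graph
#'
#' Maximizes weighted Newman modularity (resolution \code{gamma}) with a
#' seeded Louvain heuristic: \code{restarts} independent runs with shuffled
#' node orders, keeping the partition with the best Q (first encountered on
#' ties). Bit-deterministic given \code{(seed, restarts)}.
#'
#' @param graph a \linkS4class{ConnectivityGraph} (or a plain symmetric
#'   nonnegative zero-diagonal weight matrix).
#' @param gamma resolution parameter (default 1).
#' @param seed integer RNG seed.
#' @param restarts number of restarts (default 100).
#' @return list with \code{membership} (integer vector, communities numbered
#'   by first appearance) and \code{Q}.
#' @export
graphModularity <- function(graph, gamma = 1, seed = 1L, restarts = 100L) {
    W <- if (is(graph, "ConnectivityGraph")) graph@weights else
        as.matrix(graph)
    if (sum(W) <= 0)
        stop("modularity is undefined for an edgeless graph (2m = 0)")
    seeds <- vapply(seq_len(restarts), function(r) derive_seed(seed, r), 1L)
    res <- cpp_louvain(W, gamma, seeds)
    res$membership <- as.integer(res$membership)
    res
}
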