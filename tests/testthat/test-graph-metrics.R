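complete_graph <- function(n, weight = 1) {
    connectivityGraph((matrix(weight, n, n) - diag(weight, n)),
        tiny_atlas(n))
}

star_graph <- function(n = 5) {
    w <- matrix(0, n, n)
    w[1, 2:n] <- w[2:n, 1] <- 1
    connectivityGraph(w, tiny_atlas(n))
}

path_abc <- function() {
    w <- matrix(0, 3, 3)
    w[1, 2] <- w[2, 1] <- 1
    w[2, 3] <- w[3, 2] <- 1
    connectivityGraph(w, tiny_atlas(3, labels = c("a", "b", "c")))
}

test_that("closed forms hold on canonical graphs", {
    k4 <- complete_graph(4)
    expect_equal(as.numeric(nodalStrength(k4)), rep(3, 4))
    expect_equal(as.numeric(nodalTriangles(k4)), rep(3, 4))
    expect_equal(as.numeric(nodalClustering(k4)), rep(1, 4))
    expect_equal(graphTransitivity(k4), 1)

    st <- star_graph(5)
    expect_equal(as.numeric(nodalDegree(st)), c(4, 1, 1, 1, 1))
    expect_equal(as.numeric(nodalClustering(st)), rep(0, 5))
    expect_equal(as.numeric(nodalTriangles(st)), rep(0, 5))
    # leaves of a star are mutually disconnected: local efficiency 0
    expect_equal(as.numeric(nodalLocalEfficiency(st)), rep(0, 5))

    p <- path_abc()
    d <- distanceMatrix(p)
    expect_equal(d["a", "c"], 2)
    ecc <- nodalEccentricity(d)
    expect_equal(as.numeric(ecc), c(2, 1, 2))
    expect_equal(as.numeric(nodalPathLength(d)), c(1.5, 1, 1.5))

    half <- complete_graph(68, weight = 0.5)
    expect_equal(as.numeric(nodalStrength(half)), rep(33.5, 68))
})

test_that("disconnection conventions: exclusion from means, zero efficiency", {
    # two disconnected unit-weight K2 components
    w <- matrix(0, 4, 4)
    w[1, 2] <- w[2, 1] <- w[3, 4] <- w[4, 3] <- 1
    g <- connectivityGraph(w, tiny_atlas(4))
    d <- distanceMatrix(g)
    expect_true(all(is.infinite(d[1, 3:4])))
    expect_equal(as.numeric(nodalPathLength(d)), rep(1, 4))
    expect_equal(as.numeric(nodalEccentricity(d)), rep(1, 4))
    expect_equal(as.numeric(nodalGlobalEfficiency(d)), rep(1 / 3, 4))
    expect_equal(as.numeric(nodalCloseness(d)), rep(1, 4))

    none <- connectivityGraph(matrix(0, 4, 4), tiny_atlas(4))
    dn <- distanceMatrix(none)
    expect_equal(as.numeric(nodalGlobalEfficiency(dn)), rep(0, 4))
    expect_equal(as.numeric(nodalCloseness(dn)), rep(0, 4))
    expect_true(all(is.infinite(nodalPathLength(dn))))
    expect_equal(as.numeric(nodalStrength(none)), rep(0, 4))
    expect_error(graphModularity(none), "edgeless")
    expect_error(globalMeasures(none), "edgeless")
})

test_that("all measures agree with brute-force oracles on random graphs", {
    for (seed in 1:40) {
        n <- 4 + (seed %% 6)
        w <- random_weights(n, density = runif(1, 0.3, 0.9), seed = seed)
        g <- connectivityGraph(w, tiny_atlas(n))
        d_orc <- oracle_distances(w)
        expect_equal(distanceMatrix(g), d_orc, ignore_attr = TRUE,
            tolerance = 1e-12)
        expect_equal(as.numeric(nodalTriangles(g)), oracle_triangles(w),
            tolerance = 1e-9)
        expect_equal(as.numeric(nodalStrength(g)), unname(rowSums(w)))
        expect_equal(as.numeric(nodalPathLength(distanceMatrix(g))),
            oracle_path_length(d_orc), tolerance = 1e-9)
        expect_equal(as.numeric(nodalLocalEfficiency(g)),
            oracle_local_efficiency(w), tolerance = 1e-9)
    }
})

test_that("binary-graph measures match igraph's independent implementation", {
    skip_if_not_installed("igraph")
    for (seed in c(3, 14, 27)) {
        n <- 9
        w <- random_weights(n, density = 0.5, seed = seed)
        wb <- (w > 0) * 1  # binarized
        g <- connectivityGraph(wb, tiny_atlas(n))
        ig <- igraph::graph_from_adjacency_matrix(wb, mode = "undirected")
        expect_equal(as.numeric(nodalDegree(g)), igraph::degree(ig),
            ignore_attr = TRUE)
        expect_equal(as.numeric(nodalTriangles(g)),
            as.numeric(igraph::count_triangles(ig)))
        expect_equal(distanceMatrix(g),
            igraph::distances(ig), ignore_attr = TRUE)
        expect_equal(graphTransitivity(g),
            igraph::transitivity(ig, type = "global"))
    }
})

test_that("edge additions and weight scaling behave monotonically", {
    w <- random_weights(8, density = 0.4, seed = 5)
    g <- connectivityGraph(w, tiny_atlas(8))
    d0 <- distanceMatrix(g)
    # add an edge where none exists
    zero_pairs <- which(w == 0 & upper.tri(w), arr.ind = TRUE)
    ij <- zero_pairs[1, ]
    w2 <- w
    w2[ij[1], ij[2]] <- w2[ij[2], ij[1]] <- 0.8
    g2 <- connectivityGraph(w2, tiny_atlas(8))
    expect_true(all(distanceMatrix(g2) <= d0 + 1e-12))
    expect_true(all(nodalStrength(g2) >= nodalStrength(g)))
    expect_true(all(nodalDegree(g2) >= nodalDegree(g)))

    # scaling: strength ~ c, distance ~ 1/c, clustering ~ c, degree fixed
    for (c in c(0.3, 0.75)) {
        gc <- connectivityGraph(w * c, tiny_atlas(8))
        expect_equal(nodalStrength(gc), nodalStrength(g) * c)
        expect_equal(distanceMatrix(gc), d0 / c)
        expect_equal(nodalClustering(gc), nodalClustering(g) * c,
            tolerance = 1e-12)
        expect_equal(nodalDegree(gc), nodalDegree(g))
    }
})

test_that("closeness is the exact reciprocal of finite path length", {
    w <- random_weights(9, density = 0.6, seed = 13)
    d <- distanceMatrix(connectivityGraph(w, tiny_atlas(9)))
    pl <- nodalPathLength(d)
    cl <- nodalCloseness(d)
    fin <- is.finite(pl)
    expect_equal(cl[fin] * pl[fin], rep(1, sum(fin)), ignore_attr = TRUE)
})

test_that("Louvain recovers planted structure and the exhaustive optimum", {
    # two K4 cliques joined by one weak edge
    w <- matrix(0, 8, 8)
    w[1:4, 1:4] <- 1
    w[5:8, 5:8] <- 1
    diag(w) <- 0
    w[4, 5] <- w[5, 4] <- 0.01
    g <- connectivityGraph(w, tiny_atlas(8))
    res <- graphModularity(g, seed = 3)
    expect_equal(length(unique(res$membership)), 2)
    expect_equal(res$membership[1:4], rep(res$membership[1], 4))
    expect_equal(res$membership[5:8], rep(res$membership[5], 4))
    best <- oracle_best_partition(w)
    expect_equal(res$Q, best$Q, tolerance = 1e-9)

    # complete uniform graph: no nontrivial split beats Q = 0
    ku <- matrix(0.6, 6, 6) - diag(0.6, 6)
    parts <- enumerate_partitions(6)
    qs <- vapply(parts, function(p) oracle_Q(ku, p), 0)
    expect_true(all(qs[vapply(parts, max, 0) > 1] <= 1e-12))
    resk <- graphModularity(connectivityGraph(ku, tiny_atlas(6)), seed = 1)
    expect_equal(resk$Q, 0, tolerance = 1e-12)

    # random toy graphs: Louvain Q equals the exhaustive maximum
    for (seed in c(2, 8, 15, 23)) {
        n <- 5 + (seed %% 3)
        wr <- random_weights(n, density = 0.5, seed = seed)
        if (sum(wr) == 0) next
        res <- graphModularity(wr, seed = seed)
        opt <- oracle_best_partition(wr)
        expect_lte(res$Q, opt$Q + 1e-9)
        expect_equal(res$Q, opt$Q, tolerance = 1e-9)
        expect_equal(modularityValue(wr, res$membership), res$Q,
            tolerance = 1e-12)
    }

    # an 8-node instance against full enumeration (4140 partitions)
    w8 <- random_weights(8, density = 0.5, seed = 19)
    res8 <- graphModularity(w8, seed = 19)
    opt8 <- oracle_best_partition(w8)
    expect_lte(res8$Q, opt8$Q + 1e-9)
    expect_equal(res8$Q, opt8$Q, tolerance = 1e-9)
})

test_that("global measures aggregate the nodal values they summarize", {
    w <- random_weights(9, density = 0.7, seed = 31)
    g <- connectivityGraph(w, tiny_atlas(9))
    gm <- globalMeasures(g, seed = 4)
    d <- distanceMatrix(g)
    expect_equal(gm[["average_strength"]], mean(nodalStrength(g)))
    expect_equal(gm[["average_eccentricity"]],
        mean(nodalEccentricity(d)[is.finite(nodalEccentricity(d))]))
    expect_equal(gm[["characteristic_path_length"]],
        mean(nodalPathLength(d)[is.finite(nodalPathLength(d))]))
    expect_equal(gm[["global_efficiency"]], mean(nodalGlobalEfficiency(d)))
    expect_equal(gm[["local_efficiency"]], mean(nodalLocalEfficiency(g)))
    expect_equal(gm[["clustering_coefficient"]], mean(nodalClustering(g)))
    expect_equal(gm[["transitivity"]], graphTransitivity(g))
    expect_equal(gm[["modularity"]],
        graphModularity(g, seed = 4)$Q)
    nm <- nodalMeasures(g)
    expect_equal(names(nm), c("region", "degree", "strength", "triangles",
        "eccentricity", "path_length", "clustering", "global_efficiency",
        "closeness"))
    expect_equal(nm$strength, as.numeric(nodalStrength(g)))
})
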