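# Independent brute-force oracles. These deliberately share no code with the
# package: Floyd-Warshall instead of Dijkstra, explicit triple loops instead
# of matrix algebra, exhaustive set-partition search instead of Louvain.

oracle_distances <- function(w) {
    n <- nrow(w)
    d <- matrix(Inf, n, n)
    diag(d) <- 0
    for (i in 1:n) for (j in 1:n)
        if (i != j && w[i, j] > 0) d[i, j] <- 1 / w[i, j]
    for (k in 1:n) for (i in 1:n) for (j in 1:n)
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
    d
}

oracle_triangles <- function(w) {
    n <- nrow(w)
    t <- numeric(n)
    for (i in 1:n) {
        acc <- 0
        for (j in 1:n) for (h in 1:n)
            if (j != i && h != i && j != h)
                acc <- acc + (w[i, j] * w[i, h] * w[j, h])^(1 / 3)
        t[i] <- acc / 2
    }
    t
}

oracle_path_length <- function(d) {
    n <- nrow(d)
    sapply(1:n, function(i) {
        v <- d[i, -i]; v <- v[is.finite(v)]
        if (length(v) == 0) Inf else mean(v)
    })
}

oracle_eccentricity <- function(d) {
    n <- nrow(d)
    sapply(1:n, function(i) {
        v <- d[i, -i]; v <- v[is.finite(v)]
        if (length(v) == 0) Inf else max(v)
    })
}

oracle_global_efficiency <- function(d) {
    n <- nrow(d)
    sapply(1:n, function(i) {
        v <- 1 / d[i, -i]; v[!is.finite(v)] <- 0
        sum(v) / (n - 1)
    })
}

oracle_local_efficiency <- function(w) {
    n <- nrow(w)
    sapply(1:n, function(i) {
        nb <- which(w[i, ] > 0)
        if (length(nb) < 2) return(0)
        ds <- oracle_distances(w[nb, nb, drop = FALSE])
        k <- length(nb)
        acc <- 0
        for (a in 1:k) for (b in 1:k)
            if (a != b && is.finite(ds[a, b])) acc <- acc + 1 / ds[a, b]
        acc / (k * (k - 1))
    })
}

# all set partitions of 1..n as membership vectors (restricted growth)
enumerate_partitions <- function(n) {
    out <- list()
    recurse <- function(memb, mx) {
        i <- length(memb) + 1
        if (i > n) {
            out[[length(out) + 1]] <<- memb
            return()
        }
        for (c in seq_len(mx + 1)) recurse(c(memb, c), max(mx, c))
    }
    recurse(integer(0), 0L)
    out
}

oracle_Q <- function(w, memb, gamma = 1) {
    m2 <- sum(w)
    s <- rowSums(w)
    q <- 0
    n <- nrow(w)
    for (i in 1:n) for (j in 1:n)
        if (memb[i] == memb[j])
            q <- q + w[i, j] - gamma * s[i] * s[j] / m2
    q / m2
}

oracle_best_partition <- function(w, gamma = 1) {
    parts <- enumerate_partitions(nrow(w))
    qs <- vapply(parts, function(p) oracle_Q(w, p, gamma), 0)
    list(Q = max(qs), membership = parts[[which.max(qs)]])
}
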