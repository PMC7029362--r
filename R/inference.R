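#' Signed group difference
#'
#' Element-wise difference \code{b - a}. The convention is fixed so that in
#' a comparison of group A vs group B the reported difference is B minus A
#' (e.g. DLB minus AD when comparing AD against DLB).
#'
#' @param a,b numeric scalars, vectors or matrices of matching shape.
#' @return same shape as the inputs.
#' @examples
#' groupDifference(38.02, 15.69)   # -22.33
#' groupDifference(1.8538, 3.2901) #  1.4363
#' @export
groupDifference <- function(a, b) {
    if (length(a) != length(b))
        stop("shape mismatch: length ", length(a), " vs ", length(b))
    b - a
}

measure_universe <- function() {
    list(global = global_measure_names,
        nodal = paste0("nodal_", nodal_measure_names))
}

# which ingredients does a measure selection need?
measure_needs <- function(globals, nodals) {
    nod <- sub("^nodal_", "", nodals)
    list(
        dist = any(c("average_eccentricity", "characteristic_path_length",
                "global_efficiency") %in% globals) ||
            any(c("eccentricity", "path_length", "global_efficiency",
                "closeness") %in% nod),
        tri = any(c("clustering_coefficient", "transitivity") %in% globals) ||
            any(c("triangles", "clustering") %in% nod),
        loceff = "local_efficiency" %in% globals,
        louvain = "modularity" %in% globals)
}

# run correlation -> graph -> selected measures on a subjects x regions
# matrix; tolerant = flag zero-variance regions instead of erroring
pipeline_measures <- function(x, globals, nodals, gamma, modSeed, restarts,
                              negativeRule, threshold, tolerant = FALSE) {
    if (tolerant) {
        ct <- cor_tolerant(x)
        v <- ct$values
        flagged <- ct$flagged
    } else {
        s <- apply(x, 2, stats::sd)
        if (any(s == 0))
            stop("zero-variance region(s): ",
                paste(colnames(x)[s == 0], collapse = ", "))
        v <- stats::cor(x)
        v <- (v + t(v)) / 2
        flagged <- character(0)
    }
    w <- switch(negativeRule, zero = pmax(v, 0), absolute = abs(v))
    diag(w) <- 0
    if (threshold > 0) w[w < threshold] <- 0
    needs <- measure_needs(globals, nodals)
    nod <- sub("^nodal_", "", nodals)
    n <- nrow(w)
    k <- nodalDegree(w)
    str <- nodalStrength(w)
    if (needs$tri) tri <- nodalTriangles(w)
    if (needs$dist) {
        d <- cpp_shortest_paths(w)
        dimnames(d) <- dimnames(w)
        ecc <- nodalEccentricity(d)
        pl <- nodalPathLength(d)
        geff <- nodalGlobalEfficiency(d)
    }
    gvals <- vapply(globals, function(m) switch(m,
        average_strength = mean(str),
        average_eccentricity = mean_finite(ecc),
        characteristic_path_length = mean_finite(pl),
        global_efficiency = mean(geff),
        local_efficiency = mean(nodalLocalEfficiency(w)),
        clustering_coefficient = mean(ifelse(k < 2, 0,
            2 * tri / pmax(k * (k - 1), 1))),
        transitivity = if (sum(k * (k - 1)) == 0) 0 else
            sum(2 * tri) / sum(k * (k - 1)),
        modularity = graphModularity(w, gamma = gamma, seed = modSeed,
            restarts = restarts)$Q), numeric(1))
    nvals <- vapply(nod, function(m) switch(m,
        degree = as.numeric(k),
        strength = str,
        triangles = tri,
        eccentricity = ecc,
        path_length = pl,
        clustering = ifelse(k < 2, 0, 2 * tri / pmax(k * (k - 1), 1)),
        global_efficiency = geff,
        closeness = ifelse(is.finite(pl), 1 / pl, 0)),
        numeric(n))
    if (length(nod) > 0) rownames(nvals) <- colnames(x)
    list(global = gvals, nodal = nvals, flagged = flagged)
}

add_one_p <- function(abs_null, abs_obs) {
    # abs_null: B x k, abs_obs: length k; add-one permutation p
    abs_null[is.na(abs_null)] <- Inf
    (1 + colSums(abs_null >= rep(abs_obs, each = nrow(abs_null)))) /
        (nrow(abs_null) + 1)
}

#' Two-group permutation test of network measures
#'
#' Compares the selected global and nodal graph measures between two groups
#' with a two-tailed non-parametric permutation test. For every permutation
#' the pooled subjects are relabeled preserving the original group sizes and
#' the full pipeline (correlation, graph construction, measures) is
#' recomputed from scratch. Family-wise error across nodes (within each
#' nodal measure) and across the tested global measures is controlled with
#' the max-statistic null by default, or Bonferroni.
#'
#' Permutation draws are taken over the pooled subjects in a canonical
#' (id-sorted) order, so swapping the roles of the two cohorts negates every
#' difference and leaves every p-value unchanged at the same seed.
#'
#' @param cohortA,cohortB single-group \linkS4class{MetabolicCohort}s keyed
#'   to the same atlas; differences are reported as B minus A.
#' @param nPermutations number of permutations (default 1000, minimum 100).
#' @param alpha FWE significance level (default 0.05).
#' @param seed integer seed governing permutations and modularity restarts.
#' @param measures character subset of the 16 measure names — the 8 global
#'   names (\code{average_strength}, \code{average_eccentricity},
#'   \code{characteristic_path_length}, \code{global_efficiency},
#'   \code{local_efficiency}, \code{clustering_coefficient},
#'   \code{transitivity}, \code{modularity}) and the 8 nodal names prefixed
#'   \code{nodal_} (\code{nodal_degree}, \code{nodal_strength},
#'   \code{nodal_triangles}, \code{nodal_eccentricity},
#'   \code{nodal_path_length}, \code{nodal_clustering},
#'   \code{nodal_global_efficiency}, \code{nodal_closeness});
#'   \code{NULL} selects all 16.
#' @param gamma modularity resolution.
#' @param restarts Louvain restarts per modularity evaluation.
#' @param fweMethod \code{"maxstat"} (default) or \code{"bonferroni"}.
#' @param negativeRule,threshold graph construction options, see
#'   \code{\link{toGraph}}.
#' @return a \linkS4class{PermutationResult}.
#' @export
permutationTest <- function(cohortA, cohortB, nPermutations = 1000L,
                            alpha = 0.05, seed = 1L, measures = NULL,
                            gamma = 1, restarts = 100L,
                            fweMethod = c("maxstat", "bonferroni"),
                            negativeRule = c("zero", "absolute"),
                            threshold = 0) {
    stopifnot(is(cohortA, "MetabolicCohort"), is(cohortB, "MetabolicCohort"))
    fweMethod <- match.arg(fweMethod)
    negativeRule <- match.arg(negativeRule)
    nPermutations <- as.integer(nPermutations)
    if (nPermutations < 100) stop("nPermutations must be >= 100")
    if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
    if (!identical(regionLabels(cohortA), regionLabels(cohortB)))
        stop("cohorts must be keyed to the same atlas")
    ga <- unique(groupLabels(cohortA))
    gb <- unique(groupLabels(cohortB))
    if (length(ga) != 1 || length(gb) != 1)
        stop("each cohort must contain a single group")
    uni <- measure_universe()
    if (is.null(measures)) measures <- c(uni$global, uni$nodal)
    bad <- setdiff(measures, c(uni$global, uni$nodal))
    if (length(bad) > 0)
        stop("unknown measure(s): ", paste(bad, collapse = ", "))
    globals <- intersect(uni$global, measures)
    nodals <- intersect(uni$nodal, measures)

    xa <- t(suvrValues(cohortA))
    xb <- t(suvrValues(cohortB))
    na <- nrow(xa)
    nb <- nrow(xb)
    if (na + nb < 6) stop("need at least 6 subjects combined")
    if (na < 3 || nb < 3) stop("each group needs at least 3 subjects")

    # seeds are tied to group names (not argument position) so that
    # swapping cohortA and cohortB mirrors the result exactly
    gfirst <- min(ga, gb)
    obsA <- pipeline_measures(xa, globals, nodals, gamma,
        modSeed = derive_seed(seed, if (ga == gfirst) -1L else -2L),
        restarts = restarts,
        negativeRule = negativeRule, threshold = threshold)
    obsB <- pipeline_measures(xb, globals, nodals, gamma,
        modSeed = derive_seed(seed, if (gb == gfirst) -1L else -2L),
        restarts = restarts,
        negativeRule = negativeRule, threshold = threshold)

    # canonical pooled order makes the null invariant to argument order
    pool <- rbind(xa, xb)
    ord <- order(rownames(pool))
    pool <- pool[ord, , drop = FALSE]
    nfirst <- if (gfirst == ga) na else nb
    n <- na + nb

    B <- nPermutations
    nullG <- matrix(NA_real_, B, length(globals),
        dimnames = list(NULL, globals))
    nullN <- if (length(nodals) > 0)
        array(NA_real_, c(B, ncol(pool), length(nodals)),
            dimnames = list(NULL, colnames(pool), nodals)) else NULL
    flaggedPerms <- 0L
    with_seed(seed, {
        for (b in seq_len(B)) {
            shuffle <- sample.int(n)
            first <- shuffle[seq_len(nfirst)]
            xf <- pool[first, , drop = FALSE]
            xs <- pool[-first, , drop = FALSE]
            rf <- pipeline_measures(xf, globals, nodals, gamma,
                modSeed = derive_seed(seed, 100000L + b),
                restarts = restarts, negativeRule = negativeRule,
                threshold = threshold, tolerant = TRUE)
            rs <- pipeline_measures(xs, globals, nodals, gamma,
                modSeed = derive_seed(seed, 200000L + b),
                restarts = restarts, negativeRule = negativeRule,
                threshold = threshold, tolerant = TRUE)
            if (gfirst == ga) { ra <- rf; rb <- rs } else { ra <- rs; rb <- rf }
            if (length(ra$flagged) > 0 || length(rb$flagged) > 0)
                flaggedPerms <- flaggedPerms + 1L
            if (length(globals) > 0)
                nullG[b, ] <- rb$global - ra$global
            if (length(nodals) > 0)
                nullN[b, , ] <- rb$nodal - ra$nodal
        }
    })
    flaggedRate <- flaggedPerms / B
    if (flaggedRate > 0.01)
        stop("zero-variance regions were flagged in ",
            round(100 * flaggedRate, 1), "% of permutations (> 1%)")

    global <- data.frame()
    if (length(globals) > 0) {
        diffG <- obsB$global - obsA$global
        absNull <- abs(nullG)
        absNull[is.na(absNull)] <- Inf
        pRaw <- add_one_p(absNull, abs(diffG))
        pFwe <- switch(fweMethod,
            maxstat = {
                mx <- apply(absNull, 1, max)
                (1 + vapply(abs(diffG), function(o) sum(mx >= o), 0)) / (B + 1)
            },
            bonferroni = pmin(1, pRaw * length(globals)))
        pFwe <- pmax(pFwe, pRaw)
        global <- data.frame(measure = globals,
            value_a = obsA$global, value_b = obsB$global,
            difference = diffG, p_raw = pRaw, p_fwe = pFwe,
            significant = pFwe < alpha,
            null_mean = colMeans(nullG),
            null_sd = apply(nullG, 2, stats::sd),
            row.names = NULL, stringsAsFactors = FALSE)
    }

    nodal <- data.frame()
    if (length(nodals) > 0) {
        regions <- colnames(pool)
        pieces <- lapply(seq_along(nodals), function(m) {
            obs <- obsB$nodal[, m] - obsA$nodal[, m]
            nulls <- nullN[, , m, drop = FALSE]
            dim(nulls) <- c(B, length(regions))
            absNull <- abs(nulls)
            absNull[is.na(absNull)] <- Inf
            pRaw <- add_one_p(absNull, abs(obs))
            pFwe <- switch(fweMethod,
                maxstat = {
                    mx <- apply(absNull, 1, max)
                    (1 + vapply(abs(obs), function(o) sum(mx >= o), 0)) /
                        (B + 1)
                },
                bonferroni = pmin(1, pRaw * length(regions)))
            pFwe <- pmax(pFwe, pRaw)
            data.frame(measure = sub("^nodal_", "", nodals[m]),
                region = regions,
                value_a = obsA$nodal[, m], value_b = obsB$nodal[, m],
                difference = obs, p_raw = pRaw, p_fwe = pFwe,
                significant = pFwe < alpha,
                null_mean = colMeans(nulls),
                null_sd = apply(nulls, 2, stats::sd),
                row.names = NULL, stringsAsFactors = FALSE)
        })
        nodal <- do.call(rbind, pieces)
    }

    new("PermutationResult", groupA = ga, groupB = gb,
        nPermutations = B, alpha = alpha, seed = as.integer(seed),
        fweMethod = fweMethod, global = global, nodal = nodal,
        flaggedRate = flaggedRate)
}

#' Significant-findings summary table
#'
#' Collapses a \linkS4class{PermutationResult} to the rows that survive FWE
#' correction, in the conventional layout: region, measure, the two group
#' values, their signed difference (group B minus group A) and the corrected
#' p-value. Global measures appear with region \code{"(global)"}. Returns an
#' empty table (with header) when nothing is significant.
#'
#' @param result a \linkS4class{PermutationResult}.
#' @return data.frame with columns \code{region}, \code{measure},
#'   \code{value_a}, \code{value_b}, \code{difference}, \code{p_fwe}.
#' @export
summarizeComparison <- function(result) {
    stopifnot(is(result, "PermutationResult"))
    cols <- c("region", "measure", "value_a", "value_b", "difference",
        "p_fwe")
    g <- result@global
    n <- result@nodal
    rows <- list()
    if (nrow(g) > 0 && any(g$significant)) {
        gs <- g[g$significant, , drop = FALSE]
        gs$region <- "(global)"
        rows <- c(rows, list(gs[, cols]))
    }
    if (nrow(n) > 0 && any(n$significant))
        rows <- c(rows, list(n[n$significant, cols, drop = FALSE]))
    if (length(rows) == 0) {
        out <- data.frame(region = character(0), measure = character(0),
            value_a = numeric(0), value_b = numeric(0),
            difference = numeric(0), p_fwe = numeric(0))
        return(out)
    }
    out <- do.call(rbind, rows)
    out <- out[order(out$region, out$measure), , drop = FALSE]
    rownames(out) <- NULL
    out
}
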