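two_block_atlas <- function() tiny_atlas(12)

dense_group <- function(name, n, seed)
    simulateGroup(groupProfile(name, n, lambda = 0.85, seed = seed),
        two_block_atlas())

# same two-block layout with the second block either preserved or severely
# attenuated; matched blocks make preserved-block nodes exact nulls
blocked_group <- function(name, n, seed, lambda2 = 0.85) {
    labs <- regionLabels(two_block_atlas())
    simulateGroup(groupProfile(name, n, lambda = c(0.85, lambda2),
        blocks = list(labs[1:6], labs[7:12]), seed = seed),
        two_block_atlas())
}

patchy_group <- function(name, n, seed)
    blocked_group(name, n, seed, lambda2 = 0.2)

test_that("group differences follow the B-minus-A convention", {
    expect_equal(groupDifference(38.02, 15.69), -22.33)
    expect_equal(groupDifference(1.8538, 3.2901), 1.4363)
    expect_equal(groupDifference(c(1, 2), c(1, 2)), c(0, 0))
    m <- matrix(1:4, 2)
    expect_equal(groupDifference(m, m * 3), m * 2)
    expect_error(groupDifference(1:3, 1:2), "shape")
})

test_that("comparing a cohort against its own copy finds nothing", {
    a <- dense_group("G", 15, seed = 2)
    res <- permutationTest(a, a, nPermutations = 100, seed = 5,
        measures = c("average_strength", "nodal_strength", "nodal_degree"))
    expect_equal(res@global$difference, 0)
    expect_equal(res@nodal$difference, rep(0, 24))
    expect_false(any(res@global$significant))
    expect_false(any(res@nodal$significant))
    expect_true(all(res@nodal$p_fwe == 1))
})

test_that("p-values respect the add-one floor and FWE dominance", {
    a <- dense_group("A", 12, seed = 3)
    b <- patchy_group("B", 12, seed = 4)
    res <- permutationTest(a, b, nPermutations = 200, seed = 7)
    for (df in list(res@global, res@nodal)) {
        expect_true(all(df$p_raw >= 1 / 201))
        expect_true(all(df$p_raw <= 1))
        expect_true(all(df$p_fwe >= df$p_raw))
        # FWE-significant set is a subset of the raw-significant set
        expect_true(all(df$p_raw[df$significant] < res@alpha))
    }
    expect_equal(res@nodal$difference,
        res@nodal$value_b - res@nodal$value_a)
})

test_that("swapping the groups mirrors the result exactly", {
    a <- dense_group("A", 12, seed = 8)
    b <- patchy_group("B", 12, seed = 9)
    ms <- c("average_strength", "clustering_coefficient", "modularity",
        "nodal_strength", "nodal_path_length")
    ab <- permutationTest(a, b, nPermutations = 150, seed = 11,
        measures = ms)
    ba <- permutationTest(b, a, nPermutations = 150, seed = 11,
        measures = ms)
    expect_equal(ba@global$difference, -ab@global$difference)
    expect_equal(ba@nodal$difference, -ab@nodal$difference)
    expect_equal(ba@global$p_raw, ab@global$p_raw)
    expect_equal(ba@global$p_fwe, ab@global$p_fwe)
    expect_equal(ba@nodal$p_raw, ab@nodal$p_raw)
    expect_equal(ba@nodal$p_fwe, ab@nodal$p_fwe)
})

test_that("identical inputs and seed give bit-identical results", {
    a <- dense_group("A", 12, seed = 13)
    b <- dense_group("B", 12, seed = 14)
    r1 <- permutationTest(a, b, nPermutations = 120, seed = 21,
        measures = c("modularity", "nodal_strength"))
    r2 <- permutationTest(a, b, nPermutations = 120, seed = 21,
        measures = c("modularity", "nodal_strength"))
    expect_identical(r1@global, r2@global)
    expect_identical(r1@nodal, r2@nodal)
    r3 <- permutationTest(a, b, nPermutations = 120, seed = 22,
        measures = c("modularity", "nodal_strength"))
    expect_false(identical(r1@nodal$p_raw, r3@nodal$p_raw))
})

test_that("attenuated-block strength reductions are detected specifically", {
    a <- blocked_group("CNlike", 100, seed = 31)
    b <- patchy_group("LBlike", 100, seed = 32)
    res <- permutationTest(a, b, nPermutations = 500, seed = 33,
        measures = "nodal_strength")
    nod <- res@nodal
    inside <- nod$region %in% regionLabels(two_block_atlas())[7:12]
    # every attenuated-block node: significant, with negative difference
    expect_true(all(nod$significant[inside]))
    expect_true(all(nod$difference[inside] < 0))
    # preserved-block nodes stay quiet
    expect_false(any(nod$significant[!inside]))

    summary <- summarizeComparison(res)
    expect_setequal(summary$region, nod$region[inside])
    expect_equal(names(summary), c("region", "measure", "value_a",
        "value_b", "difference", "p_fwe"))
})

test_that("summaries of null results are empty but well-formed", {
    a <- dense_group("A", 12, seed = 41)
    res <- permutationTest(a, a, nPermutations = 100, seed = 1,
        measures = "nodal_degree")
    s <- summarizeComparison(res)
    expect_equal(nrow(s), 0)
    expect_equal(names(s), c("region", "measure", "value_a", "value_b",
        "difference", "p_fwe"))
})

test_that("bonferroni correction is available and more conservative", {
    a <- dense_group("A", 15, seed = 51)
    b <- patchy_group("B", 15, seed = 52)
    mx <- permutationTest(a, b, nPermutations = 150, seed = 53,
        measures = "nodal_strength")
    bf <- permutationTest(a, b, nPermutations = 150, seed = 53,
        measures = "nodal_strength", fweMethod = "bonferroni")
    expect_equal(bf@nodal$p_raw, mx@nodal$p_raw)
    expect_true(all(bf@nodal$p_fwe >= bf@nodal$p_raw))
    expect_equal(bf@nodal$p_fwe,
        pmax(pmin(1, bf@nodal$p_raw * 12), bf@nodal$p_raw))
})

test_that("invalid comparison specs are rejected", {
    a <- dense_group("A", 12, seed = 61)
    b <- dense_group("B", 12, seed = 62)
    expect_error(permutationTest(a, b, nPermutations = 50), ">= 100")
    expect_error(permutationTest(a, b, alpha = 1.2), "alpha")
    expect_error(permutationTest(a, b, measures = "bogus"), "bogus")
    small <- dense_group("C", 3, seed = 63)[, 1:2]
    expect_error(permutationTest(small, small), "6 subjects")
})
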