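test_that("bundled atlas parses with full fidelity", {
    at <- readAtlas(dk68AtlasFile())
    expect_s4_class(at, "RegionAtlas")
    expect_equal(nRegions(at), 68)
    r <- at@regions
    expect_equal(r$label[53], "rPCG")
    expect_equal(unlist(r[53, c("x", "y", "z")], use.names = FALSE),
        c(7.6, -17.1, 36.2))
    expect_equal(sum(r$hemisphere == "left"), 34)
    expect_false(anyDuplicated(r$label) > 0)
})

test_that("atlas reader accepts both delimiters and validates the schema", {
    at <- tiny_atlas(3)
    tsv <- tempfile(fileext = ".tsv")
    writeAtlas(at, tsv)
    expect_equal(readAtlas(tsv)@regions, at@regions)

    csv <- tempfile(fileext = ".csv")
    writeAtlas(at, csv, delim = ",")
    expect_equal(readAtlas(csv)@regions, at@regions)

    # duplicate label names the offender
    dup <- at@regions
    dup$label <- c("lSF", "lSF", "rSF")
    f <- tempfile()
    write.table(dup, f, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readAtlas(f), "lSF")

    # missing column is a schema error
    f2 <- tempfile()
    write.table(dup[, setdiff(names(dup), "hemisphere")], f2, sep = "\t",
        quote = FALSE, row.names = FALSE)
    expect_error(readAtlas(f2), "hemisphere")

    # non-numeric coordinate reports the row
    bad <- at@regions
    bad$x[2] <- "oops"
    f3 <- tempfile()
    write.table(bad, f3, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readAtlas(f3), "row 2")
})

test_that("atlases below three regions are rejected", {
    at <- tiny_atlas(3)
    two <- at@regions[1:2, ]
    f <- tempfile()
    write.table(two, f, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readAtlas(f), "3 regions")
})

test_that("cohort round-trips through file and canonicalizes column order", {
    at <- tiny_atlas(5)
    set.seed(42)
    vals <- matrix(runif(50, 0.8, 1.6), 10, 5)
    rownames(vals) <- sprintf("sub%02d", 1:10)
    cohort <- cohort_from_matrix(vals, group = rep(c("A", "B"), 5),
        atlas = at)
    path <- write_cohort_file(cohort)
    back <- readCohort(path, at)
    expect_equal(suvrValues(back), suvrValues(cohort))
    expect_equal(groupLabels(back), groupLabels(cohort))
    expect_equal(subjectIds(back), subjectIds(cohort))

    # permuted region columns give the identical cohort
    df <- read.delim(path, check.names = FALSE)
    perm <- df[, c("subject_id", "group", rev(regionLabels(at)))]
    path2 <- tempfile()
    write.table(perm, path2, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_equal(suvrValues(readCohort(path2, at)), suvrValues(cohort))

    # missing region column is a schema error listing the label
    drop <- df[, setdiff(names(df), "R03")]
    path3 <- tempfile()
    write.table(drop, path3, sep = "\t", quote = FALSE, row.names = FALSE)
    expect_error(readCohort(path3, at), "R03")
})

test_that("non-positive SUVR values are rejected with the subject named", {
    at <- tiny_atlas(3)
    vals <- matrix(1, 3, 3)
    rownames(vals) <- c("ok1", "broken", "ok2")
    vals[2, 2] <- -0.5
    expect_error(cohort_from_matrix(vals, atlas = at), "broken")
})

test_that("SUVR computation divides by the per-subject reference", {
    expect_equal(as.numeric(computeSUVR(rbind(c(6, 3, 9)), 3)), c(2, 1, 3))
    u <- matrix(1.7, 4, 3)
    expect_equal(computeSUVR(u, rep(1.7, 4)), matrix(1, 4, 3))
    bad <- matrix(1, 2, 3)
    rownames(bad) <- c("a", "zeroref")
    expect_error(computeSUVR(bad, c(1, 0)), "zeroref")
    # scale invariance of the ratio
    set.seed(7)
    u <- matrix(runif(12, 1, 3), 4, 3)
    r <- runif(4, 0.5, 2)
    expect_equal(computeSUVR(u * 3.7, r * 3.7), computeSUVR(u, r))
})

test_that("splitByGroup partitions without loss and preserves order", {
    at <- tiny_atlas(4)
    set.seed(1)
    vals <- matrix(runif(40, 0.9, 1.5), 10, 4)
    rownames(vals) <- sprintf("s%02d", 1:10)
    g <- c("AD", "CN", "AD", "", "DLB", "CN", "AD", "CN", "", "DLB")
    cohort <- cohort_from_matrix(vals, group = g, atlas = at)
    parts <- splitByGroup(cohort)
    expect_setequal(names(parts), c("AD", "CN", "", "DLB"))
    expect_equal(sum(vapply(parts, ncol, 0L)), ncol(cohort))
    # empty labels are kept as their own literal group, nothing dropped
    expect_equal(subjectIds(parts[[which(names(parts) == "")]]),
        c("s04", "s09"))
    # subject order within group is file order
    expect_equal(subjectIds(parts$AD), c("s01", "s03", "s07"))
    # single group
    one <- splitByGroup(cohort_from_matrix(vals, group = "X", atlas = at))
    expect_equal(names(one), "X")
    expect_equal(ncol(one$X), 10)
})
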