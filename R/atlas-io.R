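#' Path to the bundled 68-region cortical atlas
#'
#' Tab-delimited table of the 68 FreeSurfer (Desikan-Killiany) cortical
#' parcels with MNI coordinates, hemisphere and short labels, as used for
#' FDG-PET metabolic network analysis.
#'
#' @return file path of the bundled atlas table.
#' @examples
#' at <- readAtlas(dk68AtlasFile())
#' nRegions(at)
#' @export
dk68AtlasFile <- function() {
    system.file("extdata", "atlas_dk68.tsv", package = "FDGnet",
        mustWork = TRUE)
}

#' Read a region atlas table
#'
#' Reads a delimited text atlas (comma or tab, auto-detected from the header
#' line) with columns \code{index}, \code{name}, \code{x}, \code{y},
#' \code{z}, \code{hemisphere}, \code{label}. Row order is preserved and
#' becomes the node order of every downstream matrix.
#'
#' @param path path to the atlas file.
#' @param delim field delimiter; default auto-detects tab vs comma.
#' @return a \linkS4class{RegionAtlas}.
#' @examples
#' readAtlas(dk68AtlasFile())
#' @export
readAtlas <- function(path, delim = NULL) {
    if (!file.exists(path)) stop("atlas file not found: ", path)
    if (is.null(delim)) delim <- detect_delim(path)
    raw <- utils::read.delim(path, sep = delim, header = TRUE,
        colClasses = "character", check.names = FALSE,
        strip.white = TRUE, comment.char = "#")
    need <- c("index", "name", "x", "y", "z", "hemisphere", "label")
    miss <- setdiff(need, names(raw))
    if (length(miss) > 0)
        stop("atlas schema error: missing column(s) ",
            paste(miss, collapse = ", "))
    for (col in c("index", "x", "y", "z")) {
        num <- suppressWarnings(as.numeric(raw[[col]]))
        bad <- which(is.na(num) & !is.na(raw[[col]]))
        if (length(bad) > 0)
            stop("atlas parse error: non-numeric '", col, "' in data row ",
                bad[1], " (value '", raw[[col]][bad[1]], "')")
        raw[[col]] <- num
    }
    regions <- data.frame(index = as.integer(raw$index), name = raw$name,
        x = raw$x, y = raw$y, z = raw$z, hemisphere = raw$hemisphere,
        label = raw$label, stringsAsFactors = FALSE)
    new("RegionAtlas", regions = regions)
}

#' Write a region atlas table
#'
#' @param atlas a \linkS4class{RegionAtlas}.
#' @param path output path.
#' @param delim field delimiter (default tab).
#' @return \code{path}, invisibly.
#' @export
writeAtlas <- function(atlas, path, delim = "\t") {
    stopifnot(is(atlas, "RegionAtlas"))
    utils::write.table(atlas@regions, path, sep = delim, quote = FALSE,
        row.names = FALSE)
    invisible(path)
}

#' Construct a metabolic cohort from a SUVR matrix
#'
#' @param suvr numeric subjects x regions matrix; column names must be the
#'   atlas region labels (any order; columns are reordered to atlas order),
#'   row names the subject ids (generated if absent).
#' @param group character vector of group labels, one per subject.
#' @param atlas the \linkS4class{RegionAtlas} the columns are keyed to.
#' @return a \linkS4class{MetabolicCohort}.
#' @export
MetabolicCohort <- function(suvr, group, atlas) {
    stopifnot(is(atlas, "RegionAtlas"))
    suvr <- as.matrix(suvr)
    labels <- regionLabels(atlas)
    if (is.null(colnames(suvr))) {
        if (ncol(suvr) != length(labels))
            stop("SUVR matrix has ", ncol(suvr), " columns for ",
                length(labels), " atlas regions")
        colnames(suvr) <- labels
    }
    miss <- setdiff(labels, colnames(suvr))
    if (length(miss) > 0)
        stop("cohort schema error: missing region column(s) ",
            paste(miss, collapse = ", "))
    suvr <- suvr[, labels, drop = FALSE]
    if (is.null(rownames(suvr)))
        rownames(suvr) <- sprintf("S%03d", seq_len(nrow(suvr)))
    if (length(group) != nrow(suvr))
        stop("one group label per subject required")
    bad <- which(!is.finite(suvr) | suvr <= 0, arr.ind = TRUE)
    if (nrow(bad) > 0)
        stop("invalid SUVR (non-finite or <= 0) for subject '",
            rownames(suvr)[bad[1, 1]], "', region '",
            colnames(suvr)[bad[1, 2]], "'")
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(suvr = t(suvr)),
        colData = S4Vectors::DataFrame(group = as.character(group),
            row.names = rownames(suvr)),
        rowData = S4Vectors::DataFrame(atlas@regions,
            row.names = labels),
        metadata = list(atlas = atlas))
    new("MetabolicCohort", se)
}

#' Read a subject cohort table
#'
#' Reads a delimited cohort file with columns \code{subject_id},
#' \code{group}, and one SUVR column per atlas region label (any column
#' order; reordered to atlas order). If a \code{reference_value} column is
#' present the region columns are taken as raw regional uptake and SUVR is
#' computed by dividing each subject's row by its reference value (the mean
#' cerebellar uptake; the reference region is external to the cortical
#' atlas).
#'
#' @param path path to the cohort file.
#' @param atlas the \linkS4class{RegionAtlas} to validate against.
#' @param delim field delimiter; default auto-detects tab vs comma.
#' @return a \linkS4class{MetabolicCohort} with subjects in file order.
#' @export
readCohort <- function(path, atlas, delim = NULL) {
    if (!file.exists(path)) stop("cohort file not found: ", path)
    stopifnot(is(atlas, "RegionAtlas"))
    if (is.null(delim)) delim <- detect_delim(path)
    raw <- utils::read.delim(path, sep = delim, header = TRUE,
        check.names = FALSE, stringsAsFactors = FALSE, comment.char = "#")
    for (col in c("subject_id", "group"))
        if (!col %in% names(raw))
            stop("cohort schema error: missing column '", col, "'")
    labels <- regionLabels(atlas)
    miss <- setdiff(labels, names(raw))
    if (length(miss) > 0)
        stop("cohort schema error: missing region column(s) ",
            paste(miss, collapse = ", "))
    values <- as.matrix(raw[, labels, drop = FALSE])
    storage.mode(values) <- "double"
    rownames(values) <- as.character(raw$subject_id)
    if ("reference_value" %in% names(raw))
        values <- computeSUVR(values, raw$reference_value)
    MetabolicCohort(values, raw$group, atlas)
}

#' Write a cohort table
#'
#' @param cohort a \linkS4class{MetabolicCohort}.
#' @param path output path.
#' @param delim field delimiter (default tab).
#' @return \code{path}, invisibly.
#' @export
writeCohort <- function(cohort, path, delim = "\t") {
    stopifnot(is(cohort, "MetabolicCohort"))
    df <- data.frame(subject_id = subjectIds(cohort),
        group = groupLabels(cohort),
        t(suvrValues(cohort)), check.names = FALSE,
        stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = delim, quote = FALSE,
        row.names = FALSE)
    invisible(path)
}

#' Compute SUVR from raw regional uptake
#'
#' Divides each subject's regional uptake by that subject's reference-region
#' value (conventionally the mean cerebellar cortex uptake). The reference is
#' a per-subject scalar, not an atlas region.
#'
#' @param uptake numeric subjects x regions matrix of raw uptake values.
#' @param reference numeric vector, one positive value per subject.
#' @return subjects x regions matrix of SUVR.
#' @examples
#' computeSUVR(rbind(A = c(6, 3, 9)), reference = 3)  # 2 1 3
#' @export
computeSUVR <- function(uptake, reference) {
    uptake <- as.matrix(uptake)
    reference <- as.numeric(reference)
    if (length(reference) == 1L) reference <- rep(reference, nrow(uptake))
    if (length(reference) != nrow(uptake))
        stop("one reference value per subject required")
    if (!all(is.finite(uptake)))
        stop("uptake values must be finite")
    bad <- which(!is.finite(reference) | reference <= 0)
    if (length(bad) > 0) {
        ids <- rownames(uptake)
        who <- if (is.null(ids)) paste("row", bad[1]) else ids[bad[1]]
        stop("non-positive reference value for subject '", who, "'")
    }
    sweep(uptake, 1, reference, "/")
}

#' Split a cohort by group label
#'
#' Partitions the cohort into one \linkS4class{MetabolicCohort} per distinct
#' group label (order of first appearance), preserving subject order within
#' each group. No rows are dropped: an empty-string group label forms its own
#' group.
#'
#' @param cohort a \linkS4class{MetabolicCohort}.
#' @return named list of \linkS4class{MetabolicCohort}, one per group.
#' @export
splitByGroup <- function(cohort) {
    stopifnot(is(cohort, "MetabolicCohort"))
    g <- groupLabels(cohort)
    out <- lapply(unique(g), function(grp)
        cohort[, g == grp])
    names(out) <- unique(g)
    out
}
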