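#' Export a graph for BrainNet Viewer
#'
#' Writes the viewer's two plain-text files: a \code{.node} file with one
#' row per region — \code{x y z color size label} — and a \code{.edge} file
#' holding the N x N whitespace-delimited weight matrix. Node color is 2 for
#' highlighted regions (e.g. nodes with significant group differences) and
#' 1 otherwise; node size is the chosen nodal measure.
#'
#' @param graph a \linkS4class{ConnectivityGraph}.
#' @param nodal data.frame from \code{\link{nodalMeasures}} for the same
#'   graph (computed on the fly if \code{NULL}).
#' @param sizeMeasure nodal measure name used for node size (default
#'   \code{"strength"}).
#' @param highlight character vector of region labels drawn in the
#'   highlight color.
#' @param file output path without extension; \code{.node} and \code{.edge}
#'   are appended.
#' @return invisibly, named character vector with the two paths written.
#' @export
exportBrainNet <- function(graph, nodal = NULL, sizeMeasure = "strength",
                           highlight = character(0), file) {
    stopifnot(is(graph, "ConnectivityGraph"))
    if (is.null(nodal)) nodal <- nodalMeasures(graph)
    if (!sizeMeasure %in% nodal_measure_names)
        stop("unknown nodal measure '", sizeMeasure, "'")
    reg <- atlas(graph)@regions
    unknown <- setdiff(highlight, reg$label)
    if (length(unknown) > 0)
        stop("unknown highlight label(s): ", paste(unknown, collapse = ", "))
    nodeDf <- data.frame(x = reg$x, y = reg$y, z = reg$z,
        color = ifelse(reg$label %in% highlight, 2L, 1L),
        size = nodal[[sizeMeasure]], label = reg$label)
    nodePath <- paste0(file, ".node")
    edgePath <- paste0(file, ".edge")
    utils::write.table(nodeDf, nodePath, sep = "\t", quote = FALSE,
        row.names = FALSE, col.names = FALSE)
    utils::write.table(graphWeights(graph), edgePath, sep = "\t",
        quote = FALSE, row.names = FALSE, col.names = FALSE)
    invisible(c(node = nodePath, edge = edgePath))
}

#' Read a BrainNet .edge file back into a graph
#'
#' @param path path to a whitespace-delimited N x N matrix file.
#' @param atlas matching \linkS4class{RegionAtlas}.
#' @return a \linkS4class{ConnectivityGraph}.
#' @export
readEdgeFile <- function(path, atlas) {
    w <- as.matrix(utils::read.table(path, header = FALSE))
    connectivityGraph(w, atlas)
}

#' Heatmap-ready correlation matrix export
#'
#' Packages a correlation matrix with per-group display metadata for
#' rendering: the requested color range and, per cell, whether display
#' clamping applies. Values outside the range are clamped in the rendering
#' metadata only — the data themselves are returned untouched.
#'
#' @param corr a \linkS4class{CorrelationMatrix}.
#' @param colorRange numeric length-2 \code{c(min, max)} display range.
#' @return list with \code{values} (the untouched matrix), \code{group},
#'   \code{color_range}, \code{display} (the clamped copy used only for
#'   rendering) and \code{n_clamped}.
#' @export
exportMatrixFigureData <- function(corr, colorRange = c(-1, 1)) {
    stopifnot(is(corr, "CorrelationMatrix"))
    if (length(colorRange) != 2 || !(colorRange[1] < colorRange[2]))
        stop("colorRange must be c(min, max) with min < max")
    v <- corValues(corr)
    display <- pmin(pmax(v, colorRange[1]), colorRange[2])
    list(values = v, group = corr@group, color_range = colorRange,
        display = display, n_clamped = sum(display != v))
}

#' Write a labeled square matrix as delimited text
#'
#' N x N matrix with a header of region labels and a comment-line provenance
#' header; used for correlation and adjacency matrices.
#'
#' @param m matrix with region-label dimnames.
#' @param path output path.
#' @param seed seed recorded in the provenance header.
#' @param timestamp include a timestamp line (default TRUE).
#' @return \code{path}, invisibly.
#' @export
writeMatrix <- function(m, path, seed = NA, timestamp = TRUE) {
    df <- data.frame(region = rownames(m), m, check.names = FALSE,
        stringsAsFactors = FALSE)
    write_delim_with_header(df, path,
        provenance_header(seed, timestamp = timestamp))
    invisible(path)
}
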