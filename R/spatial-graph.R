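#' Build a pruned-Delaunay spatial graph
#'
#' Delaunay triangulation of cell centroids with every edge longer than
#' `max_dist` (default 50 micrometers) removed, giving the cell adjacency
#' used by all downstream spatial analyses. Coordinates are continuous
#' micrometers in the local ROI frame; no edge-effect correction is applied
#' at ROI borders.
#'
#' Degenerate inputs fall back gracefully: fewer than 2 points give an empty
#' graph with a warning; collinear point sets (where the triangulation is
#' undefined) fall back to a radius graph connecting all pairs within
#' `max_dist`; exactly coincident duplicates are attached to their retained
#' representative by a zero-length edge; all-coincident input is an error.
#'
#' Called on a `CellTable`, builds one graph per ROI and returns a named list
#' (names are ROI keys).
#'
#' @param x a [CellTable-class], or an n x 2 coordinate matrix for one ROI.
#' @param max_dist pruning threshold in micrometers.
#' @param cell_ids node names when `x` is a matrix (default row numbers).
#' @param roi ROI key used for labeling when `x` is a matrix.
#' @return A [SpatialGraph-class], or a named list of them for a `CellTable`.
#' @examples
#' pts <- cbind(c(0, 40, 40, 0), c(0, 0, 40, 40))
#' g <- buildSpatialGraph(pts, max_dist = 50)
#' numEdges(g)  # 4: the ~56.6 um square diagonal is pruned
#' @export
setGeneric("buildSpatialGraph", function(x, max_dist = 50, ...)
    standardGeneric("buildSpatialGraph"))

.collinear <- function(coords) {
    cc <- sweep(coords, 2L, colMeans(coords))
    s <- svd(cc, nu = 0L, nv = 0L)$d
    s[2] <= max(s[1], 1) * 1e-10
}

.radiusEdges <- function(coords, max_dist) {
    n <- nrow(coords)
    d <- as.matrix(stats::dist(coords))
    idx <- which(upper.tri(d) & d <= max_dist, arr.ind = TRUE)
    cbind(idx[, 1], idx[, 2])
}

.delaunayEdges <- function(coords) {
    # deldir drops exactly duplicated points; re-attach each duplicate to its
    # retained representative with a zero-length edge
    key <- paste(coords[, 1], coords[, 2])
    first <- match(key, key)
    uniq <- which(first == seq_along(key))
    if (length(uniq) < length(key) && length(uniq) == 1L)
        stop("all points coincident: triangulation undefined")
    # capture.output: deldir prints grid-adjustment notes straight to stdout
    dd <- tryCatch({
        utils::capture.output(suppressMessages(
            out <- deldir::deldir(coords[uniq, 1], coords[uniq, 2],
                                  suppressMsge = TRUE)))
        out
    }, error = function(e) {
        # near-degenerate configurations (many collinear/cocircular points)
        # can overflow deldir's incremental insertion; retry with a fixed,
        # sub-nanometer deterministic jitter that cannot alter adjacency at
        # tissue scale
        jit <- 1e-6 * cbind(sin(seq_along(uniq) * 1.7),
                            cos(seq_along(uniq) * 2.3))
        utils::capture.output(suppressMessages(
            out <- deldir::deldir(coords[uniq, 1] + jit[, 1],
                                  coords[uniq, 2] + jit[, 2],
                                  suppressMsge = TRUE)))
        out
    })
    e <- cbind(uniq[dd$delsgs$ind1], uniq[dd$delsgs$ind2])
    dup <- which(first != seq_along(key))
    if (length(dup)) e <- rbind(e, cbind(first[dup], dup))
    e
}

.makeGraph <- function(coords, max_dist, cell_ids, roi) {
    n <- nrow(coords)
    if (is.null(cell_ids)) cell_ids <- as.character(seq_len(n))
    empty <- function() new("SpatialGraph", roi = roi, cellIds = cell_ids,
                            coords = coords,
                            edges = matrix(integer(), ncol = 2L),
                            lengths = numeric(), maxDist = max_dist)
    if (n < 2L) {
        warning("fewer than 2 points in ROI '", roi, "': empty graph")
        return(empty())
    }
    if (all(coords[, 1] == coords[1, 1] & coords[, 2] == coords[1, 2]))
        stop("all points coincident in ROI '", roi, "'")
    e <- if (n == 2L || .collinear(coords)) .radiusEdges(coords, max_dist)
         else .delaunayEdges(coords)
    if (!nrow(e)) return(empty())
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    e <- unique(e)
    len <- sqrt((coords[e[, 1], 1] - coords[e[, 2], 1])^2 +
                (coords[e[, 1], 2] - coords[e[, 2], 2])^2)
    keep <- len <= max_dist
    e <- e[keep, , drop = FALSE]
    len <- len[keep]
    o <- order(e[, 1], e[, 2])
    new("SpatialGraph", roi = roi, cellIds = cell_ids, coords = coords,
        edges = matrix(as.integer(e[o, ]), ncol = 2L), lengths = len[o],
        maxDist = max_dist)
}

#' @rdname buildSpatialGraph
#' @export
setMethod("buildSpatialGraph", "matrix",
    function(x, max_dist = 50, cell_ids = NULL, roi = "ROI") {
        storage.mode(x) <- "double"
        .makeGraph(x, max_dist, cell_ids, roi)
    })

#' @rdname buildSpatialGraph
#' @export
setMethod("buildSpatialGraph", "CellTable", function(x, max_dist = 50) {
    keys <- roiKeys(x)
    coords <- cellCoordinates(x)
    uk <- unique(keys)
    out <- lapply(uk, function(k) {
        idx <- which(keys == k)
        .makeGraph(coords[idx, , drop = FALSE], max_dist,
                   rownames(coords)[idx], k)
    })
    stats::setNames(out, uk)
})

#' @rdname SpatialGraph-class
#' @param object,graph a `SpatialGraph`.
#' @export
setMethod("show", "SpatialGraph", function(object) {
    cat("SpatialGraph '", object@roi, "': ", length(object@cellIds),
        " cells, ", nrow(object@edges), " edges (max_dist = ",
        object@maxDist, " um)\n", sep = "")
})

#' Number of cells / edges in a spatial graph
#'
#' @param graph a `SpatialGraph`.
#' @return Integer count.
#' @export
numCells <- function(graph) length(graph@cellIds)

#' @rdname numCells
#' @export
numEdges <- function(graph) nrow(graph@edges)

#' Edge list of a spatial graph
#'
#' @param graph a `SpatialGraph`.
#' @return data.frame: cell_a, cell_b, length_um.
#' @export
edgeTable <- function(graph) {
    data.frame(cell_a = graph@cellIds[graph@edges[, 1]],
               cell_b = graph@cellIds[graph@edges[, 2]],
               length_um = graph@lengths)
}

#' Adjacency lists
#'
#' @param graph a `SpatialGraph`.
#' @return Named list mapping each cell id to its neighbors' cell ids; the
#'   handshake identity sum(degree) == 2 * numEdges(graph) always holds.
#' @export
neighborLists <- function(graph) {
    n <- length(graph@cellIds)
    nb <- vector("list", n)
    e <- graph@edges
    for (i in seq_len(nrow(e))) {
        nb[[e[i, 1]]] <- c(nb[[e[i, 1]]], e[i, 2])
        nb[[e[i, 2]]] <- c(nb[[e[i, 2]]], e[i, 1])
    }
    stats::setNames(lapply(nb, function(ix) graph@cellIds[ix]),
                    graph@cellIds)
}
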