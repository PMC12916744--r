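#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment assay assay<- assayNames colData colData<-
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @importFrom SingleCellExperiment SingleCellExperiment
#' @useDynLib spatialTME, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.SURGERIES <- c("primary", "recurrent")
.REQUIRED_CELL_COLS <- c("patient", "surgery", "roi", "cell_id", "x", "y")

#' CellTable: per-cell marker intensities with spatial and sample annotation
#'
#' A `CellTable` is a [SingleCellExperiment::SingleCellExperiment] whose
#' columns are segmented cells and whose rows are protein markers. The
#' `"intensities"` assay holds raw (non-negative) mean marker intensities per
#' cell; downstream steps add `"asinh"` (cofactor-transformed) and `"z"`
#' (per-marker z-scored) assays. The column data carries, at minimum, the
#' identity keys `patient`, `surgery` (one of `"primary"`/`"recurrent"`),
#' `roi`, `cell_id`, and centroid coordinates `x`, `y` in micrometers.
#' Phenotyping appends `cell_type`, `category`, `hypoxic` and `emt`;
#' neighborhood analysis appends `cn`; spatial-context detection appends `sc`.
#'
#' @slot int_elementMetadata,int_colData,... inherited from
#'   `SingleCellExperiment`.
#' @export
setClass("CellTable", contains = "SingleCellExperiment")

setValidity("CellTable", function(object) {
    msg <- character()
    cd <- colData(object)
    missing_cols <- setdiff(.REQUIRED_CELL_COLS, colnames(cd))
    if (length(missing_cols))
        msg <- c(msg, paste0("missing required cell columns: ",
                             paste(missing_cols, collapse = ", ")))
    if (!"intensities" %in% assayNames(object))
        msg <- c(msg, "an 'intensities' assay is required")
    if (!length(missing_cols)) {
        if (anyDuplicated(cd$cell_id))
            msg <- c(msg, "cell_id values must be unique")
        bad <- setdiff(unique(as.character(cd$surgery)), .SURGERIES)
        if (length(bad))
            msg <- c(msg, paste0("surgery must be one of {",
                                 paste(.SURGERIES, collapse = ", "),
                                 "}; found: ", paste(bad, collapse = ", ")))
        if (!is.numeric(cd$x) || !is.numeric(cd$y) ||
            any(!is.finite(cd$x)) || any(!is.finite(cd$y)))
            msg <- c(msg, "coordinates x/y must be finite numerics")
    }
    if (length(msg)) msg else TRUE
})

#' Spatial adjacency graph of one ROI
#'
#' Undirected cell adjacency for a single region of interest, obtained from a
#' Delaunay triangulation of cell centroids pruned at a maximum edge length
#' (default 50 micrometers). Edges are stored as a two-column integer matrix of
#' indices into `cellIds`, together with Euclidean lengths in micrometers.
#'
#' @slot roi character(1), the ROI key (`patient.surgery.roi`).
#' @slot cellIds character, cell identifiers (graph nodes).
#' @slot coords numeric matrix (n x 2) of centroid coordinates in micrometers.
#' @slot edges integer matrix (m x 2) of node index pairs, each row i < j.
#' @slot lengths numeric, Euclidean edge lengths in micrometers.
#' @slot maxDist numeric(1), the pruning threshold in micrometers.
#' @export
setClass("SpatialGraph",
    representation(roi = "character", cellIds = "character",
                   coords = "matrix", edges = "matrix",
                   lengths = "numeric", maxDist = "numeric"))

setValidity("SpatialGraph", function(object) {
    msg <- character()
    n <- length(object@cellIds)
    e <- object@edges
    if (nrow(object@coords) != n || ncol(object@coords) != 2)
        msg <- c(msg, "coords must be an n x 2 matrix matching cellIds")
    if (ncol(e) != 2 && nrow(e) > 0)
        msg <- c(msg, "edges must have two columns")
    if (nrow(e) > 0) {
        if (any(e < 1L) || any(e > n))
            msg <- c(msg, "edge indices out of range")
        if (any(e[, 1] == e[, 2]))
            msg <- c(msg, "self-edges are not allowed")
        key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
        if (anyDuplicated(key))
            msg <- c(msg, "duplicate edges are not allowed")
        if (length(object@lengths) != nrow(e))
            msg <- c(msg, "lengths must match the number of edges")
        else if (any(object@lengths > object@maxDist + 1e-9))
            msg <- c(msg, "retained edges must not exceed maxDist")
    }
    if (length(msg)) msg else TRUE
})

#' Cellular-neighborhood model from k-means on neighbor composition
#'
#' Holds the fitted k-means solution over per-cell neighbor-composition
#' vectors: the `k` centroid compositions (rows sum to 1), the per-cell CN
#' label (`"CN1"` ... `"CNk"`, or `"isolated"` for cells without neighbors),
#' the within-cluster sum of squares of the best restart, and the seed.
#'
#' @slot k integer(1) number of neighborhoods.
#' @slot centers numeric matrix (k x types) of centroid compositions.
#' @slot labels named character vector, CN label per cell id.
#' @slot inertia numeric(1), total within-cluster sum of squares.
#' @slot seed integer(1) seed used for the k-means++ restarts.
#' @slot nInit integer(1) number of restarts.
#' @export
setClass("NeighborhoodModel",
    representation(k = "integer", centers = "matrix", labels = "character",
                   inertia = "numeric", seed = "integer", nInit = "integer"))

setValidity("NeighborhoodModel", function(object) {
    msg <- character()
    if (nrow(object@centers) != object@k)
        msg <- c(msg, "centers must have k rows")
    s <- rowSums(object@centers)
    if (any(object@centers < -1e-9) || any(abs(s - 1) > 1e-6))
        msg <- c(msg, "centroids must be nonnegative and sum to 1")
    if (length(msg)) msg else TRUE
})

#' Per-cell spatial contexts
#'
#' The spatial context (SC) of a cell is the minimal set of cellular
#' neighborhoods whose cumulative fraction within the cell's wider spatial
#' window reaches the dominance threshold. The label is the sorted CN set
#' joined by `"&"` (e.g. `"CN2&CN6"`); cells with an empty window are `NA`.
#'
#' @slot cells DataFrame with columns patient, surgery, roi, cell_id, sc.
#' @slot threshold numeric(1), the cumulative dominance threshold.
#' @slot window character(1), description of the window used (e.g. "2-hop").
#' @export
setClass("SpatialContextResult",
    representation(cells = "DataFrame", threshold = "numeric",
                   window = "character"))

#' Cellular-neighborhood interaction network
#'
#' Nodes are CNs appearing in the retained (dominant) spatial contexts of one
#' surgery; an undirected edge joins two CNs that co-occur in at least one
#' retained SC. Per-node degree, closeness (Wasserman-Faust component-size
#' corrected) and normalized betweenness are tabulated alongside per-CN cell
#' counts.
#'
#' @slot graph an igraph object.
#' @slot surgery character(1).
#' @slot centralities data.frame: cn, degree, closeness, betweenness, n_cells.
#' @export
setClass("CNNetwork",
    representation(graph = "ANY", surgery = "character",
                   centralities = "data.frame"))
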