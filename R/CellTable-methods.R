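#' Construct a CellTable
#'
#' @param intensities numeric matrix of raw marker intensities, markers in
#'   rows and cells in columns. Must be non-negative.
#' @param cellData a `data.frame` or [S4Vectors::DataFrame] with one row per
#'   cell; must contain `patient`, `surgery`, `roi`, `cell_id`, `x`, `y`.
#' @param metadata optional list stored as experiment metadata.
#'
#' @return A [CellTable-class] object.
#' @examples
#' m <- matrix(rexp(12), nrow = 3,
#'             dimnames = list(c("CD45", "GFAP", "CD31"), NULL))
#' cd <- data.frame(patient = "P01", surgery = "primary", roi = "R1",
#'                  cell_id = paste0("c", 1:4),
#'                  x = runif(4, 0, 100), y = runif(4, 0, 100))
#' ct <- CellTable(m, cd)
#' @export
CellTable <- function(intensities, cellData, metadata = list()) {
    intensities <- as.matrix(intensities)
    if (is.null(rownames(intensities)))
        stop("intensity matrix must carry marker names as rownames")
    if (any(intensities < 0))
        stop("raw intensities must be non-negative")
    cd <- DataFrame(cellData)
    if (nrow(cd) != ncol(intensities))
        stop("cellData rows must match intensity columns")
    colnames(intensities) <- as.character(cd$cell_id)
    sce <- SingleCellExperiment(assays = list(intensities = intensities),
                                colData = cd)
    metadata(sce) <- metadata
    new("CellTable", sce)
}

#' @describeIn CellTable marker (row) names.
#' @param x,object a `CellTable`.
#' @export
markerNames <- function(x) rownames(x)

#' Assay accessors for CellTable
#'
#' `rawIntensities()` returns the raw intensity assay; `asinhIntensities()`
#' the cofactor-transformed assay added by [transformIntensities()];
#' `zScores()` the per-marker z-scored assay added by [zScoreIntensities()].
#'
#' @param x a `CellTable`.
#' @return A markers x cells numeric matrix.
#' @export
rawIntensities <- function(x) assay(x, "intensities")

#' @rdname rawIntensities
#' @export
asinhIntensities <- function(x) {
    if (!"asinh" %in% assayNames(x))
        stop("no 'asinh' assay; run transformIntensities() first")
    assay(x, "asinh")
}

#' @rdname rawIntensities
#' @export
zScores <- function(x) {
    if (!"z" %in% assayNames(x))
        stop("no 'z' assay; run zScoreIntensities() first")
    assay(x, "z")
}

#' Spatial coordinates of cells
#'
#' @param x a `CellTable`.
#' @return n x 2 matrix of centroid coordinates (micrometers), rownames are
#'   cell ids.
#' @export
cellCoordinates <- function(x) {
    cd <- colData(x)
    m <- cbind(x = cd$x, y = cd$y)
    rownames(m) <- cd$cell_id
    m
}

#' ROI keys
#'
#' Every cell belongs to one region of interest, identified by the composite
#' key `patient.surgery.roi`.
#'
#' @param x a `CellTable`.
#' @return Character vector of ROI keys, one per cell.
#' @export
roiKeys <- function(x) {
    cd <- colData(x)
    paste(cd$patient, cd$surgery, cd$roi, sep = ".")
}

#' Assigned cell types and categories
#'
#' @param x a `CellTable` after [assignTypes()].
#' @return Named character vector (names are cell ids).
#' @export
cellTypes <- function(x) {
    if (!"cell_type" %in% colnames(colData(x)))
        stop("no cell types assigned; run assignTypes() first")
    stats::setNames(as.character(colData(x)$cell_type), colData(x)$cell_id)
}

#' @rdname cellTypes
#' @export
cellCategories <- function(x) {
    if (!"category" %in% colnames(colData(x)))
        stop("no categories assigned; run assignTypes() first")
    stats::setNames(as.character(colData(x)$category), colData(x)$cell_id)
}

setMethod("show", "CellTable", function(object) {
    cd <- colData(object)
    cat("CellTable:", ncol(object), "cells,", nrow(object), "markers\n")
    cat("  patients:", length(unique(cd$patient)),
        "| surgeries:", paste(sort(unique(as.character(cd$surgery))),
                              collapse = "/"),
        "| ROIs:", length(unique(roiKeys(object))), "\n")
    cat("  assays:", paste(assayNames(object), collapse = ", "), "\n")
    extra <- intersect(c("cell_type", "category", "hypoxic", "emt", "cn", "sc"),
                       colnames(cd))
    if (length(extra)) cat("  annotations:", paste(extra, collapse = ", "), "\n")
})

#' Flatten a CellTable to a tidy data.frame
#'
#' One row per cell: identity keys, coordinates, annotation columns, then one
#' column per marker from the requested assay.
#'
#' @param x a `CellTable`.
#' @param assay_name which assay to flatten (default `"intensities"`).
#' @return A base `data.frame`.
#' @export
asCellDataFrame <- function(x, assay_name = "intensities") {
    cd <- as.data.frame(colData(x))
    mat <- t(assay(x, assay_name))
    stopifnot(!any(colnames(mat) %in% colnames(cd)))
    cbind(cd, as.data.frame(mat, row.names = NULL))
}

#' Read / write a cell table as delimited text
#'
#' The on-disk format is a plain CSV with the identity/coordinate columns
#' (`patient`, `surgery`, `roi`, `cell_id`, `x`, `y`), any annotation columns,
#' and one column per marker holding raw intensities. Marker columns are all
#' columns not otherwise recognized, or can be named explicitly.
#'
#' @param path file path.
#' @param markers optional character vector naming the marker columns; by
#'   default every column that is not an identity/annotation column.
#' @return `readCellTable()` returns a [CellTable-class];
#'   `writeCellTable()` invisibly returns `path`.
#' @export
readCellTable <- function(path, markers = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.csv(path, check.names = FALSE)
    missing_cols <- setdiff(.REQUIRED_CELL_COLS, colnames(df))
    if (length(missing_cols))
        stop("schema error: missing column(s) ",
             paste(missing_cols, collapse = ", "))
    known <- c(.REQUIRED_CELL_COLS,
               "cell_type", "category", "true_type", "true_hypoxic",
               "true_emt", "hypoxic", "emt", "cn", "sc")
    if (is.null(markers)) markers <- setdiff(colnames(df), known)
    if (!length(markers)) stop("no marker columns found")
    for (m in markers) {
        v <- df[[m]]
        if (!is.numeric(v)) {
            bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
            stop("parse error: non-numeric marker '", m, "' at row ", bad)
        }
    }
    ann <- intersect(setdiff(known, .REQUIRED_CELL_COLS), colnames(df))
    ct <- CellTable(t(as.matrix(df[, markers, drop = FALSE])),
                    df[, c(.REQUIRED_CELL_COLS, ann), drop = FALSE])
    ct
}

#' @rdname readCellTable
#' @param x a `CellTable`.
#' @export
writeCellTable <- function(x, path) {
    utils::write.csv(asCellDataFrame(x), path, row.names = FALSE)
    invisible(path)
}
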