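#' Per-cell neighbor-composition vectors
#'
#' For each cell, the fraction of each cell type among its graph neighbors
#' (optionally including the cell itself). Vectors live on the simplex: they
#' are non-negative and sum to 1. Cells without neighbors have no defined
#' composition and are excluded (tracked via the `"isolated"` attribute).
#'
#' @param graph a [SpatialGraph-class] or a named list of them.
#' @param labels named character vector of cell types covering all nodes.
#' @param include_self count the cell's own type in its composition
#'   (default FALSE: a neighborhood is its neighbors).
#' @param types optional fixed type universe for the columns (useful when
#'   pooling graphs whose ROIs do not all contain every type).
#' @return numeric matrix (cells x types), rownames are cell ids; attribute
#'   `"isolated"` lists excluded cell ids. For a list of graphs the rows of
#'   all ROIs are pooled.
#' @export
neighborComposition <- function(graph, labels, include_self = FALSE,
                                types = NULL) {
    if (is.list(graph)) {
        if (is.null(types)) types <- sort(unique(as.character(labels)))
        parts <- lapply(graph, neighborComposition, labels = labels,
                        include_self = include_self, types = types)
        out <- do.call(rbind, parts)
        attr(out, "isolated") <- unlist(lapply(parts, attr, "isolated"),
                                        use.names = FALSE)
        return(out)
    }
    lc <- .labelCodes(graph, labels)
    lev <- if (is.null(types)) lc$levels else types
    code <- match(lc$levels[lc$codes], lev)
    if (any(is.na(code)))
        stop("labels contain types outside the supplied type universe")
    n <- length(lc$codes)
    K <- length(lev)
    e <- graph@edges
    counts <- matrix(0, nrow = n, ncol = K,
                     dimnames = list(graph@cellIds, lev))
    if (nrow(e)) {
        inc <- base::table(factor(e[, 1], seq_len(n)),
                           factor(code[e[, 2]], seq_len(K))) +
               base::table(factor(e[, 2], seq_len(n)),
                           factor(code[e[, 1]], seq_len(K)))
        counts <- counts + as.matrix(unclass(inc))
    }
    if (include_self)
        counts[cbind(seq_len(n), code)] <- counts[cbind(seq_len(n), code)] + 1
    deg <- rowSums(counts)
    isolated <- graph@cellIds[deg == 0]
    keep <- deg > 0
    out <- counts[keep, , drop = FALSE] / deg[keep]
    dimnames(out) <- list(graph@cellIds[keep], lev)
    attr(out, "isolated") <- isolated
    out
}

.kmeansPlusPlusInit <- function(x, k) {
    n <- nrow(x)
    centers <- matrix(0, nrow = k, ncol = ncol(x))
    idx <- sample.int(n, 1L)
    centers[1L, ] <- x[idx, ]
    d2 <- rowSums((x - matrix(centers[1L, ], n, ncol(x), byrow = TRUE))^2)
    for (j in seq_len(k - 1L) + 1L) {
        if (sum(d2) == 0) idx <- sample.int(n, 1L)
        else idx <- sample.int(n, 1L, prob = d2)
        centers[j, ] <- x[idx, ]
        d2 <- pmin(d2, rowSums(
            (x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2))
    }
    centers
}

#' Cluster neighbor compositions into cellular neighborhoods
#'
#' k-means (Lloyd iterations, k-means++ seeding, `n_init` restarts keeping
#' the lowest within-cluster sum of squares) over the pooled neighbor
#' composition vectors of all patients and surgeries, so that CN labels are
#' comparable between timepoints. Deterministic under the seed.
#'
#' @param vectors cells x types composition matrix from
#'   [neighborComposition()].
#' @param k number of neighborhoods (default 12).
#' @param seed integer seed.
#' @param n_init number of k-means++ restarts.
#' @return A [NeighborhoodModel-class]; isolated cells carried in the
#'   `"isolated"` attribute of `vectors` get label `"isolated"`.
#' @export
fitNeighborhoods <- function(vectors, k = 12L, seed = 1L, n_init = 10L) {
    k <- as.integer(k)
    n_distinct <- nrow(unique(vectors))
    if (n_distinct < k)
        stop("only ", n_distinct, " distinct composition vectors; choose ",
             "k <= ", n_distinct)
    set.seed(seed)
    best <- NULL
    for (i in seq_len(n_init)) {
        init <- .kmeansPlusPlusInit(vectors, k)
        fit <- tryCatch(
            suppressWarnings(stats::kmeans(vectors, centers = init,
                                           iter.max = 100L,
                                           algorithm = "Lloyd")),
            error = function(e) NULL)  # rare degenerate restart; skip it
        if (is.null(fit)) next
        if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    if (is.null(best))
        stop("k-means failed in every restart; try a smaller k")
    centers <- best$centers
    centers[centers < 0] <- 0
    centers <- centers / rowSums(centers)
    dimnames(centers) <- list(paste0("CN", seq_len(k)), colnames(vectors))
    labels <- paste0("CN", best$cluster)
    names(labels) <- rownames(vectors)
    iso <- attr(vectors, "isolated")
    if (length(iso))
        labels <- c(labels, stats::setNames(rep("isolated", length(iso)), iso))
    new("NeighborhoodModel", k = k, centers = centers, labels = labels,
        inertia = best$tot.withinss, seed = as.integer(seed),
        nInit = as.integer(n_init))
}

setMethod("show", "NeighborhoodModel", function(object) {
    cat("NeighborhoodModel: k =", object@k, "over",
        ncol(object@centers), "types;", length(object@labels),
        "labeled cells; inertia", signif(object@inertia, 6), "\n")
    top <- colnames(object@centers)[apply(object@centers, 1L, which.max)]
    frac <- apply(object@centers, 1L, max)
    cat("  dominant types:",
        paste0(rownames(object@centers), ":", top,
               " (", round(100 * frac), "%)", collapse = ", "), "\n")
})

#' CN labels per cell
#'
#' @param model a [NeighborhoodModel-class].
#' @return Named character vector of CN labels.
#' @export
cnLabels <- function(model) model@labels

#' @rdname cnLabels
#' @export
cnCenters <- function(model) model@centers

#' Attach CN labels to a cell table
#'
#' @param table a `CellTable`.
#' @param model a fitted [NeighborhoodModel-class].
#' @return The `CellTable` with a `cn` column.
#' @export
addCNLabels <- function(table, model) {
    lab <- model@labels[colData(table)$cell_id]
    colData(table)$cn <- unname(lab)
    table
}

#' CN composition and prevalence summaries
#'
#' Per CN, the cell-type composition of its member cells; per surgery, the
#' relative proportion of cells in each CN (summing to 1 over CNs within a
#' surgery); and a per-CN primary-vs-recurrent Wilcoxon rank-sum comparison
#' across per-patient CN proportions. A CN absent from one surgery
#' contributes proportion 0 there.
#'
#' @param model a [NeighborhoodModel-class].
#' @param table the `CellTable` the model was fitted on.
#' @param type_column cell column with types (default `cell_type` falling
#'   back to `true_type`).
#' @return list: `composition` (CN x type fractions), `prevalence`
#'   (surgery x CN proportions), `tests` (per-CN Wilcoxon p).
#' @export
cnPrevalence <- function(model, table, type_column = NULL) {
    cd <- as.data.frame(colData(table))
    if (is.null(type_column))
        type_column <- if ("cell_type" %in% colnames(cd)) "cell_type"
                       else "true_type"
    lab <- model@labels[cd$cell_id]
    keep <- !is.na(lab) & lab != "isolated"
    cd <- cd[keep, , drop = FALSE]
    lab <- factor(lab[keep], levels = rownames(model@centers))
    comp <- base::table(lab, cd[[type_column]])
    comp <- comp / pmax(rowSums(comp), 1)
    prev <- base::table(cd$surgery, lab)
    prev <- prev / rowSums(prev)
    per_pat <- base::table(paste(cd$patient, cd$surgery, sep = "."), lab)
    per_pat <- per_pat / rowSums(per_pat)
    meta <- do.call(rbind, strsplit(rownames(per_pat), ".", fixed = TRUE))
    tests <- lapply(colnames(per_pat), function(cn) {
        x <- per_pat[meta[, 2] == "primary", cn]
        y <- per_pat[meta[, 2] == "recurrent", cn]
        p <- if (length(x) && length(y))
            suppressWarnings(stats::wilcox.test(x, y)$p.value) else NA_real_
        data.frame(cn = cn, mean_primary = mean(x), mean_recurrent = mean(y),
                   p = p)
    })
    list(composition = as.matrix(unclass(comp)),
         prevalence = as.matrix(unclass(prev)),
         tests = do.call(rbind, tests))
}
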