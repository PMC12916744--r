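#' Spatial-context specification
#'
#' @param window `"2-hop"` (the cell's graph neighbors and their neighbors,
#'   excluding the cell itself) or a numeric radius in micrometers.
#' @param dominance_threshold cumulative CN fraction a spatial context must
#'   reach (default 0.9).
#' @param min_patients dominant-SC filter: an SC must appear in strictly
#'   more than this many patients (default 3).
#' @param min_cell_fraction dominant-SC filter: an SC must cover strictly
#'   more than this fraction of the group's cells (default 0.05).
#' @return A list of class `"SCSpec"`.
#' @export
scSpec <- function(window = "2-hop", dominance_threshold = 0.9,
                   min_patients = 3L, min_cell_fraction = 0.05) {
    stopifnot(dominance_threshold > 0, dominance_threshold <= 1)
    structure(list(window = window,
                   dominance_threshold = dominance_threshold,
                   min_patients = as.integer(min_patients),
                   min_cell_fraction = min_cell_fraction),
              class = "SCSpec")
}

.windowNeighbors <- function(graph, spec) {
    n <- length(graph@cellIds)
    e <- graph@edges
    adj <- vector("list", n)
    for (i in seq_len(nrow(e))) {
        adj[[e[i, 1]]] <- c(adj[[e[i, 1]]], e[i, 2])
        adj[[e[i, 2]]] <- c(adj[[e[i, 2]]], e[i, 1])
    }
    if (is.numeric(spec$window)) {
        d <- as.matrix(stats::dist(graph@coords))
        lapply(seq_len(n), function(i)
            setdiff(which(d[i, ] <= spec$window), i))
    } else {
        lapply(seq_len(n), function(i) {
            w <- unique(c(adj[[i]], unlist(adj[adj[[i]]])))
            setdiff(w, i)
        })
    }
}

#' Assign the minimal dominant CN set per cell
#'
#' For every cell, the CN fractions over its wider spatial window are sorted
#' in decreasing order and the spatial context (SC) is the smallest prefix
#' whose cumulative fraction reaches the dominance threshold; the SC label is
#' the sorted CN set joined with `"&"`. Ties in CN fraction are broken by CN
#' name for determinism. Cells with an empty window get `NA`.
#'
#' @param table a `CellTable` with a `cn` column (see [addCNLabels()]).
#' @param graphs named list of per-ROI [SpatialGraph-class] objects.
#' @param spec an [scSpec()].
#' @return A [SpatialContextResult-class]; the per-cell labels are also
#'   returned in the `cells` slot.
#' @export
detectSpatialContexts <- function(table, graphs, spec = scSpec()) {
    cd <- as.data.frame(colData(table))
    if (is.null(cd$cn)) stop("no 'cn' column; run addCNLabels() first")
    cn <- stats::setNames(cd$cn, cd$cell_id)
    res <- lapply(names(graphs), function(k) {
        g <- graphs[[k]]
        win <- .windowNeighbors(g, spec)
        lab <- cn[g@cellIds]
        sc <- vapply(seq_along(win), function(i) {
            w <- win[[i]]
            wl <- lab[w]
            wl <- wl[!is.na(wl) & wl != "isolated"]
            if (!length(wl)) return(NA_character_)
            fr <- sort(base::table(wl) / length(wl), decreasing = TRUE)
            # deterministic tie-break: equal fractions ordered by CN name
            fr <- fr[order(-as.numeric(fr), names(fr))]
            m <- which(cumsum(fr) >= spec$dominance_threshold - 1e-12)[1]
            paste(sort(names(fr)[seq_len(m)]), collapse = "&")
        }, character(1))
        data.frame(cell_id = g@cellIds, sc = sc)
    })
    res <- do.call(rbind, res)
    cells <- DataFrame(cd[match(res$cell_id, cd$cell_id),
                          c("patient", "surgery", "roi", "cell_id")],
                       sc = res$sc)
    new("SpatialContextResult", cells = cells,
        threshold = spec$dominance_threshold,
        window = if (is.numeric(spec$window))
            paste0(spec$window, "um") else spec$window)
}

setMethod("show", "SpatialContextResult", function(object) {
    cat("SpatialContextResult:", nrow(object@cells), "cells,",
        length(unique(stats::na.omit(object@cells$sc))), "distinct SCs",
        "(threshold", object@threshold, ", window", object@window, ")\n")
})

#' Filter dominant spatial contexts
#'
#' Within each group (surgery by default), an SC is retained iff it is
#' present in strictly more than `min_patients` patients AND covers strictly
#' more than `min_cell_fraction` of the group's cells.
#'
#' @param result a [SpatialContextResult-class].
#' @param spec an [scSpec()].
#' @param group grouping column of the `cells` slot (default `"surgery"`).
#' @return data.frame: group, sc, n_patients, cell_fraction, retained.
#' @export
filterDominantSCs <- function(result, spec = scSpec(), group = "surgery") {
    cells <- as.data.frame(result@cells)
    cells <- cells[!is.na(cells$sc), , drop = FALSE]
    out <- lapply(split(cells, cells[[group]]), function(df) {
        tab <- base::table(df$sc)
        npat <- vapply(names(tab), function(s)
            length(unique(df$patient[df$sc == s])), 0L)
        data.frame(group = df[[group]][1], sc = names(tab),
                   n_patients = as.integer(npat),
                   cell_fraction = as.numeric(tab) / nrow(df))
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out$retained <- out$n_patients > spec$min_patients &
        out$cell_fraction > spec$min_cell_fraction
    out
}

#' Build the CN interaction network of one surgery
#'
#' Nodes are the CNs appearing in the surgery's retained spatial contexts;
#' an (undirected, simple) edge joins two CNs that co-occur in at least one
#' retained SC. Construction is idempotent and invariant to the order of the
#' retained-SC list.
#'
#' @param retained output of [filterDominantSCs()] (only rows with
#'   `retained = TRUE` are used), or a character vector of SC labels.
#' @param surgery which group to build (matched against the `group` column).
#' @param cell_counts optional named vector of per-CN cell counts to carry
#'   into the centrality table.
#' @return A [CNNetwork-class] (empty, with a warning, when nothing is
#'   retained).
#' @export
buildCNNetwork <- function(retained, surgery = "primary",
                           cell_counts = NULL) {
    if (is.character(retained)) {
        scs <- retained
    } else {
        scs <- retained$sc[retained$retained &
                               retained$group == surgery]
    }
    if (!length(scs)) {
        warning("no retained spatial contexts for surgery '", surgery, "'")
        g <- igraph::make_empty_graph(0, directed = FALSE)
        return(new("CNNetwork", graph = g, surgery = surgery,
                   centralities = data.frame(cn = character(),
                                             degree = numeric(),
                                             closeness = numeric(),
                                             betweenness = numeric(),
                                             n_cells = numeric())))
    }
    sets <- strsplit(unique(scs), "&", fixed = TRUE)
    nodes <- sort(unique(unlist(sets)))
    edges <- unique(do.call(rbind, lapply(sets, function(s) {
        if (length(s) < 2) return(NULL)
        cmb <- utils::combn(sort(s), 2L)
        t(cmb)
    })))
    g <- igraph::make_empty_graph(length(nodes), directed = FALSE)
    g <- igraph::set_vertex_attr(g, "name", value = nodes)
    if (!is.null(edges) && nrow(edges))
        g <- igraph::add_edges(g, t(matrix(match(edges, nodes),
                                           ncol = 2L)))
    g <- igraph::simplify(g)
    cent <- cnCentralities(g)
    cent$n_cells <- if (is.null(cell_counts)) NA_real_
                    else as.numeric(cell_counts[cent$cn])
    new("CNNetwork", graph = g, surgery = surgery, centralities = cent)
}

setMethod("show", "CNNetwork", function(object) {
    cat("CNNetwork (", object@surgery, "): ",
        igraph::vcount(object@graph), " CNs, ",
        igraph::ecount(object@graph), " edges\n", sep = "")
})

#' Degree, closeness and betweenness of a CN network
#'
#' Degree is the neighbor count. Closeness uses the Wasserman-Faust
#' component-size correction, `(r / (n - 1)) * (r / sum(d))` with `r` the
#' number of other vertices reachable from the node, so values are
#' comparable across disconnected graphs; singletons get 0. Betweenness is
#' the fraction of shortest paths passing through the node, normalized by
#' `(n - 1)(n - 2) / 2`.
#'
#' @param network a [CNNetwork-class] or an igraph object.
#' @return data.frame: cn, degree, closeness, betweenness.
#' @export
cnCentralities <- function(network) {
    g <- if (is(network, "CNNetwork")) network@graph else network
    n <- igraph::vcount(g)
    if (n == 0)
        return(data.frame(cn = character(), degree = numeric(),
                          closeness = numeric(), betweenness = numeric()))
    nm <- igraph::V(g)$name
    if (is.null(nm)) nm <- as.character(seq_len(n))
    deg <- as.numeric(igraph::degree(g))
    d <- igraph::distances(g)
    clo <- vapply(seq_len(n), function(i) {
        di <- d[i, -i]
        reach <- di[is.finite(di)]
        r <- length(reach)
        if (r == 0 || n == 1) return(0)
        (r / (n - 1)) * (r / sum(reach))
    }, 0)
    btw <- if (n > 2)
        as.numeric(igraph::betweenness(g, normalized = TRUE)) else rep(0, n)
    data.frame(cn = nm, degree = deg, closeness = clo, betweenness = btw)
}

#' Compare primary and recurrent CN networks
#'
#' Per-CN centrality deltas (recurrent minus primary; a CN absent from one
#' network contributes 0 there and is flagged), edge-set differences and
#' counts of surgery-specific edges, with optional CN annotation (see
#' [defaultCNAnnotation()]).
#'
#' @param primary,recurrent [CNNetwork-class] objects.
#' @param annotation optional data.frame with a `cn` column merged onto the
#'   deltas.
#' @return list: `deltas`, `edges_primary_only`, `edges_recurrent_only`,
#'   `edges_shared`, `counts`.
#' @export
compareNetworks <- function(primary, recurrent, annotation = NULL) {
    cp <- primary@centralities
    cr <- recurrent@centralities
    cns <- sort(union(cp$cn, cr$cn))
    get <- function(tab, cn, what) {
        i <- match(cn, tab$cn)
        ifelse(is.na(i), 0, tab[[what]][i])
    }
    deltas <- data.frame(
        cn = cns,
        in_primary = cns %in% cp$cn,
        in_recurrent = cns %in% cr$cn,
        delta_degree = get(cr, cns, "degree") - get(cp, cns, "degree"),
        delta_closeness = get(cr, cns, "closeness") -
            get(cp, cns, "closeness"),
        delta_betweenness = get(cr, cns, "betweenness") -
            get(cp, cns, "betweenness"))
    if (!is.null(annotation))
        deltas <- merge(deltas, annotation, by = "cn", all.x = TRUE,
                        sort = TRUE)
    etab <- function(net) {
        if (igraph::ecount(net@graph) == 0) return(character())
        el <- igraph::as_edgelist(net@graph)
        paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "--")
    }
    ep <- etab(primary); er <- etab(recurrent)
    list(deltas = deltas,
         edges_primary_only = setdiff(ep, er),
         edges_recurrent_only = setdiff(er, ep),
         edges_shared = intersect(ep, er),
         counts = c(primary_only = length(setdiff(ep, er)),
                    recurrent_only = length(setdiff(er, ep)),
                    shared = length(intersect(ep, er))))
}

#' Shipped CN annotation map
#'
#' Static default mapping of the twelve CNs to the transcriptional
#' metaprograms and structural layers of the reference GBM atlas (hypoxic
#' core, hypoxia-adjacent, angiogenesis/immune hub, astrocytic/neoplastic
#' transition, infiltrative brain). CN9 is dual-mapped (neuron and reactive
#' astrocyte) and carries both rows. Purely an annotation aid for network
#' figures; replace with your own map as needed.
#'
#' @return data.frame: cn, metaprogram, layer.
#' @export
defaultCNAnnotation <- function() {
    data.frame(
        cn = c("CN1", "CN2", "CN3", "CN4", "CN5", "CN6", "CN7", "CN8",
               "CN9", "CN9", "CN10", "CN11", "CN12"),
        metaprogram = c("Mac", "MES-Ast", "Oligo/OPC", "T-cell", "Vasc",
                        "MES-Hyp", "Neuron", "AC", "Neuron", "Reactive-Ast",
                        "T-cell", "Reactive-Ast", "Inflammatory-Mac"),
        layer = c(3L, 2L, 5L, 3L, 3L, 1L, 5L, 4L, 5L, 2L, 3L, 2L, 3L))
}
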