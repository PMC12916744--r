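#' Transform / normalization specification
#'
#' @param cofactor positive cofactor for the asinh transform (default 5, the
#'   standard choice for mass-cytometry intensities).
#' @param batch_key optional column of the cell data (e.g. `"patient"`); when
#'   set, z-scoring is computed within each batch instead of globally.
#' @param exclusion_quantile per-marker z threshold for the "broadly high"
#'   artifact filter, expressed as a normal quantile (default 0.99).
#' @param exclusion_min_marker_fraction fraction of markers that must exceed
#'   that threshold for a cell to be excluded (default 0.75).
#' @return A list of class `"TransformSpec"`.
#' @export
transformSpec <- function(cofactor = 5, batch_key = NULL,
                          exclusion_quantile = 0.99,
                          exclusion_min_marker_fraction = 0.75) {
    stopifnot(cofactor > 0, exclusion_quantile > 0, exclusion_quantile < 1)
    structure(list(cofactor = cofactor, batch_key = batch_key,
                   exclusion_quantile = exclusion_quantile,
                   exclusion_min_marker_fraction =
                       exclusion_min_marker_fraction),
              class = "TransformSpec")
}

#' asinh-transform raw marker intensities
#'
#' Adds an `"asinh"` assay holding `asinh(raw / cofactor)`. Raw intensities
#' must be non-negative; a negative value is reported with its cell and
#' marker.
#'
#' @param table a [CellTable-class].
#' @param spec a [transformSpec()].
#' @return The `CellTable` with an `"asinh"` assay.
#' @export
transformIntensities <- function(table, spec = transformSpec()) {
    raw <- rawIntensities(table)
    if (any(raw < 0)) {
        idx <- which(raw < 0, arr.ind = TRUE)[1, ]
        stop("data error: negative intensity for cell '",
             colnames(raw)[idx[2]], "', marker '", rownames(raw)[idx[1]], "'")
    }
    assay(table, "asinh") <- asinh(raw / spec$cofactor)
    table
}

#' Per-marker z-scoring of transformed intensities
#'
#' Adds a `"z"` assay: each marker centered and scaled across cells. With a
#' `batch_key` (e.g. per-patient standardization, the package's lightweight
#' stand-in for cross-patient batch alignment) the scaling is computed within
#' each batch. Zero-variance markers get z = 0.
#'
#' @param table a `CellTable` with an `"asinh"` assay.
#' @param batch_key optional cell-data column name.
#' @return The `CellTable` with a `"z"` assay.
#' @export
zScoreIntensities <- function(table, batch_key = NULL) {
    tr <- asinhIntensities(table)
    zs <- function(m) {
        mu <- rowMeans(m)
        sd <- apply(m, 1L, stats::sd)
        sd[sd == 0 | is.na(sd)] <- Inf
        (m - mu) / sd
    }
    if (is.null(batch_key)) {
        z <- zs(tr)
    } else {
        b <- colData(table)[[batch_key]]
        if (is.null(b)) stop("configuration error: no column '", batch_key, "'")
        z <- tr
        for (lev in unique(b)) z[, b == lev] <- zs(tr[, b == lev, drop = FALSE])
    }
    assay(table, "z") <- z
    table
}

#' Exclude cells with broadly high marker expression
#'
#' Segmentation artifacts (debris, doublets) show uniformly elevated signal.
#' A cell is excluded when its z-score exceeds the normal quantile
#' `exclusion_quantile` in at least `exclusion_min_marker_fraction` of the
#' markers. Survivors are re-z-scored, since the artifact cells inflate the
#' original scaling.
#'
#' @param table a `CellTable` with a `"z"` assay.
#' @param spec a [transformSpec()].
#' @return The filtered `CellTable`; excluded cell ids are recorded in
#'   `metadata(x)$excluded_cells`.
#' @export
excludeBroadlyHigh <- function(table, spec = transformSpec()) {
    z <- zScores(table)
    cut <- stats::qnorm(spec$exclusion_quantile)
    frac_high <- colMeans(z > cut)
    drop <- frac_high >= spec$exclusion_min_marker_fraction
    if (all(drop))
        stop("pipeline error: the exclusion rule removed every cell")
    excluded <- colnames(z)[drop]
    out <- table[, !drop]
    out <- zScoreIntensities(out, batch_key = spec$batch_key)
    md <- metadata(out)
    md$excluded_cells <- excluded
    metadata(out) <- md
    out
}

#' Gating rules for marker-based cell typing
#'
#' A rule names a cell type, its category, the markers that must be high
#' (z above the high gate) and low (z below the low gate), and a priority
#' rank; cells are tested against rules in priority order and take the first
#' match.
#'
#' @param cell_type,category labels.
#' @param required_high,required_low character vectors of marker names
#'   (disjoint).
#' @param priority unique numeric rank (lower = tried earlier).
#' @return One-row data.frame; combine rule rows with `rbind()`.
#' @export
gatingRule <- function(cell_type, category, required_high,
                       required_low = character(), priority) {
    if (length(intersect(required_high, required_low)))
        stop("required_high and required_low must be disjoint")
    data.frame(cell_type = cell_type, category = category,
               required_high = paste(required_high, collapse = ";"),
               required_low = paste(required_low, collapse = ";"),
               priority = priority)
}

#' The shipped default gating rule set
#'
#' Covers the four categories and the thirteen cell types of the default
#' signatures: five immune types gated on CD45 plus a lineage marker,
#' endothelium on CD31/CD34, the four neoplastic GBM states (AC, MES, NPC,
#' OPC) on glioma markers, then the normal brain types. Cancer rules precede
#' normal-brain rules so that e.g. EGFR+/SOX2+ astrocytic cancer cells are
#' not captured by the astrocyte rule. The set is a replaceable default, not
#' a fixed truth: any rule table with the same columns works.
#'
#' @return data.frame of gating rules (one per cell type).
#' @export
defaultGatingRules <- function() {
    rbind(
        gatingRule("macrophage", "immune", c("CD45", "CD68"),
                   c("TMEM119", "GFAP"), 1),
        gatingRule("microglia", "immune", c("CD45", "TMEM119", "P2RY12"),
                   "GFAP", 2),
        gatingRule("t_cell", "immune", c("CD45", "CD3"), "CD68", 3),
        gatingRule("nk_cell", "immune", c("CD45", "NCR1"), "CD3", 4),
        gatingRule("neutrophil", "immune", c("CD45", "MPO"),
                   c("CD3", "CD68"), 5),
        gatingRule("endothelial", "vasculature", c("CD31", "CD34"),
                   "CD45", 6),
        gatingRule("AC", "cancer", c("GFAP", "EGFR", "SOX2"),
                   c("CD45", "RBFOX3"), 7),
        gatingRule("MES", "cancer", c("CD44", "VIM"),
                   c("CD45", "MOG", "RBFOX3"), 8),
        gatingRule("NPC", "cancer", c("SOX2", "NESTIN", "DLL3"),
                   c("GFAP", "CD45"), 9),
        gatingRule("OPC", "cancer", c("OLIG2", "PDGFRA", "SOX2"),
                   c("MOG", "CD45"), 10),
        gatingRule("astrocyte", "normal brain", c("GFAP", "AQP4", "S100B"),
                   c("SOX2", "EGFR", "CD45"), 11),
        gatingRule("neuron", "normal brain", c("RBFOX3", "MAP2", "SYP"),
                   c("GFAP", "CD45"), 12),
        gatingRule("oligodendrocyte", "normal brain", c("MOG", "CNP"),
                   c("CD45", "GFAP"), 13))
}

.splitMarkers <- function(s) if (!nzchar(s)) character() else
    strsplit(s, ";", fixed = TRUE)[[1]]

#' Assign cell types by priority-ordered logical gating
#'
#' Each cell is tested against the rules in increasing priority rank; the
#' first rule whose `required_high` markers all have z strictly above
#' `gate_hi` and whose `required_low` markers all have z strictly below
#' `gate_lo` assigns the type and category. Cells matching no rule are
#' `"unassigned"`. Assignment is invariant to cell order and to any affine
#' rescaling of raw intensities absorbed by the z-scoring.
#'
#' @param table a `CellTable` with a `"z"` assay.
#' @param rules a rule table as from [defaultGatingRules()].
#' @param gate_hi,gate_lo z-score gates for high/low requirements (default
#'   0.5 both; configurable, not a cohort-derived estimate).
#' @return The `CellTable` with `cell_type` and `category` columns.
#' @export
assignTypes <- function(table, rules = defaultGatingRules(),
                        gate_hi = 0.5, gate_lo = 0.5) {
    z <- zScores(table)
    if (nrow(rules)) {
        if (anyDuplicated(rules$priority))
            stop("configuration error: rule priorities must be unique")
        rules <- rules[order(rules$priority), , drop = FALSE]
        all_m <- unique(unlist(lapply(
            c(rules$required_high, rules$required_low), .splitMarkers)))
        unknown <- setdiff(all_m, rownames(z))
        if (length(unknown))
            stop("configuration error: rule references unknown marker(s): ",
                 paste(unknown, collapse = ", "))
    }
    n <- ncol(z)
    type <- rep("unassigned", n)
    category <- rep("unassigned", n)
    undecided <- rep(TRUE, n)
    for (i in seq_len(nrow(rules))) {
        hi <- .splitMarkers(rules$required_high[i])
        lo <- .splitMarkers(rules$required_low[i])
        ok <- undecided
        for (m in hi) ok <- ok & (z[m, ] > gate_hi)
        for (m in lo) ok <- ok & (z[m, ] < gate_lo)
        type[ok] <- rules$cell_type[i]
        category[ok] <- rules$category[i]
        undecided <- undecided & !ok
    }
    colData(table)$cell_type <- type
    colData(table)$category <- category
    table
}

#' State-call thresholds
#'
#' @param hi_cut,lo_cut z-score cutoffs (defaults +1.2 / -1.2); calls use
#'   strict inequalities.
#' @param hypoxia_marker marker defining hypoxia (default HIF1A).
#' @param emt_markers markers defining EMT (default SNAI1; adding TGFBeta
#'   makes the call conjunctive over both).
#' @return A list of class `"StateThresholds"`.
#' @export
stateThresholds <- function(hi_cut = 1.2, lo_cut = -1.2,
                            hypoxia_marker = "HIF1A",
                            emt_markers = "SNAI1") {
    stopifnot(lo_cut < hi_cut)
    structure(list(hi_cut = hi_cut, lo_cut = lo_cut,
                   hypoxia_marker = hypoxia_marker,
                   emt_markers = emt_markers),
              class = "StateThresholds")
}

#' Call per-cell hypoxia and EMT states
#'
#' A cell is hypoxic when z(HIF1A) is strictly above `hi_cut`, and EMT when
#' every configured EMT marker (default SNAI1 alone) is strictly above
#' `hi_cut`.
#'
#' @param table a `CellTable` with a `"z"` assay.
#' @param thresholds a [stateThresholds()].
#' @return The `CellTable` with logical `hypoxic` and `emt` columns.
#' @export
callStates <- function(table, thresholds = stateThresholds()) {
    z <- zScores(table)
    need <- c(thresholds$hypoxia_marker, thresholds$emt_markers)
    missing_m <- setdiff(need, rownames(z))
    if (length(missing_m))
        stop("configuration error: state marker(s) absent from panel: ",
             paste(missing_m, collapse = ", "))
    colData(table)$hypoxic <- z[thresholds$hypoxia_marker, ] > thresholds$hi_cut
    emt <- rep(TRUE, ncol(table))
    for (m in thresholds$emt_markers) emt <- emt & (z[m, ] > thresholds$hi_cut)
    colData(table)$emt <- emt
    table
}

#' Fraction of state-positive cells per group and cell type
#'
#' Tabulates, per cell type within each group, the fraction of cells carrying
#' the given state flag, and compares primary vs recurrent per cell type with
#' a two-sided Wilcoxon rank-sum test. The default unit is the per-cell
#' binary indicator (matching per-cell comparisons on large n); `unit =
#' "roi"` instead compares per-ROI fractions.
#'
#' @param table a `CellTable` with states called and types assigned.
#' @param state `"hypoxic"` or `"emt"` (any logical cell column).
#' @param types optional subset of cell types to report.
#' @param unit `"cell"` or `"roi"`.
#' @return list with `fractions` (group x type table; groups with zero cells
#'   of a type give NA, not 0) and `tests` (per-type Wilcoxon p-values).
#' @export
stateFractionByGroup <- function(table, state = "hypoxic", types = NULL,
                                 unit = c("cell", "roi")) {
    unit <- match.arg(unit)
    cd <- as.data.frame(colData(table))
    if (is.null(cd[[state]]))
        stop("configuration error: no state column '", state, "'")
    if (is.null(cd$cell_type)) stop("assign types first")
    if (!is.null(types)) cd <- cd[cd$cell_type %in% types, , drop = FALSE]
    grid <- expand.grid(surgery = unique(cd$surgery),
                        cell_type = unique(cd$cell_type),
                        stringsAsFactors = FALSE)
    agg <- stats::aggregate(cd[[state]],
                            by = list(surgery = cd$surgery,
                                      cell_type = cd$cell_type),
                            FUN = mean)
    names(agg)[3] <- "fraction"
    # absent (surgery, type) combinations are undefined, reported as NA
    agg <- merge(grid, agg, all.x = TRUE, sort = TRUE)
    tests <- lapply(unique(agg$cell_type), function(ty) {
        sub <- cd[cd$cell_type == ty, , drop = FALSE]
        pri <- sub[sub$surgery == "primary", , drop = FALSE]
        rec <- sub[sub$surgery == "recurrent", , drop = FALSE]
        if (!nrow(pri) || !nrow(rec))
            return(data.frame(cell_type = ty, p = NA_real_))
        if (unit == "cell") {
            xs <- as.numeric(pri[[state]]); ys <- as.numeric(rec[[state]])
        } else {
            xs <- tapply(pri[[state]], paste(pri$patient, pri$roi), mean)
            ys <- tapply(rec[[state]], paste(rec$patient, rec$roi), mean)
        }
        p <- tryCatch(stats::wilcox.test(xs, ys, exact = FALSE)$p.value,
                      error = function(e) NA_real_)
        data.frame(cell_type = ty, p = p)
    })
    list(fractions = agg, tests = do.call(rbind, tests))
}
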