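#' Shannon entropy of a type-count vector
#'
#' H = -sum(p_i * ln p_i) over types with p_i > 0, natural log. Bounded by
#' 0 <= H <= ln(K) for K observed types, and invariant to type relabeling.
#'
#' @param type_counts non-negative counts (a named vector or `table`).
#' @return H in nats.
#' @examples
#' shannonEntropy(c(a = 2, b = 2, c = 4))  # ~ 1.0397
#' @export
shannonEntropy <- function(type_counts) {
    type_counts <- as.numeric(type_counts)
    if (any(type_counts < 0)) stop("counts must be non-negative")
    tot <- sum(type_counts)
    if (tot == 0) stop("entropy undefined: total count is zero")
    p <- type_counts[type_counts > 0] / tot
    -sum(p * log(p))
}

#' Subsampling specification for per-ROI entropy
#'
#' Defaults follow the standard protocol of 1,000 randomly sampled cells per
#' ROI over 10 iterations; sampling is without replacement, and ROIs smaller
#' than the subsample take all their cells (the iteration is still repeated,
#' so such ROIs contribute identical values).
#'
#' @param subsample_size cells sampled per ROI per iteration.
#' @param iterations number of iterations.
#' @param seed integer seed.
#' @return A list of class `"EntropySpec"`.
#' @export
entropySpec <- function(subsample_size = 1000L, iterations = 10L, seed = 1L) {
    stopifnot(subsample_size >= 1, iterations >= 1)
    structure(list(subsample_size = as.integer(subsample_size),
                   iterations = as.integer(iterations),
                   seed = as.integer(seed)),
              class = "EntropySpec")
}

#' Subsampled Shannon entropy per ROI
#'
#' For every ROI and iteration, samples `subsample_size` cells without
#' replacement and computes the Shannon entropy of their cell-type counts.
#' Deterministic under the spec's seed.
#'
#' @param table a `CellTable`; uses `cell_type` if assigned, else
#'   `true_type`.
#' @param spec an [entropySpec()].
#' @param type_column which cell column holds the type labels.
#' @return data.frame: patient, surgery, roi, iteration, H.
#' @export
subsampledEntropy <- function(table, spec = entropySpec(),
                              type_column = NULL) {
    cd <- as.data.frame(colData(table))
    if (is.null(type_column))
        type_column <- if ("cell_type" %in% colnames(cd)) "cell_type"
                       else "true_type"
    if (is.null(cd[[type_column]]))
        stop("no type column '", type_column, "'")
    keys <- roiKeys(table)
    set.seed(spec$seed)
    out <- lapply(unique(keys), function(k) {
        idx <- which(keys == k)
        types <- cd[[type_column]][idx]
        m <- min(spec$subsample_size, length(idx))
        H <- vapply(seq_len(spec$iterations), function(it)
            shannonEntropy(base::table(types[sample.int(length(idx), m)])), 0)
        data.frame(patient = cd$patient[idx[1]],
                   surgery = cd$surgery[idx[1]],
                   roi = cd$roi[idx[1]],
                   iteration = seq_len(spec$iterations), H = H)
    })
    do.call(rbind, out)
}

#' Compare entropy between surgeries
#'
#' Two-sided Wilcoxon rank-sum on subsampled entropy values, primary versus
#' recurrent. At the cohort level all values are pooled by surgery; at the
#' patient level each patient is tested separately and p-values are
#' Benjamini-Hochberg adjusted across patients (reported as `q`). The default
#' observation unit is the per-ROI x iteration value; `unit = "roi"` first
#' averages iterations within each ROI.
#'
#' @param result output of [subsampledEntropy()].
#' @param level `"cohort"` or `"patient"`.
#' @param unit `"iteration"` or `"roi"`.
#' @return data.frame with group, n per arm, median difference
#'   (recurrent - primary), p and q.
#' @export
compareEntropy <- function(result, level = c("cohort", "patient"),
                           unit = c("iteration", "roi")) {
    level <- match.arg(level)
    unit <- match.arg(unit)
    if (unit == "roi") {
        result <- stats::aggregate(
            H ~ patient + surgery + roi, data = result, FUN = mean)
    }
    one <- function(df, label) {
        x <- df$H[df$surgery == "primary"]
        y <- df$H[df$surgery == "recurrent"]
        if (!length(x) || !length(y))
            stop("both surgeries must be present for group '", label, "'")
        if (length(x) < 2 || length(y) < 2)
            stop("too few observations per arm for a rank-sum test in ",
                 "group '", label, "' (need >= 2 per surgery at this ",
                 "grouping; use unit = 'iteration' or pool ROIs)")
        p <- stats::wilcox.test(x, y, exact = FALSE)$p.value
        data.frame(group = label, n_primary = length(x),
                   n_recurrent = length(y),
                   delta_median = stats::median(y) - stats::median(x), p = p)
    }
    if (level == "cohort") {
        out <- one(result, "cohort")
        out$q <- out$p
    } else {
        out <- do.call(rbind, lapply(split(result, result$patient),
                                     function(df) one(df, df$patient[1])))
        out$q <- stats::p.adjust(out$p, method = "BH")
        rownames(out) <- NULL
    }
    out
}

#' Partition composition variance across patient and surgery
#'
#' For each cell category (or type), computes the per-ROI proportion and fits
#' a two-factor ANOVA `proportion ~ patient + surgery`; the residual captures
#' ROI-to-ROI (intra-tumor) variability. Zero-variance responses are flagged
#' degenerate rather than tested.
#'
#' @param table a `CellTable` with types/categories assigned (or planted).
#' @param granularity `"category"` or `"type"`.
#' @param type_column override the cell column used for grouping.
#' @return data.frame: group, F and p for patient and surgery effects,
#'   residual df, degenerate flag.
#' @export
compositionVariance <- function(table, granularity = c("category", "type"),
                                type_column = NULL) {
    granularity <- match.arg(granularity)
    cd <- as.data.frame(colData(table))
    if (is.null(type_column)) {
        type_column <- if (granularity == "category") {
            if ("category" %in% colnames(cd)) "category" else
                stop("no category column; run assignTypes() first")
        } else {
            if ("cell_type" %in% colnames(cd)) "cell_type" else "true_type"
        }
    }
    if (length(unique(cd$patient)) < 2)
        stop("need >= 2 patients")
    rk <- paste(cd$patient, cd$surgery, cd$roi, sep = ".")
    n_roi_per_sample <- base::table(unique(data.frame(
        s = paste(cd$patient, cd$surgery), r = rk))$s)
    if (any(n_roi_per_sample < 2))
        stop("need >= 2 ROIs per patient x surgery for a residual term")
    groups <- sort(unique(cd[[type_column]]))
    tab <- base::table(rk, cd[[type_column]])
    prop <- tab / rowSums(tab)
    meta <- do.call(rbind, strsplit(rownames(tab), ".", fixed = TRUE))
    out <- lapply(groups, function(g) {
        df <- data.frame(prop = prop[, g], patient = meta[, 1],
                         surgery = meta[, 2])
        if (stats::var(df$prop) < .Machine$double.eps)
            return(data.frame(group = g, F_patient = NA, p_patient = NA,
                              F_surgery = NA, p_surgery = NA,
                              df_residual = NA, degenerate = TRUE))
        fit <- stats::aov(prop ~ patient + surgery, data = df)
        s <- summary(fit)[[1]]
        data.frame(group = g,
                   F_patient = s["patient", "F value"],
                   p_patient = s["patient", "Pr(>F)"],
                   F_surgery = s["surgery", "F value"],
                   p_surgery = s["surgery", "Pr(>F)"],
                   df_residual = s["Residuals", "Df"],
                   degenerate = FALSE)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}
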