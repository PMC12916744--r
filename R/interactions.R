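#' Permutation-test specification for cell-cell interactions
#'
#' Defaults follow the standard protocol: 1,000 label shuffles, significance
#' at P < .01, cross-patient consistency requiring at least 3 patients, and
#' within-patient consistency requiring significance in a majority of that
#' patient's ROIs (2 of 3 by default).
#'
#' @param n_permutations label shuffles per graph (>= 1).
#' @param alpha one-sided significance level (0 < alpha < 1).
#' @param variant `"at_least_one_normalized"` (links from A to B divided by
#'   the number of A cells with at least one B neighbor) or `"classic"`
#'   (divided by the number of A cells).
#' @param min_patients patients in which a pair must be significant, with the
#'   same direction, to be retained by [aggregateCalls()].
#' @param min_rois ROIs (per patient x surgery) in which a pair must be
#'   significant for a per-patient call.
#' @param seed integer seed for the permutations.
#' @return A list of class `"InteractionSpec"`.
#' @export
interactionSpec <- function(n_permutations = 1000L, alpha = 0.01,
                            variant = c("at_least_one_normalized", "classic"),
                            min_patients = 3L, min_rois = 2L, seed = 1L) {
    stopifnot(n_permutations >= 1, alpha > 0, alpha < 1)
    variant <- match.arg(variant)
    structure(list(n_permutations = as.integer(n_permutations),
                   alpha = alpha, variant = variant,
                   min_patients = as.integer(min_patients),
                   min_rois = as.integer(min_rois),
                   seed = as.integer(seed)),
              class = "InteractionSpec")
}

.labelCodes <- function(graph, labels) {
    lab <- labels[graph@cellIds]
    if (any(is.na(lab)))
        stop("labels must cover all graph nodes")
    lev <- sort(unique(as.character(lab)))
    list(codes = match(as.character(lab), lev), levels = lev)
}

#' Pairwise adjacency statistic
#'
#' For an ordered type pair (A, B) on one ROI graph: the total number of
#' directed A->B neighbor links, normalized either by the number of A cells
#' (`"classic"`) or by the number of A cells having at least one B neighbor
#' (`"at_least_one_normalized"`). Undefined (NA) when the denominator is
#' zero.
#'
#' @param graph a [SpatialGraph-class].
#' @param labels named character vector of cell-type labels (names = cell
#'   ids), covering all nodes.
#' @param typeA,typeB type labels.
#' @param variant statistic variant.
#' @return The statistic (numeric scalar, possibly NA).
#' @export
pairStatistic <- function(graph, labels, typeA, typeB,
                          variant = c("at_least_one_normalized", "classic")) {
    variant <- match.arg(variant)
    lc <- .labelCodes(graph, labels)
    e <- graph@edges
    la <- lc$levels[lc$codes[e[, 1]]]
    lb <- lc$levels[lc$codes[e[, 2]]]
    links <- sum(la == typeA & lb == typeB) + sum(lb == typeA & la == typeB)
    if (variant == "classic") {
        nA <- sum(lc$levels[lc$codes] == typeA)
        if (nA == 0) return(NA_real_)
        links / nA
    } else {
        isA <- lc$levels[lc$codes] == typeA
        hasB <- logical(length(lc$codes))
        bmatch <- lb == typeB
        hasB[e[bmatch, 1]] <- TRUE
        amatch <- la == typeB
        hasB[e[amatch, 2]] <- TRUE
        nAq <- sum(isA & hasB)
        if (nAq == 0) return(NA_real_)
        links / nAq
    }
}

#' Permutation test of interaction/avoidance for all ordered type pairs
#'
#' The observed statistic for every ordered pair is compared against a null
#' obtained by uniformly permuting the type labels across the ROI's cells
#' (preserving the type multiset) `n_permutations` times. Empirical one-sided
#' p-values use the add-one estimator `p = (b + 1) / (m + 1)`, which never
#' returns 0 and has floor `1 / (n_permutations + 1)` (~9.99e-4 at 1,000
#' shuffles). A pair is called `"interacting"` when `p_interact < alpha`,
#' `"avoiding"` when `p_avoid < alpha`, otherwise `"ns"`. Pairs whose
#' observed statistic is undefined are excluded with a reason.
#'
#' @param graph a [SpatialGraph-class].
#' @param labels named character vector of types covering all nodes.
#' @param spec an [interactionSpec()]; `spec$seed` (xor an explicit `seed`)
#'   makes the permutations reproducible.
#' @param seed optional seed overriding `spec$seed`; `NULL` uses the current
#'   RNG state.
#' @return data.frame: typeA, typeB, observed, null_mean, p_interact,
#'   p_avoid, call.
#' @export
permutationTest <- function(graph, labels, spec = interactionSpec(),
                            seed = spec$seed) {
    lc <- .labelCodes(graph, labels)
    K <- length(lc$levels)
    m <- spec$n_permutations
    if (!is.null(seed)) set.seed(seed)
    cnt <- perm_pair_counts(graph@edges, as.integer(lc$codes), K, m)
    nA <- tabulate(lc$codes, K)
    out <- vector("list", K * K)
    for (a in seq_len(K)) {
        for (b in seq_len(K)) {
            col <- (a - 1L) * K + b
            num <- cnt$num[, col]
            den <- if (spec$variant == "classic") rep(nA[a], m + 1L)
                   else cnt$denom[, col]
            stat <- ifelse(den > 0, num / den, NA_real_)
            obs <- stat[1]
            null <- stat[-1]
            if (is.na(obs)) {
                out[[col]] <- data.frame(
                    typeA = lc$levels[a], typeB = lc$levels[b],
                    observed = NA_real_, null_mean = NA_real_,
                    p_interact = NA_real_, p_avoid = NA_real_,
                    call = "undefined")
                next
            }
            # permutations with an undefined statistic contribute a zero
            # observed intensity (no qualifying A cell): count them in the
            # lower tail
            null0 <- ifelse(is.na(null), 0, null)
            p_int <- (sum(null0 >= obs) + 1) / (m + 1)
            p_avd <- (sum(null0 <= obs) + 1) / (m + 1)
            call <- if (p_int < spec$alpha) "interacting"
                    else if (p_avd < spec$alpha) "avoiding" else "ns"
            out[[col]] <- data.frame(
                typeA = lc$levels[a], typeB = lc$levels[b], observed = obs,
                null_mean = mean(null0), p_interact = p_int, p_avoid = p_avd,
                call = call)
        }
    }
    do.call(rbind, out)
}

#' Interaction tests across a whole cohort
#'
#' Runs [permutationTest()] on every ROI graph, then combines ROIs into a
#' per-patient, per-surgery call: a pair is significant for a patient when
#' the same directional call reaches significance in at least `min_rois` of
#' that patient's ROIs.
#'
#' @param table a `CellTable` with types assigned (or planted truth).
#' @param graphs named list of [SpatialGraph-class] from
#'   [buildSpatialGraph()].
#' @param spec an [interactionSpec()].
#' @param type_column cell column holding the labels (default `cell_type`
#'   falling back to `true_type`).
#' @return list with `roi` (per-ROI results) and `patient` (per patient x
#'   surgery x pair call table).
#' @export
testInteractions <- function(table, graphs, spec = interactionSpec(),
                             type_column = NULL) {
    cd <- as.data.frame(colData(table))
    if (is.null(type_column))
        type_column <- if ("cell_type" %in% colnames(cd)) "cell_type"
                       else "true_type"
    labels <- stats::setNames(as.character(cd[[type_column]]), cd$cell_id)
    keys <- roiKeys(table)
    roi_res <- list()
    for (k in names(graphs)) {
        idx <- which(keys == k)
        res <- permutationTest(graphs[[k]], labels, spec,
                               seed = spec$seed + match(k, names(graphs)))
        res$patient <- cd$patient[idx[1]]
        res$surgery <- cd$surgery[idx[1]]
        res$roi <- cd$roi[idx[1]]
        roi_res[[k]] <- res
    }
    roi <- do.call(rbind, c(roi_res, list(make.row.names = FALSE)))
    roi$sig_call <- ifelse(roi$call %in% c("interacting", "avoiding"),
                           roi$call, NA)
    agg <- stats::aggregate(
        cbind(n_rois = call != "undefined",
              n_interacting = call == "interacting",
              n_avoiding = call == "avoiding") ~
            patient + surgery + typeA + typeB,
        data = roi, FUN = sum)
    agg$call <- ifelse(agg$n_interacting >= spec$min_rois, "interacting",
                ifelse(agg$n_avoiding >= spec$min_rois, "avoiding", "ns"))
    list(roi = roi, patient = agg)
}

#' Aggregate per-patient calls into cross-patient consistency classes
#'
#' A pair is retained within a surgery when at least `min_patients` patients
#' share the same significant call there. Retained pairs are classified as
#' `primary-only`, `recurrent-only`, `both` (same call in both surgeries) or
#' `changed` (interacting in one surgery, avoiding in the other).
#'
#' @param results the `patient` table from [testInteractions()] (or any
#'   data.frame with patient, surgery, typeA, typeB, call).
#' @param spec an [interactionSpec()].
#' @return data.frame: typeA, typeB, call_primary, call_recurrent,
#'   n_patients_primary, n_patients_recurrent, classification.
#' @export
aggregateCalls <- function(results, spec = interactionSpec()) {
    empty <- data.frame(typeA = character(), typeB = character(),
                        call_primary = character(),
                        call_recurrent = character(),
                        n_patients_primary = integer(),
                        n_patients_recurrent = integer(),
                        classification = character())
    sig <- results[results$call %in% c("interacting", "avoiding"), ,
                   drop = FALSE]
    if (!nrow(sig)) return(empty)
    cnt <- stats::aggregate(
        patient ~ surgery + typeA + typeB + call, data = sig,
        FUN = function(p) length(unique(p)))
    names(cnt)[names(cnt) == "patient"] <- "n_patients"
    cnt <- cnt[cnt$n_patients >= spec$min_patients, , drop = FALSE]
    if (!nrow(cnt)) return(empty)
    pairs <- unique(cnt[, c("typeA", "typeB")])
    out <- lapply(seq_len(nrow(pairs)), function(i) {
        sub <- cnt[cnt$typeA == pairs$typeA[i] & cnt$typeB == pairs$typeB[i], ]
        getcall <- function(s) {
            r <- sub[sub$surgery == s, , drop = FALSE]
            if (!nrow(r)) list(call = "ns", n = 0L)
            else {
                r <- r[which.max(r$n_patients), ]
                list(call = r$call, n = r$n_patients)
            }
        }
        p <- getcall("primary"); r <- getcall("recurrent")
        classification <-
            if (p$call != "ns" && r$call == "ns") "primary-only"
            else if (p$call == "ns" && r$call != "ns") "recurrent-only"
            else if (p$call == r$call) "both"
            else "changed"
        data.frame(typeA = pairs$typeA[i], typeB = pairs$typeB[i],
                   call_primary = p$call, call_recurrent = r$call,
                   n_patients_primary = p$n, n_patients_recurrent = r$n,
                   classification = classification)
    })
    out <- do.call(rbind, out)
    out[order(out$typeA, out$typeB), , drop = FALSE]
}
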