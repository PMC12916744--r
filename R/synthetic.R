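#' The default 34-marker panel
#'
#' Marker names used by the shipped type signatures and gating rules: immune
#' lineage (CD45, CD68, CD163, IBA1, TMEM119, P2RY12, CD3, CD4, CD8a, NCR1,
#' MPO), proliferation (KI67), glioma/neural (GFAP, EGFR, SOX2, NESTIN,
#' OLIG2, PDGFRA, DLL3, CD44, VIM, S100B, AQP4), neuronal (RBFOX3, MAP2,
#' SYP), oligodendrocyte (MOG, CNP), vascular (CD31, CD34, SMA) and state
#' markers (TGFBeta, HIF1A, SNAI1).
#'
#' @return Character vector of 34 marker names.
#' @export
defaultMarkerPanel <- function() {
    c("CD45", "CD68", "CD163", "IBA1", "TMEM119", "P2RY12", "CD3", "CD4",
      "CD8a", "NCR1", "MPO", "KI67", "GFAP", "EGFR", "SOX2", "NESTIN",
      "OLIG2", "PDGFRA", "DLL3", "CD44", "VIM", "S100B", "AQP4", "RBFOX3",
      "MAP2", "SYP", "MOG", "CNP", "CD31", "CD34", "SMA", "TGFBeta",
      "HIF1A", "SNAI1")
}

.CATEGORIES <- c("immune", "cancer", "normal brain", "vasculature")

#' Cohort design for the synthetic generator
#'
#' Mirrors the study layout by default: 5 patients, paired primary/recurrent
#' surgeries, 3 ROIs per sample, 1,000 um square ROIs and ~3,500 cells per
#' ROI. `patient_effect_sd` adds per-patient lognormal jitter to the type
#' proportions (shared across that patient's surgeries) so that inter-patient
#' compositional heterogeneity dominates intra-patient heterogeneity, as in
#' real cohorts; set it to 0 for exact nominal proportions.
#'
#' @param n_patients number of patients (>= 1).
#' @param surgeries ordered surgery labels.
#' @param rois_per_sample ROIs per patient x surgery (>= 1).
#' @param roi_side ROI side length in micrometers (> 0).
#' @param cells_per_roi cells per ROI (>= 1).
#' @param seed integer master seed; identical seeds give bit-identical output.
#' @param patient_effect_sd sd of the per-patient log-proportion jitter.
#' @return A list of class `"CohortDesign"`.
#' @export
cohortDesign <- function(n_patients = 5L, surgeries = c("primary", "recurrent"),
                         rois_per_sample = 3L, roi_side = 1000,
                         cells_per_roi = 3500L, seed = 1L,
                         patient_effect_sd = 0.25) {
    stopifnot(n_patients >= 1, rois_per_sample >= 1, roi_side > 0,
              cells_per_roi >= 1, length(surgeries) >= 1,
              patient_effect_sd >= 0)
    if (!all(surgeries %in% .SURGERIES))
        stop("surgeries must be drawn from {primary, recurrent}")
    structure(list(n_patients = as.integer(n_patients),
                   surgeries = surgeries,
                   rois_per_sample = as.integer(rois_per_sample),
                   roi_side = roi_side,
                   cells_per_roi = as.integer(cells_per_roi),
                   seed = as.integer(seed),
                   patient_effect_sd = patient_effect_sd),
              class = "CohortDesign")
}

#' Define a cell-type signature
#'
#' A signature fixes a type's marker intensity distribution (lognormal: raw
#' intensity ~ Lognormal(log(location), dispersion), with elevated locations
#' for the type's characteristic markers), its spatial placement mode and its
#' expected proportion in each surgery.
#'
#' @param cell_type type label.
#' @param category one of immune, cancer, normal brain, vasculature.
#' @param high_markers markers elevated in this type.
#' @param proportions named numeric, expected proportion per surgery.
#' @param spatial_mode `"uniform"` or `"clustered"`.
#' @param n_foci,focus_sd number of spatial foci and isotropic Gaussian sd
#'   (um) used when `spatial_mode = "clustered"`.
#' @param base_loc,high_loc lognormal location (natural scale) for background
#'   and elevated markers.
#' @param dispersion lognormal scale (log scale), recycled over markers.
#' @param markers the marker panel.
#' @return A list of class `"TypeSignature"`.
#' @export
typeSignature <- function(cell_type, category, high_markers = character(),
                          proportions, spatial_mode = c("uniform", "clustered"),
                          n_foci = 5L, focus_sd = 50, base_loc = 1.5,
                          high_loc = 25, dispersion = 0.35,
                          markers = defaultMarkerPanel()) {
    spatial_mode <- match.arg(spatial_mode)
    if (!category %in% .CATEGORIES)
        stop("unknown category: ", category)
    bad <- setdiff(high_markers, markers)
    if (length(bad)) stop("unknown marker(s): ", paste(bad, collapse = ", "))
    means <- stats::setNames(rep(base_loc, length(markers)), markers)
    means[high_markers] <- high_loc
    disp <- stats::setNames(rep_len(dispersion, length(markers)), markers)
    if (any(disp <= 0)) stop("dispersions must be positive")
    structure(list(cell_type = cell_type, category = category,
                   marker_means = means, marker_dispersion = disp,
                   spatial = list(mode = spatial_mode,
                                  n_foci = as.integer(n_foci),
                                  focus_sd = focus_sd),
                   proportions = proportions),
              class = "TypeSignature")
}

#' Shipped type signatures
#'
#' Thirteen GBM-microenvironment cell types across the four categories, with
#' default proportions emulating the cohort's composition shift from primary
#' to recurrence (vascular loss, normal-brain and especially astrocyte gain)
#' and clustered placement for vessel-, macrophage- and hypoxia-associated
#' types.
#'
#' @return Named list of `TypeSignature` objects whose proportions sum to 1
#'   within each surgery.
#' @export
defaultTypeSignatures <- function() {
    # every type is clustered: the tissue these cohorts emulate is a mosaic
    # of niches (hypoxic tumor cores, vascular niches, immune hubs,
    # infiltrative brain), with per-type focus counts/scales setting the
    # niche grain
    sig <- function(ct, cat, hi, pr, nf, sd)
        typeSignature(ct, cat, hi, pr, "clustered", nf, sd)
    sigs <- list(
        sig("macrophage", "immune", c("CD45", "CD68", "CD163", "IBA1"),
            c(primary = 0.10, recurrent = 0.08), 5L, 70),
        sig("microglia", "immune", c("CD45", "IBA1", "TMEM119", "P2RY12"),
            c(primary = 0.06, recurrent = 0.05), 5L, 80),
        sig("t_cell", "immune", c("CD45", "CD3", "CD4", "CD8a"),
            c(primary = 0.03, recurrent = 0.03), 6L, 50),
        sig("nk_cell", "immune", c("CD45", "NCR1"),
            c(primary = 0.02, recurrent = 0.02), 6L, 50),
        sig("neutrophil", "immune", c("CD45", "MPO"),
            c(primary = 0.01, recurrent = 0.01), 6L, 50),
        sig("AC", "cancer", c("GFAP", "EGFR", "SOX2", "S100B"),
            c(primary = 0.14, recurrent = 0.10), 4L, 90),
        sig("MES", "cancer", c("CD44", "VIM", "NESTIN"),
            c(primary = 0.12, recurrent = 0.12), 3L, 100),
        sig("NPC", "cancer", c("SOX2", "NESTIN", "DLL3"),
            c(primary = 0.08, recurrent = 0.07), 4L, 80),
        sig("OPC", "cancer", c("OLIG2", "PDGFRA", "SOX2"),
            c(primary = 0.06, recurrent = 0.06), 4L, 80),
        sig("astrocyte", "normal brain", c("GFAP", "AQP4", "S100B"),
            c(primary = 0.12, recurrent = 0.20), 4L, 100),
        sig("neuron", "normal brain", c("RBFOX3", "MAP2", "SYP"),
            c(primary = 0.06, recurrent = 0.10), 4L, 100),
        sig("oligodendrocyte", "normal brain", c("MOG", "CNP", "OLIG2"),
            c(primary = 0.05, recurrent = 0.08), 4L, 90),
        sig("endothelial", "vasculature", c("CD31", "CD34", "SMA"),
            c(primary = 0.15, recurrent = 0.08), 8L, 40))
    stats::setNames(sigs, vapply(sigs, `[[`, "", "cell_type"))
}

#' Planted ground truth for the generator
#'
#' @param enrichment data.frame with columns `typeA`, `typeB`, `multiplier`
#'   and optionally `surgery` (NA or absent = both surgeries). Multiplier 1
#'   leaves the pair completely spatially random relative to one another;
#'   multipliers > 1 co-locate a fraction `1 - 1/multiplier` of the pair's
#'   spatial foci; multipliers < 1 push the pair's foci apart.
#' @param state_rates data.frame with columns `cell_type`, `surgery`,
#'   `hypoxia`, `emt`: per-type per-surgery probabilities that a cell is
#'   flagged hypoxic / EMT (flagged cells get boosted HIF1A / SNAI1+TGFBeta).
#' @return A list of class `"PlantedTruth"`.
#' @export
plantedTruth <- function(enrichment = NULL, state_rates = NULL) {
    if (!is.null(enrichment)) {
        stopifnot(all(c("typeA", "typeB", "multiplier") %in%
                          colnames(enrichment)))
        if (!"surgery" %in% colnames(enrichment)) enrichment$surgery <- NA
        if (any(enrichment$multiplier < 0))
            stop("enrichment multipliers must be >= 0")
    }
    if (!is.null(state_rates))
        stopifnot(all(c("cell_type", "surgery", "hypoxia", "emt") %in%
                          colnames(state_rates)))
    structure(list(enrichment = enrichment, state_rates = state_rates),
              class = "PlantedTruth")
}

#' Default planted truth emulating the study's headline spatial findings
#'
#' Endothelial cells share foci with microglia and MES cells in primary
#' samples and with macrophages in recurrent samples; AC cancer cells gain
#' and MES/NPC cells lose hypoxia at recurrence; EMT rises in all cancer
#' types at recurrence.
#'
#' @return A `PlantedTruth` object.
#' @export
defaultPlantedTruth <- function() {
    enr <- data.frame(
        typeA = c("endothelial", "endothelial", "endothelial"),
        typeB = c("microglia", "MES", "macrophage"),
        multiplier = c(3, 3, 3),
        surgery = c("primary", "primary", "recurrent"))
    ca <- c("AC", "MES", "NPC", "OPC")
    st <- rbind(
        data.frame(cell_type = ca, surgery = "primary",
                   hypoxia = c(0.08, 0.25, 0.10, 0.08), emt = 0.05),
        data.frame(cell_type = ca, surgery = "recurrent",
                   hypoxia = c(0.25, 0.10, 0.05, 0.08), emt = 0.20))
    plantedTruth(enr, st)
}

.checkSignatures <- function(signatures, surgeries) {
    props <- vapply(signatures, function(s)
        s$proportions[surgeries], numeric(length(surgeries)))
    props <- matrix(props, nrow = length(surgeries))
    if (any(is.na(props)))
        stop("configuration error: every signature needs a proportion for ",
             "each surgery")
    tot <- rowSums(props)
    if (any(abs(tot - 1) > 1e-9))
        stop("configuration error: type proportions must sum to 1 per ",
             "surgery (got ", paste(signif(tot, 10), collapse = ", "), ")")
    invisible(TRUE)
}

## One ROI worth of cells. All randomness is drawn inside the caller-set
## per-ROI substream in a fixed order: type counts, foci (signature order),
## positions, state flags, marker intensities.
.generateROI <- function(n, side, signatures, props, truth, surgery,
                         draw_markers) {
    types <- names(signatures)
    K <- length(types)
    counts <- as.integer(stats::rmultinom(1L, n, props))
    names(counts) <- types

    foci <- vector("list", K)
    names(foci) <- types
    clustered <- stats::setNames(vapply(signatures, function(s)
        s$spatial$mode == "clustered", TRUE), types)
    enr <- truth$enrichment
    if (!is.null(enr)) {
        act <- is.na(enr$surgery) | enr$surgery == surgery
        enr <- enr[act & enr$multiplier != 1, , drop = FALSE]
        unknown <- setdiff(c(enr$typeA, enr$typeB), types)
        if (length(unknown))
            stop("configuration error: unknown type label in truth: ",
                 paste(unknown, collapse = ", "))
        clustered[c(enr$typeA, enr$typeB)] <- TRUE
    } else enr <- data.frame()
    for (ty in types) {
        if (clustered[[ty]]) {
            nf <- max(1L, signatures[[ty]]$spatial$n_foci)
            foci[[ty]] <- matrix(stats::runif(2L * nf, 0, side), ncol = 2L)
        }
    }
    if (nrow(enr)) {
        lent <- list()  # foci of A already lent to an earlier partner
        for (i in seq_len(nrow(enr))) {
            a <- enr$typeA[i]; b <- enr$typeB[i]; m <- enr$multiplier[i]
            fa <- foci[[a]]; fb <- foci[[b]]
            if (m > 1) {
                k <- min(nrow(fb), ceiling((1 - 1 / m) * nrow(fb)))
                if (k > 0) {
                    # share a random subset of A's foci; distinct partners
                    # of the same hub type take distinct foci while any
                    # remain, so they spread over its territory
                    avail <- setdiff(seq_len(nrow(fa)), lent[[a]])
                    if (length(avail) < k)
                        avail <- seq_len(nrow(fa))
                    pickA <- if (length(avail) == 1) rep(avail, k)
                             else sample(avail, k, replace = k > length(avail))
                    lent[[a]] <- c(lent[[a]], pickA)
                    fb[seq_len(k), ] <- fa[pickA, , drop = FALSE]
                }
            } else {
                dmin <- 2 * max(signatures[[a]]$spatial$focus_sd,
                                signatures[[b]]$spatial$focus_sd)
                for (j in seq_len(nrow(fb))) {
                    for (try in 1:200) {
                        d2 <- (fa[, 1] - fb[j, 1])^2 + (fa[, 2] - fb[j, 2])^2
                        if (min(d2) > dmin^2) break
                        fb[j, ] <- stats::runif(2L, 0, side)
                    }
                }
            }
            foci[[b]] <- fb
        }
    }

    xy <- matrix(0, nrow = n, ncol = 2L)
    type_vec <- rep(types, counts)
    off <- 0L
    for (ty in types) {
        nt <- counts[[ty]]
        if (nt == 0L) next
        idx <- off + seq_len(nt)
        if (clustered[[ty]]) {
            f <- foci[[ty]]
            pick <- sample.int(nrow(f), nt, replace = TRUE)
            sd <- signatures[[ty]]$spatial$focus_sd
            pos <- f[pick, , drop = FALSE] +
                matrix(stats::rnorm(2L * nt, 0, sd), ncol = 2L)
            # reflect at ROI borders: keeps coordinates in bounds without
            # stacking cells onto the exact boundary (degenerate for the
            # downstream triangulation)
            pos <- abs(pos)
            pos[pos > side] <- 2 * side - pos[pos > side]
            xy[idx, ] <- pmin(pmax(pos, 0), side)
        } else {
            xy[idx, ] <- matrix(stats::runif(2L * nt, 0, side), ncol = 2L)
        }
        off <- off + nt
    }

    hyp <- logical(n); emt <- logical(n)
    sr <- truth$state_rates
    off <- 0L
    for (ty in types) {
        nt <- counts[[ty]]
        if (nt == 0L) next
        idx <- off + seq_len(nt)
        rh <- re <- 0
        if (!is.null(sr)) {
            row <- sr[sr$cell_type == ty & sr$surgery == surgery, , drop = FALSE]
            if (nrow(row)) { rh <- row$hypoxia[1]; re <- row$emt[1] }
        }
        if (rh > 0) hyp[idx] <- stats::runif(nt) < rh
        if (re > 0) emt[idx] <- stats::runif(nt) < re
        off <- off + nt
    }

    raw <- NULL
    if (draw_markers) {
        markers <- names(signatures[[1]]$marker_means)
        raw <- matrix(0, nrow = length(markers), ncol = n,
                      dimnames = list(markers, NULL))
        off <- 0L
        for (ty in types) {
            nt <- counts[[ty]]
            if (nt == 0L) next
            idx <- off + seq_len(nt)
            loc <- matrix(signatures[[ty]]$marker_means,
                          nrow = length(markers), ncol = nt,
                          dimnames = list(markers, NULL))
            boost <- .STATE_BOOST
            loc["HIF1A", hyp[idx]] <- loc["HIF1A", hyp[idx]] * boost
            loc["SNAI1", emt[idx]] <- loc["SNAI1", emt[idx]] * boost
            loc["TGFBeta", emt[idx]] <- loc["TGFBeta", emt[idx]] * boost / 2
            disp <- signatures[[ty]]$marker_dispersion
            raw[, idx] <- matrix(
                stats::rlnorm(length(markers) * nt, meanlog = log(loc),
                              sdlog = disp),
                nrow = length(markers))
            off <- off + nt
        }
    }
    list(xy = xy, type = type_vec, hypoxic = hyp, emt = emt, raw = raw)
}

.STATE_BOOST <- 12

## per-ROI substream index: ROIs are reproducible in isolation because each
## one reseeds from seed + its (1-based) position in the patient x surgery x
## roi grid; patient-level proportion jitter uses seed + 500000 + patient.
.roiSeed <- function(design, p, s, r) {
    design$seed + ((p - 1L) * length(design$surgeries) + (s - 1L)) *
        design$rois_per_sample + (r - 1L) + 1L
}

.patientFactors <- function(design, K) {
    out <- matrix(1, nrow = design$n_patients, ncol = K)
    if (design$patient_effect_sd > 0) {
        for (p in seq_len(design$n_patients)) {
            set.seed(design$seed + 500000L + p)
            out[p, ] <- exp(stats::rnorm(K, 0, design$patient_effect_sd))
        }
    }
    out
}

#' Generate a synthetic paired cohort with planted ground truth
#'
#' Produces one [CellTable-class] covering every patient x surgery x ROI in
#' the design. Marker intensities are lognormal per the type signatures;
#' clustered types are placed by drawing foci uniformly in the ROI and cells
#' at isotropic Gaussian offsets; pairwise adjacency enrichment is realized
#' by co-locating the enriched pair's foci. True type and state flags are
#' kept in the column data (`true_type`, `true_hypoxic`, `true_emt`), and the
#' full generating configuration is stored in the metadata so that
#' [shiftComposition()] can regenerate deterministically.
#'
#' @param design a [cohortDesign()].
#' @param signatures named list of [typeSignature()] objects.
#' @param truth a [plantedTruth()] (or NULL for none).
#' @param draw_markers set FALSE to skip marker synthesis (types, states and
#'   coordinates only) when only spatial/compositional behavior is needed.
#' @return A `CellTable`.
#' @examples
#' d <- cohortDesign(n_patients = 1, rois_per_sample = 1, cells_per_roi = 200,
#'                   patient_effect_sd = 0)
#' ct <- generateCohort(d)
#' table(SummarizedExperiment::colData(ct)$true_type)
#' @export
generateCohort <- function(design, signatures = defaultTypeSignatures(),
                           truth = defaultPlantedTruth(),
                           draw_markers = TRUE) {
    stopifnot(inherits(design, "CohortDesign"))
    if (is.null(truth)) truth <- plantedTruth()
    .checkSignatures(signatures, design$surgeries)
    if (!is.null(truth$enrichment)) {
        unknown <- setdiff(c(truth$enrichment$typeA, truth$enrichment$typeB),
                           names(signatures))
        if (length(unknown))
            stop("configuration error: unknown type label in truth: ",
                 paste(unknown, collapse = ", "))
    }
    K <- length(signatures)
    pf <- .patientFactors(design, K)
    parts <- list()
    for (p in seq_len(design$n_patients)) {
        for (s in seq_along(design$surgeries)) {
            surgery <- design$surgeries[s]
            base <- vapply(signatures, function(sg)
                sg$proportions[[surgery]], 0)
            props <- base * pf[p, ]
            props <- props / sum(props)
            for (r in seq_len(design$rois_per_sample)) {
                set.seed(.roiSeed(design, p, s, r))
                roi <- .generateROI(design$cells_per_roi, design$roi_side,
                                    signatures, props, truth, surgery,
                                    draw_markers)
                n <- design$cells_per_roi
                cd <- data.frame(
                    patient = sprintf("P%02d", p),
                    surgery = surgery,
                    roi = sprintf("R%d", r),
                    cell_id = sprintf("P%02d_%s_R%d_c%05d", p, surgery, r,
                                      seq_len(n)),
                    x = roi$xy[, 1], y = roi$xy[, 2],
                    true_type = roi$type, true_hypoxic = roi$hypoxic,
                    true_emt = roi$emt)
                parts[[length(parts) + 1L]] <- list(cd = cd, raw = roi$raw)
            }
        }
    }
    cd <- do.call(rbind, lapply(parts, `[[`, "cd"))
    if (draw_markers) {
        raw <- do.call(cbind, lapply(parts, `[[`, "raw"))
    } else {
        raw <- matrix(0, nrow = 1L, ncol = nrow(cd),
                      dimnames = list("none", NULL))
    }
    CellTable(raw, cd,
              metadata = list(design = design, signatures = signatures,
                              truth = truth, draw_markers = draw_markers))
}

#' Shift the planted composition of one surgery and regenerate
#'
#' Adds `deltas` to the named types' proportions in the given surgery,
#' rescales the remaining types proportionally so the total stays 1, and
#' regenerates the cohort from its stored design and seed. ROIs of the other
#' surgery are untouched (bit-identical), because every ROI draws from its
#' own seeded substream.
#'
#' @param table a `CellTable` produced by [generateCohort()].
#' @param surgery which surgery to shift (default `"recurrent"`).
#' @param deltas named numeric vector of proportion changes by type.
#' @return A regenerated `CellTable`.
#' @export
shiftComposition <- function(table, surgery = "recurrent", deltas) {
    md <- metadata(table)
    if (is.null(md$design))
        stop("table does not carry its generating configuration")
    sigs <- md$signatures
    unknown <- setdiff(names(deltas), names(sigs))
    if (length(unknown))
        stop("configuration error: unknown type(s): ",
             paste(unknown, collapse = ", "))
    cur <- vapply(sigs, function(s) s$proportions[[surgery]], 0)
    target <- cur
    target[names(deltas)] <- target[names(deltas)] + deltas
    if (any(target < 0) || any(target > 1))
        stop("configuration error: shifted proportions leave [0, 1]")
    rest <- setdiff(names(sigs), names(deltas))
    rest_mass <- 1 - sum(target[names(deltas)])
    if (rest_mass < 0)
        stop("configuration error: shifted proportions exceed 1 in total")
    if (sum(cur[rest]) > 0)
        target[rest] <- cur[rest] * rest_mass / sum(cur[rest])
    for (ty in names(sigs))
        sigs[[ty]]$proportions[[surgery]] <- target[[ty]]
    generateCohort(md$design, sigs, md$truth, md$draw_markers)
}

#' Write a generated cohort to a directory
#'
#' Writes `cells.csv` (the cell table), `truth.csv` (planted per-cell truth
#' keyed by cell id) and `manifest.json` (design, seed, type proportions and
#' a configuration hash).
#'
#' @param table a `CellTable` from [generateCohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
writeCohort <- function(table, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeCellTable(table, file.path(dir, "cells.csv"))
    cd <- as.data.frame(colData(table))
    utils::write.csv(
        cd[, c("cell_id", "true_type", "true_hypoxic", "true_emt")],
        file.path(dir, "truth.csv"), row.names = FALSE)
    md <- metadata(table)
    man <- list(design = unclass(md$design),
                proportions = lapply(md$signatures, `[[`, "proportions"),
                config_hash = configHash(md[c("design", "signatures",
                                              "truth")]))
    jsonlite::write_json(man, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(dir)
}
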