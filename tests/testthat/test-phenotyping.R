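# Builds a small table with a hand-set z assay so gate logic can be checked
# against exact values.
zFixture <- function(z) {
    n <- ncol(z)
    cd <- data.frame(patient = "P01", surgery = "primary", roi = "R1",
                     cell_id = paste0("c", seq_len(n)),
                     x = seq_len(n), y = rep(1, n))
    ct <- CellTable(pmax(z, 0), cd)  # raw assay unused by gating
    colnames(z) <- cd$cell_id
    assay(ct, "asinh") <- z
    assay(ct, "z") <- z
    ct
}

test_that("asinh transform matches the closed form and is monotone", {
    m <- matrix(c(0, 5, 1, 10), nrow = 1, dimnames = list("CD45", NULL))
    cd <- data.frame(patient = "P01", surgery = "primary", roi = "R1",
                     cell_id = paste0("c", 1:4), x = 1:4, y = 1:4)
    ct <- transformIntensities(CellTable(m, cd), transformSpec(cofactor = 5))
    tr <- asinhIntensities(ct)
    expect_identical(tr[1, 1], 0)
    expect_equal(tr[1, 2], log(1 + sqrt(2)), tolerance = 1e-12)  # asinh(1)
    expect_true(all(diff(tr[1, c(1, 3, 2, 4)]) > 0))
    mneg <- m; mneg[1, 2] <- -1
    expect_error(CellTable(mneg, cd), "non-negative")
})

test_that("broadly-high exclusion removes only uniformly extreme cells", {
    set.seed(1)
    markers <- defaultMarkerPanel()
    n <- 200
    raw <- matrix(rlnorm(length(markers) * n, log(2), 0.3),
                  nrow = length(markers), dimnames = list(markers, NULL))
    cd <- data.frame(patient = "P01", surgery = "primary", roi = "R1",
                     cell_id = paste0("c", seq_len(n)),
                     x = runif(n), y = runif(n))
    clean <- zScoreIntensities(transformIntensities(CellTable(raw, cd)))
    out <- excludeBroadlyHigh(clean)
    expect_length(metadata(out)$excluded_cells, 0)

    raw2 <- raw
    raw2[, 1] <- exp(log(2) + 5 * 0.3)  # all markers ~ +5 z for cell 1
    dirty <- zScoreIntensities(transformIntensities(CellTable(raw2, cd)))
    out2 <- excludeBroadlyHigh(dirty)
    expect_identical(metadata(out2)$excluded_cells, "c1")
    expect_equal(ncol(out2), n - 1)

    # unsatisfiable marker fraction excludes nothing
    out3 <- excludeBroadlyHigh(dirty, transformSpec(
        exclusion_min_marker_fraction = 1.01))
    expect_length(metadata(out3)$excluded_cells, 0)
})

test_that("gating assigns by priority with strict gates", {
    markers <- c("CD45", "CD68", "GFAP")
    z <- matrix(c(2, 0, -1,     # immune-like
                  -1, 0, 2,     # astro-like
                  2, 2, -1),    # satisfies both immune rules below
                nrow = 3, dimnames = list(markers, NULL))
    ct <- zFixture(z)
    rules <- rbind(
        gatingRule("immune_a", "immune", "CD45", "CD68", priority = 2),
        gatingRule("immune_b", "immune", "CD45", character(), priority = 1),
        gatingRule("astro", "normal brain", "GFAP", "CD45", priority = 3))
    out <- assignTypes(ct, rules)
    types <- unname(cellTypes(out))
    expect_identical(types, c("immune_b", "astro", "immune_b"))
    # lower priority rank wins when two rules match (cell 1 fits a and b)
    expect_identical(types[1], "immune_b")
    # empty rule set leaves everything unassigned
    expect_true(all(cellTypes(assignTypes(ct, rules[0, ])) == "unassigned"))
    expect_error(assignTypes(ct, gatingRule("x", "immune", "NOPE",
                                            character(), 1)),
                 "unknown marker")
    expect_error(assignTypes(ct, rbind(
        gatingRule("a", "immune", "CD45", character(), 1),
        gatingRule("b", "immune", "CD68", character(), 1))),
        "priorities")
})

test_that("state calls use strict z cutoffs", {
    markers <- c("HIF1A", "SNAI1")
    z <- matrix(c(1.3, -2,
                  1.2, -2,
                  0, 1.21), nrow = 2, dimnames = list(markers, NULL))
    ct <- zFixture(z)
    out <- callStates(ct, stateThresholds())
    cd <- colData(out)
    expect_identical(unname(cd$hypoxic), c(TRUE, FALSE, FALSE))
    expect_identical(unname(cd$emt), c(FALSE, FALSE, TRUE))
    expect_error(callStates(ct, stateThresholds(hypoxia_marker = "NOPE")),
                 "absent from panel")
})

test_that("type recovery on well-separated signatures exceeds 95%", {
    d <- cohortDesign(n_patients = 2, rois_per_sample = 2,
                      cells_per_roi = 700, seed = 21)
    ct <- generateCohort(d)
    ct <- callStates(assignTypes(excludeBroadlyHigh(zScoreIntensities(
        transformIntensities(ct)))))
    cd <- as.data.frame(colData(ct))
    expect_gt(mean(cd$cell_type == cd$true_type), 0.95)
    # categories partition types: each type maps to exactly one category
    expect_true(all(rowSums(base::table(cd$cell_type, cd$category) > 0) == 1))
})

test_that("gating is invariant to row order and affine intensity rescaling", {
    d <- cohortDesign(n_patients = 1, rois_per_sample = 1,
                      cells_per_roi = 300, seed = 8)
    ct <- generateCohort(d)
    run <- function(tb) unname(cellTypes(assignTypes(zScoreIntensities(
        transformIntensities(tb)))))
    base_types <- run(ct)
    perm <- sample(ncol(ct))
    expect_identical(run(ct[, perm]), base_types[perm])
    # scaling absorbed by z-scoring (applied on the transformed scale)
    ct2 <- ct
    tr <- asinh(rawIntensities(ct) / 5)
    assay(ct2, "asinh") <- tr * 3 + 1
    expect_identical(unname(cellTypes(assignTypes(zScoreIntensities(ct2)))),
                     base_types)
})

test_that("planted state-fraction differences are recovered and tested", {
    d <- cohortDesign(n_patients = 1, rois_per_sample = 1,
                      cells_per_roi = 5000, seed = 13, patient_effect_sd = 0)
    sigs <- list(AC = typeSignature("AC", "cancer", c("GFAP", "EGFR"),
                                    c(primary = 1, recurrent = 1)))
    tr <- plantedTruth(state_rates = data.frame(
        cell_type = "AC", surgery = c("primary", "recurrent"),
        hypoxia = c(0.1, 0.3), emt = 0))
    ct <- generateCohort(d, sigs, tr)
    ct <- callStates(zScoreIntensities(transformIntensities(ct)))
    colData(ct)$cell_type <- colData(ct)$true_type
    res <- stateFractionByGroup(ct, "hypoxic")
    fr <- res$fractions
    f_pri <- fr$fraction[fr$surgery == "primary"]
    f_rec <- fr$fraction[fr$surgery == "recurrent"]
    expect_lt(abs(f_pri - 0.1), 3 * sqrt(0.1 * 0.9 / 5000) + 0.01)
    expect_lt(abs(f_rec - 0.3), 3 * sqrt(0.3 * 0.7 / 5000) + 0.01)
    expect_lt(res$tests$p, 0.01)
})

test_that("state-fraction p-values are calibrated under identical arms", {
    set.seed(99)
    ps <- replicate(200, {
        flags <- rbinom(600, 1, 0.2) == 1
        cd <- data.frame(patient = "P01",
                         surgery = rep(c("primary", "recurrent"), each = 300),
                         roi = "R1", cell_id = paste0("c", 1:600),
                         x = runif(600), y = runif(600))
        ct <- tinyCellTable(cd)
        colData(ct)$cell_type <- "AC"
        colData(ct)$hypoxic <- flags
        stateFractionByGroup(ct, "hypoxic")$tests$p
    })
    # p-values from binary data are discrete, so check calibration via
    # rejection rates rather than a KS statistic
    for (a in c(0.05, 0.2))
        expect_lt(abs(mean(ps < a) - a), 3 * sqrt(a * (1 - a) / 200) + 0.02)
})
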