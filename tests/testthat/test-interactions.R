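test_that("pair statistics match hand counts on fixtures", {
    # two adjacent cells A-B: both variants give 1
    g <- makeGraph(cbind(c(0, 10), c(0, 0)), rbind(c(1, 2)))
    lab <- c("1" = "A", "2" = "B")
    expect_equal(pairStatistic(g, lab, "A", "B", "classic"), 1)
    expect_equal(pairStatistic(g, lab, "A", "B", "at_least_one_normalized"), 1)

    # star: one A adjacent to three B
    gs <- makeGraph(cbind(c(0, 10, -10, 0), c(0, 0, 0, 10)),
                    rbind(c(1, 2), c(1, 3), c(1, 4)))
    labs <- c("1" = "A", "2" = "B", "3" = "B", "4" = "B")
    expect_equal(pairStatistic(gs, labs, "A", "B", "classic"), 3)
    expect_equal(pairStatistic(gs, labs, "A", "B", "at_least_one_normalized"),
                 3)

    # two A cells, one with two B neighbors, one isolated from B:
    # classic averages over all A, the at-least-one variant only over
    # qualifying A
    g2 <- makeGraph(cbind(c(0, 10, 0, 40, 50), c(0, 0, 10, 0, 0)),
                    rbind(c(1, 2), c(1, 3), c(4, 5)))
    lab2 <- c("1" = "A", "2" = "B", "3" = "B", "4" = "A", "5" = "C")
    expect_equal(pairStatistic(g2, lab2, "A", "B", "classic"), 1.0)
    expect_equal(pairStatistic(g2, lab2, "A", "B", "at_least_one_normalized"),
                 2.0)
    # zero A cells: statistic undefined
    expect_true(is.na(pairStatistic(g2, lab2, "Z", "B", "classic")))
})

test_that("compiled null counts agree with plain-R statistics", {
    set.seed(3)
    pts <- matrix(runif(40, 0, 80), ncol = 2)
    g <- buildSpatialGraph(pts, 40)
    lab <- setNames(sample(c("A", "B", "C"), 20, replace = TRUE),
                    g@cellIds)
    res <- permutationTest(g, lab, interactionSpec(n_permutations = 5,
                                                   seed = 1))
    for (v in c("classic", "at_least_one_normalized")) {
        spec <- interactionSpec(n_permutations = 5, variant = v, seed = 1)
        res <- permutationTest(g, lab, spec)
        for (i in seq_len(nrow(res))) {
            expect_equal(res$observed[i],
                         pairStatistic(g, lab, res$typeA[i], res$typeB[i], v))
        }
    }
})

test_that("the permutation p-value floor is exactly 1/(m+1)", {
    ap <- alternatingPathTable(40)
    g <- buildSpatialGraph(ap$coords, 50)
    expect_equal(numEdges(g), 39)  # pure path: skip edges pruned
    res <- permutationTest(g, ap$labels,
                           interactionSpec(n_permutations = 200,
                                           variant = "classic", seed = 5))
    ab <- res[res$typeA == "A" & res$typeB == "B", ]
    expect_equal(ab$p_interact, 1 / 201)
    expect_true(all(stats::na.omit(
        pmin(res$p_interact, res$p_avoid)) >= 1 / 201))
    expect_identical(ab$call, "interacting")
})

test_that("a single-type graph is its own null", {
    g <- makeGraph(cbind(c(0, 10, 20), c(0, 5, 0)),
                   rbind(c(1, 2), c(2, 3)))
    lab <- setNames(rep("A", 3), g@cellIds)
    res <- permutationTest(g, lab, interactionSpec(n_permutations = 50,
                                                   seed = 2))
    expect_equal(res$p_interact, 1)
    expect_equal(res$p_avoid, 1)
    expect_identical(res$call, "ns")
})

test_that("permutation results are deterministic under the seed", {
    set.seed(10)
    pts <- matrix(runif(100, 0, 120), ncol = 2)
    g <- buildSpatialGraph(pts, 50)
    lab <- setNames(sample(c("A", "B"), 50, replace = TRUE), g@cellIds)
    r1 <- permutationTest(g, lab, interactionSpec(100, seed = 77))
    r2 <- permutationTest(g, lab, interactionSpec(100, seed = 77))
    expect_identical(r1, r2)
    r3 <- permutationTest(g, lab, interactionSpec(100, seed = 78))
    expect_false(identical(r1$p_interact, r3$p_interact))
})

test_that("aggregateCalls applies the patient-consistency rules", {
    mk <- function(patient, surgery, call)
        data.frame(patient = patient, surgery = surgery,
                   typeA = "A", typeB = "B", call = call)
    spec <- interactionSpec(min_patients = 3)
    # significant in 3 of 5 patients at primary only
    tab <- rbind(mk(paste0("P", 1:3), "primary", "interacting"),
                 mk(paste0("P", 4:5), "primary", "ns"),
                 mk(paste0("P", 1:5), "recurrent", "ns"))
    out <- aggregateCalls(tab, spec)
    expect_identical(out$classification, "primary-only")
    # interacting at primary, avoiding at recurrent, both >= 3 patients
    tab2 <- rbind(mk(paste0("P", 1:4), "primary", "interacting"),
                  mk(paste0("P", 1:4), "recurrent", "avoiding"))
    expect_identical(aggregateCalls(tab2, spec)$classification, "changed")
    # < 3 patients everywhere: nothing retained
    tab3 <- rbind(mk(paste0("P", 1:2), "primary", "interacting"))
    expect_equal(nrow(aggregateCalls(tab3, spec)), 0)
    # same call in both surgeries
    tab4 <- rbind(mk(paste0("P", 1:3), "primary", "interacting"),
                  mk(paste0("P", 1:3), "recurrent", "interacting"))
    expect_identical(aggregateCalls(tab4, spec)$classification, "both")
})

test_that("label-permutation null is invariant to node reordering", {
    set.seed(21)
    pts <- matrix(runif(60, 0, 100), ncol = 2)
    g <- buildSpatialGraph(pts, 50)
    lab <- setNames(rep(c("A", "B"), 15), g@cellIds)
    r1 <- permutationTest(g, lab, interactionSpec(400, seed = 9))
    perm <- sample(30)
    g2 <- makeGraph(pts[perm, , drop = FALSE],
                    cbind(match(g@edges[, 1], perm),
                          match(g@edges[, 2], perm)),
                    ids = g@cellIds[perm])
    r2 <- permutationTest(g2, lab, interactionSpec(400, seed = 9))
    # observed statistics are identical; null p-values agree within
    # Monte-Carlo error
    m <- merge(r1, r2, by = c("typeA", "typeB"))
    expect_equal(m$observed.x, m$observed.y, tolerance = 1e-12)
    expect_true(all(abs(m$p_interact.x - m$p_interact.y) <
                        4 * sqrt(0.25 / 400) + 0.01))
})
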