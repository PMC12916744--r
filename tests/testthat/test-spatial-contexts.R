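# Hub-and-ring fixture: the hub's radius window contains exactly the ring
# cells, whose CN mix is set per test.
ringTable <- function(cn_ring) {
    n <- length(cn_ring)
    th <- 2 * pi * seq_len(n) / n
    coords <- rbind(c(0, 0), cbind(10 * cos(th), 10 * sin(th)))
    cd <- data.frame(patient = "P01", surgery = "primary", roi = "R1",
                     cell_id = c("hub", paste0("r", seq_len(n))),
                     x = coords[, 1], y = coords[, 2])
    ct <- tinyCellTable(cd)
    colData(ct)$cn <- c("CN1", cn_ring)
    g <- makeGraph(coords, cbind(1, 1 + seq_len(n)),
                   ids = cd$cell_id, max_dist = 50)
    list(ct = ct, g = list(P01.primary.R1 = g))
}

hubSC <- function(cn_ring, threshold = 0.9) {
    fx <- ringTable(cn_ring)
    res <- detectSpatialContexts(fx$ct, fx$g,
                                 scSpec(window = 15,
                                        dominance_threshold = threshold))
    cells <- as.data.frame(res@cells)
    cells$sc[cells$cell_id == "hub"]
}

test_that("spatial contexts take the minimal dominant CN prefix", {
    expect_identical(hubSC(rep(c("CN6", "CN5"), c(19, 1))), "CN6")
    expect_identical(hubSC(rep(c("CN6", "CN5", "CN4"), c(10, 9, 1))),
                     "CN5&CN6")
    # threshold 1 takes every CN present in the window
    expect_identical(hubSC(rep(c("CN6", "CN5", "CN4"), c(10, 9, 1)), 1),
                     "CN4&CN5&CN6")
})

test_that("detected SCs are prefix-minimal against an igraph window oracle", {
    d <- cohortDesign(n_patients = 1, surgeries = "primary",
                      rois_per_sample = 1, cells_per_roi = 300, seed = 14)
    ct <- generateCohort(d, truth = NULL, draw_markers = FALSE)
    gs <- buildSpatialGraph(ct)
    set.seed(9)
    colData(ct)$cn <- paste0("CN", sample(1:6, 300, TRUE))
    res <- detectSpatialContexts(ct, gs, scSpec(dominance_threshold = 0.9))
    cells <- as.data.frame(res@cells)
    g <- gs[[1]]
    ig <- igraph::graph_from_edgelist(
        cbind(g@edges[, 1], g@edges[, 2]), directed = FALSE)
    ig <- igraph::add_vertices(ig, max(0, numCells(g) -
                                           igraph::vcount(ig)))
    cn <- colData(ct)$cn
    for (i in sample(numCells(g), 60)) {
        w <- setdiff(unlist(igraph::ego(ig, 2, nodes = i)), i)
        sc <- cells$sc[cells$cell_id == g@cellIds[i]]
        if (!length(w)) {
            expect_true(is.na(sc))
            next
        }
        fr <- sort(base::table(cn[w]) / length(w), decreasing = TRUE)
        fr <- fr[order(-as.numeric(fr), names(fr))]
        got <- strsplit(sc, "&", fixed = TRUE)[[1]]
        expect_gte(sum(fr[got]), 0.9 - 1e-12)
        # dropping the last (smallest) member falls below the threshold
        if (length(got) > 1) {
            drop1 <- sum(sort(fr[got], decreasing = TRUE)[
                seq_len(length(got) - 1)])
            expect_lt(drop1, 0.9)
        }
    }
})

test_that("dominant-SC filter applies strict inequalities", {
    mk <- function(sc, patient, n)
        data.frame(patient = rep(patient, n), sc = rep(sc, n))
    # group of 100 cells: X in 4 patients / 6%; Y in 3 patients / 10%;
    # Z in 5 patients / exactly 5%
    cells <- rbind(
        mk("X", c("P1", "P2", "P3", "P4", "P4", "P4"), 1)[1:6, ],
        mk("Y", rep(c("P1", "P2", "P3"), c(4, 3, 3)), 1)[1:10, ],
        mk("Z", c("P1", "P2", "P3", "P4", "P5"), 1)[1:5, ],
        data.frame(patient = rep("P1", 79), sc = "FILL"))
    cells$surgery <- "primary"
    cells$roi <- "R1"
    cells$cell_id <- paste0("c", seq_len(nrow(cells)))
    res <- new("SpatialContextResult",
               cells = S4Vectors::DataFrame(
                   cells[, c("patient", "surgery", "roi", "cell_id", "sc")]),
               threshold = 0.9, window = "2-hop")
    out <- filterDominantSCs(res, scSpec())
    expect_true(out$retained[out$sc == "X"])     # 4 > 3 and 0.06 > 0.05
    expect_false(out$retained[out$sc == "Y"])    # 3 patients, not > 3
    expect_false(out$retained[out$sc == "Z"])    # exactly 5%, not > 5%
})

test_that("CN networks connect co-occurring CNs only", {
    n1 <- buildCNNetwork(c("CN1", "CN1&CN2"), "primary")
    expect_identical(sort(igraph::V(n1@graph)$name), c("CN1", "CN2"))
    expect_equal(igraph::ecount(n1@graph), 1)
    # all singleton SCs: no edges
    n2 <- buildCNNetwork(c("CN1", "CN2", "CN3"), "primary")
    expect_equal(igraph::ecount(n2@graph), 0)
    # {A,B}, {B,C}: no transitive A-C edge
    n3 <- buildCNNetwork(c("CN1&CN2", "CN2&CN3"), "primary")
    el <- igraph::as_edgelist(n3@graph)
    keys <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    expect_identical(sort(keys), c("CN1 CN2", "CN2 CN3"))
    # order-invariance and idempotence of construction
    n3b <- buildCNNetwork(c("CN2&CN3", "CN1&CN2", "CN2&CN3"), "primary")
    expect_identical(sort(paste(igraph::as_edgelist(n3b@graph)[, 1],
                                igraph::as_edgelist(n3b@graph)[, 2])),
                     sort(paste(el[, 1], el[, 2])))
    expect_warning(buildCNNetwork(character(0), "primary"), "no retained")
})

test_that("centralities match fixtures and the brute-force oracle", {
    # path a-b-c
    np <- buildCNNetwork("CN1&CN2&CN3", "primary")  # triangle, not a path
    path <- buildCNNetwork(c("CN1&CN2", "CN2&CN3"), "primary")
    cp <- path@centralities
    expect_gt(cp$betweenness[cp$cn == "CN2"], 0)
    expect_equal(cp$betweenness[cp$cn != "CN2"], c(0, 0))
    # complete graph on 4 nodes: betweenness 0, degree 3
    k4 <- buildCNNetwork("CN1&CN2&CN3&CN4", "primary")
    expect_true(all(k4@centralities$degree == 3))
    expect_true(all(k4@centralities$betweenness == 0))
    # star on 5 nodes: hub degree 4, maximal betweenness
    star <- buildCNNetwork(paste0("CN1&CN", 2:5), "primary")
    cs <- star@centralities
    expect_equal(cs$degree[cs$cn == "CN1"], 4)
    expect_equal(cs$betweenness[cs$cn == "CN1"], 1)  # all paths via hub
    expect_true(all(cs$betweenness[cs$cn != "CN1"] == 0))

    # random graphs <= 12 nodes against the BFS oracle
    for (seed in 1:20) {
        set.seed(seed)
        n <- sample(4:12, 1)
        adj <- matrix(0L, n, n)
        for (i in seq_len(n - 1)) for (j in (i + 1):n)
            if (runif(1) < 0.35) adj[i, j] <- adj[j, i] <- 1L
        ig <- igraph::graph_from_adjacency_matrix(adj, "undirected")
        igraph::V(ig)$name <- paste0("CN", seq_len(n))
        got <- cnCentralities(ig)
        want <- oracleCentralities(adj)
        expect_equal(got$degree, unname(want$degree))
        expect_equal(got$closeness, want$closeness, tolerance = 1e-12)
        expect_equal(got$betweenness, want$betweenness, tolerance = 1e-12)
    }
    # singleton component: closeness 0 by convention
    iso <- igraph::make_empty_graph(1, directed = FALSE)
    expect_equal(cnCentralities(iso)$closeness, 0)
})

test_that("a planted core-periphery niche structure yields higher core
           closeness", {
    # the core type holds 8 tight foci; three peripheral types each ring a
    # distinct one of them (shared focus, wider spread), so each focus is a
    # micro-niche with a core center and one peripheral rim and the CN
    # network should be a star around the core CN
    wins <- 0L
    n_seeds <- 10L
    for (s in seq_len(n_seeds)) {
        sigs <- list(
            core = typeSignature("core", "cancer", "GFAP",
                                 c(primary = 0.4), "clustered", 8L, 40),
            p1 = typeSignature("p1", "immune", "CD45",
                               c(primary = 0.2), "clustered", 1L, 80),
            p2 = typeSignature("p2", "normal brain", "MOG",
                               c(primary = 0.2), "clustered", 1L, 80),
            p3 = typeSignature("p3", "vasculature", "CD31",
                               c(primary = 0.2), "clustered", 1L, 80))
        truth <- plantedTruth(data.frame(
            typeA = "core", typeB = c("p1", "p2", "p3"), multiplier = 25))
        d <- cohortDesign(n_patients = 5, surgeries = "primary",
                          rois_per_sample = 2, cells_per_roi = 800,
                          seed = 40000 + s * 1000, patient_effect_sd = 0)
        ct <- generateCohort(d, sigs, truth, draw_markers = FALSE)
        gs <- buildSpatialGraph(ct)
        cd <- as.data.frame(colData(ct))
        lab <- setNames(cd$true_type, cd$cell_id)
        vec <- neighborComposition(gs, lab)
        m <- fitNeighborhoods(vec, k = 4, seed = s, n_init = 5)
        ct <- addCNLabels(ct, m)
        # name each CN by its dominant member type
        dom_type <- colnames(cnCenters(m))[apply(cnCenters(m), 1,
                                                 which.max)]
        scr <- detectSpatialContexts(ct, gs, scSpec())
        dom <- filterDominantSCs(scr, scSpec())
        net <- suppressWarnings(buildCNNetwork(dom, "primary"))
        cent <- net@centralities
        cent$type <- dom_type[match(cent$cn, rownames(cnCenters(m)))]
        core_c <- cent$closeness[cent$type == "core"]
        peri_c <- cent$closeness[cent$type != "core"]
        if (length(core_c) == 1 && length(peri_c) >= 2 &&
            all(core_c > peri_c)) wins <- wins + 1L
    }
    expect_gte(wins, 9L)
})

test_that("network comparison reports deltas and edge differences", {
    a <- buildCNNetwork(c("CN1&CN2", "CN2&CN3"), "primary")
    b <- buildCNNetwork(c("CN1&CN2", "CN2&CN3"), "recurrent")
    cmp <- compareNetworks(a, b)
    expect_true(all(cmp$deltas$delta_degree == 0))
    expect_true(all(cmp$deltas$delta_closeness == 0))
    expect_equal(unname(cmp$counts), c(0, 0, 2))
    # recurrent = primary + 3 extra edges
    b2 <- buildCNNetwork(c("CN1&CN2", "CN2&CN3", "CN1&CN3&CN4"),
                         "recurrent")
    cmp2 <- compareNetworks(a, b2)
    expect_equal(unname(cmp2$counts["recurrent_only"]), 3)
    # absent node flagged and compared against zero
    expect_false(cmp2$deltas$in_primary[cmp2$deltas$cn == "CN4"])
    ann <- compareNetworks(a, b2, defaultCNAnnotation())
    expect_true("metaprogram" %in% colnames(ann$deltas))
})
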