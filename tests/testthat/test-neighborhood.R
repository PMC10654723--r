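test_that("nearest neighbors match brute force, with id tie-breaking", {
    p <- cbind(c(0, 1, 3), 0, 0)
    nn <- nearestNeighbors(p)
    expect_identical(nn$nn_index, c(2L, 1L, 2L))
    expect_equal(nn$nn_dist_um, c(1, 1, 2))

    ## equidistant pair: lower index wins
    tie <- cbind(c(0, 1, 2), 0, 0)
    expect_identical(nearestNeighbors(tie)$nn_index[2L], 1L)

    ## surface mode: centroid distance minus both radii, floored at 0
    two <- cbind(c(0, 10), 0, 0)
    expect_equal(nearestNeighbors(two, radii = c(5, 5),
        mode = "surface")$nn_dist_um, c(0, 0))
    expect_error(nearestNeighbors(matrix(0, 1L, 3L)), "at least 2")
    expect_error(nearestNeighbors(two, mode = "surface"), "radii")

    set.seed(61)
    for (i in 1:20) {
        n <- sample(5:50, 1L)
        q <- matrix(runif(n * 3L) * 100, ncol = 3L)
        got <- nearestNeighbors(q)
        ref <- bruteNN(q)
        expect_identical(got$nn_index, ref$index)
        expect_equal(got$nn_dist_um, ref$dist)
    }
})

test_that("nearest-neighbor composition tallies neighbor identities", {
    p <- cbind(c(0, 1, 3), 0, 0)
    labs <- c("A", "A", "B")
    comp <- nnComposition(p, labs, "A")
    expect_equal(unname(comp@aggregate["A"]), 100)
    expect_equal(selfPercentage(comp), 100)

    ## singleton query class whose neighbor is B
    comp2 <- nnComposition(cbind(c(0, 1, 2), 0, 0), c("A", "B", "B"), "A")
    expect_equal(unname(comp2@aggregate["B"]), 100)
    expect_equal(selfPercentage(comp2), 0)

    comp3 <- nnComposition(p, rep("A", 3L), "A")
    expect_equal(selfPercentage(comp3), 100)
    expect_error(nnComposition(p, labs, "Z"), "not present")
    expect_equal(sum(comp@aggregate), 100)
})

test_that("shuffle null matches the exchangeability closed form", {
    set.seed(71)
    p <- matrix(runif(600) * 100, ncol = 3L)
    labs <- sample(rep(c("A", "B"), c(60, 140)))
    nd <- shuffleNull(p, labs, "A", nShuffles = 1000, seed = 5)
    expected <- 100 * 59 / 199
    se <- sd(nullShuffles(nd)) / sqrt(1000)
    expect_lt(abs(mean(nullShuffles(nd)) - expected), 3 * se)
    ## per-shuffle compositions are full distributions
    expect_equal(unname(rowSums(nullComposition(nd))),
        rep(100, 1000), tolerance = 1e-9)
    expect_error(shuffleNull(p, labs, "A", nShuffles = 0), "nShuffles")
    ## determinism
    nd2 <- shuffleNull(p, labs, "A", nShuffles = 50, seed = 9)
    nd3 <- shuffleNull(p, labs, "A", nShuffles = 50, seed = 9)
    expect_identical(nullShuffles(nd2), nullShuffles(nd3))
})

test_that("clustered fields break the permutation null", {
    set.seed(81)
    pos <- sampleCellPositions(400, VolumeSpec(200), minSep = 8)
    parents <- data.frame(x_um = c(30, 170), y_um = c(30, 170),
        z_um = c(30, 170), label = c("A", "B"))
    labs <- assignLabelsClustered(pos, c(A = 0.5, B = 0.5),
        list(parents = parents))
    nd <- shuffleNull(pos, labs, "A", nShuffles = 500, seed = 2)
    expect_gt(nd@observed, quantile(nullShuffles(nd), 0.975))
    expect_gt(nullPercentile(nd), 97.5)
})

test_that("Voronoi adjacency matches geometry oracles", {
    ## regular tetrahedron plus centroid: centroid adjacent to all vertices
    tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1),
        c(0, 0, 0))
    g <- voronoiNeighbors(tet)
    expect_setequal(edgeNeighbors(g@edges, 5L), 1:4)

    ## two cells share the single bisector facet
    g2 <- voronoiNeighbors(matrix(c(0, 0, 0, 10, 0, 0), 2L,
        byrow = TRUE))
    expect_identical(unname(g2@edges[1L, ]), c(1L, 2L))

    expect_error(voronoiNeighbors(cbind(runif(8), runif(8), 1)),
        "degenerate")

    ## scipy Delaunay oracle on random fields: adjacency never exceeds
    ## Delaunay, and interior cells recover it exactly
    set.seed(91)
    fields <- lapply(1:20, function(i)
        matrix(runif(3 * sample(8:50, 1L)) * 100, ncol = 3L))
    oracle <- scipyDelaunay(fields)
    for (f in seq_along(fields)) {
        p <- fields[[f]]
        g <- voronoiNeighbors(p, maxCandidates = nrow(p) - 1L)
        gkey <- paste(g@edges[, 1L], g@edges[, 2L])
        okey <- paste(oracle[[f]][, 1L], oracle[[f]][, 2L])
        expect_true(all(gkey %in% okey))
        for (i in which(!g@boundary))
            expect_identical(edgeNeighbors(g@edges, i),
                edgeNeighbors(oracle[[f]], i))
        ## Delaunay property: an interior cell's NN is among its neighbors
        for (i in which(!g@boundary))
            expect_true(g@nnIndex[i] %in% edgeNeighbors(g@edges, i))
        ## symmetry of the adjacency list
        adj <- adjacencyList(g)
        for (i in seq_along(adj))
            for (j in adj[[i]])
                expect_true(i %in% adj[[j]])
    }
})

test_that("Voronoi neighborhood composition gives per-cell fractions", {
    tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1),
        c(0, 0, 0)) * 10
    g <- voronoiNeighbors(tet)
    labs <- c("A", "A", "A", "B", "C")
    comp <- neighborhoodComposition(g, labs, "C")
    expect_equal(unname(comp@perCell$fractions[1L, c("A", "B")]),
        c(0.75, 0.25))
    expect_equal(sum(comp@aggregate), 100)

    ## one-class field: self fraction 1 everywhere
    set.seed(101)
    p <- sampleCellPositions(60, VolumeSpec(100), minSep = 6)
    g1 <- voronoiNeighbors(p)
    c1 <- neighborhoodComposition(g1, rep("A", 60L), "A")
    expect_true(all(c1@perCell$fractions[, "A"] == 1))
    expect_equal(unname(c1@histogram["(0.9,1]", "A"]),
        nrow(c1@perCell))

    ## i.i.d. labels: mean neighbor fraction tracks class abundance
    p2 <- sampleCellPositions(2000, VolumeSpec(300), minSep = 8,
        seed = 13)
    labs2 <- assignLabelsIID(p2, c(A = 0.3, B = 0.7), seed = 14)
    g2 <- voronoiNeighbors(p2)
    c2 <- neighborhoodComposition(g2, labs2, "A")
    fr <- c2@perCell$fractions[, "A"]
    se <- sd(fr) / sqrt(length(fr))
    ## exchangeability: a query cell's neighbor is class A with
    ## probability (k - 1) / (n - 1) given k class-A cells in the field
    kA <- sum(labs2 == "A")
    expect_lt(abs(mean(fr) - (kA - 1) / (2000 - 1)), 3 * se + 0.01)
    expect_lt(abs(mean(fr) - 0.3), 0.04) # binomial field-level noise
    ## fraction vectors always normalized
    expect_equal(unname(rowSums(c2@perCell$fractions)),
        rep(1, nrow(c2@perCell)), tolerance = 1e-9)
})

test_that("self/non-self distances separate rare classes", {
    p <- cbind(c(0, 10, 2), 0, 0)
    r <- selfNonselfDistances(p, radii = 0, labels = c("A", "A", "B"),
        queryClass = "A")
    expect_equal(r$perCell$self_um, c(10, 10))
    expect_equal(r$perCell$nonself_um, c(2, 8))

    one <- selfNonselfDistances(p, radii = 0, labels = rep("A", 3L),
        queryClass = "A")
    expect_length(one$nonself, 0L)
    expect_equal(unname(one$dropped["nonself"]), 3L)

    set.seed(111)
    p2 <- sampleCellPositions(400, VolumeSpec(200), minSep = 8)
    labs <- assignLabelsIID(p2, c(rare = 0.05, common = 0.95))
    r2 <- selfNonselfDistances(p2, radii = 5, labels = labs,
        queryClass = "rare")
    expect_gt(mean(r2$self), mean(r2$nonself))
})
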