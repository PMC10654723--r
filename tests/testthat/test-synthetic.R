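test_that("hard-core sampling respects the volume, separation and seed", {
    vol <- VolumeSpec(100)
    expect_equal(nrow(sampleCellPositions(0, vol, seed = 1)), 0L)

    p <- sampleCellPositions(100, vol, minSep = 8, seed = 7)
    expect_equal(dim(p), c(100L, 3L))
    expect_true(all(p >= 0 & p <= 100))
    expect_gte(min(dist(p)), 8)

    p2 <- sampleCellPositions(100, vol, minSep = 8, seed = 7)
    expect_identical(p, p2)
    p3 <- sampleCellPositions(100, vol, minSep = 8, seed = 8)
    expect_false(identical(p, p3))
})

test_that("slab restriction confines sampling to the slab", {
    vol <- VolumeSpec(100, slab = list(axis = "z", min = 40, max = 60))
    p <- sampleCellPositions(200, vol, minSep = 4, seed = 1)
    expect_true(all(p[, 3L] >= 40 & p[, 3L] <= 60))
    expect_true(any(p[, 1L] < 40 | p[, 1L] > 60)) # other axes unrestricted
})

test_that("infeasible packings fail explicitly", {
    expect_error(sampleCellPositions(100, VolumeSpec(10), minSep = 8,
        seed = 1), "infeasible packing")
    ## feasible density but an exhausted dart budget
    expect_error(sampleCellPositions(200, VolumeSpec(50), minSep = 7,
        seed = 1, maxAttempts = 250), "packing failure")
})

test_that("i.i.d. labels follow the frequency table", {
    pos <- matrix(runif(300), ncol = 3L)
    expect_identical(unique(assignLabelsIID(pos, c(A = 1), seed = 1)), "A")
    expect_identical(assignLabelsIID(pos[0, , drop = FALSE],
        c(A = 0.5, B = 0.5), seed = 1), character(0))
    expect_error(assignLabelsIID(pos, c(A = 0.5, B = 0.6)), "sum to 1")

    big <- matrix(0, nrow = 10000L, ncol = 3L)
    labs <- assignLabelsIID(big, c(epi = 0.3, other = 0.7), seed = 42)
    sd3 <- 3 * sqrt(10000 * 0.3 * 0.7)
    expect_lt(abs(sum(labs == "epi") - 3000), sd3)
})

test_that("nearest-parent clustering builds contiguous fate domains", {
    ## two parents at opposite box ends -> two contiguous label blocks
    set.seed(5)
    pos <- rbind(cbind(runif(10, 0, 20), runif(10, 0, 100),
                       runif(10, 0, 100)),
                 cbind(runif(10, 80, 100), runif(10, 0, 100),
                       runif(10, 0, 100)))
    parents <- data.frame(x_um = c(5, 95), y_um = 50, z_um = 50,
        label = c("A", "B"))
    labs <- assignLabelsClustered(pos, c(A = 0.5, B = 0.5),
        list(parents = parents), seed = 1)
    expect_identical(labs, rep(c("A", "B"), each = 10L))
    ## brute-force check: every cell's nearest neighbor shares its label
    nn <- bruteNN(pos)
    expect_true(all(labs[nn$index] == labs))

    labs1 <- assignLabelsClustered(pos, c(A = 1),
        list(parentsPerClass = 3), seed = 2)
    expect_identical(unique(labs1), "A")
    expect_error(assignLabelsClustered(pos, c(A = 1),
        list(parentsPerClass = 0), seed = 1), "parentsPerClass")
})

test_that("gaussian-weight clustering approaches i.i.d. as sigma grows", {
    freqs <- c(A = 0.5, B = 0.5)
    vol <- VolumeSpec(100)
    selfFrac <- function(labs, nnIdx) mean(labs[nnIdx] == labs)
    set.seed(17)
    diffs <- replicate(100, {
        pos <- matrix(runif(300 * 3) * 100, ncol = 3L)
        nnIdx <- nearestNeighbors(pos)$nn_index
        a <- assignLabelsClustered(pos, freqs,
            list(parentsPerClass = 10, sigma = 3 * sqrt(3) * 100,
                 mode = "gaussian-weight"), volume = vol)
        b <- assignLabelsIID(pos, freqs)
        selfFrac(a, nnIdx) - selfFrac(b, nnIdx)
    })
    expect_lt(abs(mean(diffs)), 0.02)
})

test_that("target bias reduces to i.i.d. at enrichment 1 and attracts at 50", {
    geom <- buildTissueGeometry(list(
        target = list(kind = "plane", axis = "z", value = 0)))
    freqs <- c(A = 0.3, B = 0.7)
    pos <- matrix(runif(600) * 100, ncol = 3L)
    unbiased <- assignLabelsTargetBiased(pos, freqs, geom,
        list(A = list(target = "target", lambda = 10, enrichment = 1)),
        seed = 11)
    expect_identical(unbiased, assignLabelsIID(pos, freqs, seed = 11))

    set.seed(23)
    hits <- replicate(100, {
        p <- matrix(runif(600) * 100, ncol = 3L)
        labs <- assignLabelsTargetBiased(p, freqs, geom,
            list(A = list(target = "target", lambda = 10,
                enrichment = 50)))
        mean(p[labs == "A", 3L]) < mean(p[, 3L])
    })
    expect_gte(sum(hits), 95)

    one <- assignLabelsTargetBiased(matrix(c(1, 1, 1), 1L), freqs, geom,
        list(A = list(target = "target", lambda = 10, enrichment = 50)),
        seed = 3)
    expect_true(one %in% names(freqs))
    expect_error(assignLabelsTargetBiased(pos, freqs, geom,
        list(A = list(target = "nope", lambda = 10))), "not found")
})

test_that("count emission is Poisson with the configured means", {
    panel <- defaultMarkerPanel()
    model <- defaultEmissionModel(panel)
    expect_error(simulateCounts("mystery", panel, model, seed = 1),
        "absent from the emission model")

    zero <- EmissionModel(matrix(0, 1L, 2L,
        dimnames = list("x", c("pan", "core_other"))))
    expect_true(all(simulateCounts(rep("x", 50), panel, zero,
        seed = 1) == 0L))

    cts <- simulateCounts(rep("other", 4000), panel, model, seed = 9)
    smedwi <- cts[panGene(panel), ]
    core <- colSums(cts[setdiff(poolGenes(panel, "neoblast_core"),
        panGene(panel)), ])
    ## Poisson(1) and Poisson(8) totals, 3 standard errors at n = 4000
    expect_lt(abs(mean(smedwi) - 1), 3 * sqrt(1 / 4000))
    expect_lt(abs(mean(core) - 8), 3 * sqrt(8 / 4000))

    expect_identical(cts, simulateCounts(rep("other", 4000), panel,
        model, seed = 9))
})

test_that("simulateCellField composes stages deterministically", {
    cf <- simulateCellField(150, seed = 4)
    expect_s4_class(cf, "CellField")
    expect_equal(ncol(cf), 150L)
    expect_gte(min(dist(cellPositions(cf))), 10)
    expect_true(all(cellLabels(cf) %in%
        names(defaultClassFrequencies())))
    expect_equal(nrow(cellCounts(cf)),
        length(unlist(defaultMarkerPanel()@pools)))
    cf2 <- simulateCellField(150, seed = 4)
    expect_identical(cellPositions(cf), cellPositions(cf2))
    expect_identical(cellCounts(cf), cellCounts(cf2))
})
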