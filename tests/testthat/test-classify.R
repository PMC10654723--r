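panel <- defaultMarkerPanel()

test_that("neoblast calling applies both thresholds at their boundaries", {
    cts <- makeCounts(panel, list(
        at_threshold = list(pan = 5, core_other = 6),
        low_smedwi = list(pan = 4, core_other = 100),
        typical_pos = list(pan = 8, core_other = 37),
        typical_neg = list(pan = 1, core_other = 8),
        low_core = list(pan = 100, core_other = 5)))
    nb <- callNeoblasts(cts, panel)
    expect_identical(unname(nb),
        c(TRUE, FALSE, TRUE, FALSE, FALSE))
    ## missing pan-neoblast gene
    expect_error(callNeoblasts(cts[rownames(cts) != "smedwi-1", ], panel),
        "smedwi-1")
})

test_that("specialized calling needs a sufficient strict-majority signature", {
    cts <- makeCounts(panel, list(
        majority = list(pan = 8, core_other = 37, `fstf:epidermis` = 6,
            `fstf:intestine` = 1),
        low_total = list(pan = 8, core_other = 37, `fstf:epidermis` = 3,
            `fstf:intestine` = 1),
        tie = list(pan = 8, core_other = 37, `fstf:epidermis` = 4,
            `fstf:intestine` = 4),
        no_fstf = list(pan = 8, core_other = 37)))
    nb <- callNeoblasts(cts, panel)
    expect_true(all(nb))
    spec <- callSpecialized(cts, nb, panel)
    expect_identical(unname(spec),
        c("epidermis", "unassigned", "unassigned", "unassigned"))
    ## non-neoblasts are never assigned
    spec2 <- callSpecialized(cts, c(FALSE, TRUE, TRUE, TRUE), panel)
    expect_true(is.na(spec2[1L]))
})

test_that("smedwi-low progenitors require 1-4 pan transcripts and a signature", {
    cts <- makeCounts(panel, list(
        prog = list(pan = 2, `fstf:epidermis` = 8),
        neoblast_range = list(pan = 6, `fstf:epidermis` = 8),
        no_pan = list(pan = 0, `fstf:epidermis` = 8),
        weak_signature = list(pan = 2, `fstf:epidermis` = 3)))
    pr <- callSmedwiLowProgenitors(cts, panel)
    expect_identical(unname(pr$is_progenitor),
        c(TRUE, FALSE, FALSE, FALSE))
    expect_identical(pr$progenitor_class[1L], "epidermis")
})

test_that("mature calls are exclusive with neoblast calls", {
    cts <- makeCounts(panel, list(
        mat = list(`mature:epidermis` = 20, `mature:intestine` = 1),
        nb = list(pan = 8, core_other = 37, `mature:epidermis` = 20),
        none = list()))
    nb <- callNeoblasts(cts, panel)
    mat <- callMature(cts, nb, panel)
    expect_identical(unname(mat), c("epidermis", NA, NA))
    calls <- classifyCells(cts, panel)
    expect_false(any(calls$is_neoblast & !is.na(calls$mature_tissue)))
})

test_that("neoblast and specialized calls are monotone in their evidence", {
    model <- defaultEmissionModel(panel)
    set.seed(31)
    labs <- sample(rownames(model@means), 200, replace = TRUE)
    cts <- simulateCounts(labs, panel, model)
    nb <- callNeoblasts(cts, panel)
    spec <- callSpecialized(cts, nb, panel)
    coreGenes <- poolGenes(panel, "neoblast_core")
    for (rep in 1:20) {
        cts2 <- cts
        ## raise a random neoblast-core gene everywhere
        g <- sample(coreGenes, 1L)
        cts2[g, ] <- cts2[g, ] + sample(1:10, 1L)
        nb2 <- callNeoblasts(cts2, panel)
        expect_true(all(nb2[nb])) # no TRUE -> FALSE flips
        ## raise each assigned cell's own majority pool
        assigned <- which(nb & !spec %in% "unassigned" & !is.na(spec))
        cts3 <- cts
        for (i in assigned) {
            g <- poolGenes(panel, paste0("fstf:", spec[i]))[1L]
            cts3[g, i] <- cts3[g, i] + 5L
        }
        spec3 <- callSpecialized(cts3, callNeoblasts(cts3, panel), panel)
        expect_identical(spec3[assigned], spec[assigned])
    }
})

test_that("classifier recovers generator truth on default synthetic fields", {
    model <- defaultEmissionModel(panel)
    truth <- assignLabelsIID(matrix(0, 5000L, 3L),
        defaultTissueFrequencies(), seed = 101)
    cts <- simulateCounts(truth, panel, model, seed = 102)
    calls <- classifyCells(cts, panel)

    trueNb <- startsWith(truth, "neoblast:")
    nbAccuracy <- mean(calls$is_neoblast == trueNb)
    expect_gte(nbAccuracy, 0.95)

    ## fate assignment accuracy among called neoblasts with a true fate
    fates <- sub("^neoblast:", "", truth)
    sel <- calls$is_neoblast & trueNb & fates != "unassigned"
    specAccuracy <- mean(calls$specialized_class[sel] == fates[sel])
    expect_gte(specAccuracy, 0.90)
})

test_that("class frequencies are fractions of called neoblasts", {
    spec <- c(rep("epidermis", 3L), rep("unassigned", 7L))
    fr <- classFrequencies(spec)
    expect_equal(unname(fr["epidermis"]), 0.30)
    expect_equal(sum(fr), 1)
    expect_error(classFrequencies(character(0)), "no neoblast calls")

    allUn <- classFrequencies(rep("unassigned", 5L))
    expect_identical(names(allUn), "unassigned")
    expect_equal(unname(allUn), 1)

    ## end-to-end recovery of the epidermal proportion among neoblasts
    truth <- assignLabelsIID(matrix(0, 5000L, 3L),
        defaultClassFrequencies(), seed = 7)
    cts <- simulateCounts(truth, panel, defaultEmissionModel(panel),
        seed = 8)
    calls <- classifyCells(cts, panel)
    fr <- classFrequencies(calls)
    nNb <- sum(calls$is_neoblast)
    sd3 <- 3 * sqrt(0.3 * 0.7 / nNb)
    expect_lt(abs(fr[["epidermis"]] - 0.30), sd3)
})
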