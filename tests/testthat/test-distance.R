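test_that("nearest mature-cell distances are exact and non-negative", {
    dt <- distanceToTissueCells(c(0, 0, 0),
        list(muscle = rbind(c(3, 4, 0), c(10, 0, 0))))
    expect_equal(distanceSamples(dt)$distance_um, 5)

    dt0 <- distanceToTissueCells(c(1, 2, 3),
        list(gut = matrix(c(1, 2, 3), 1L)))
    expect_equal(distanceSamples(dt0)$distance_um, 0)

    ## empty tissue is reported dropped, not fatal
    dt2 <- distanceToTissueCells(c(0, 0, 0),
        list(gut = rbind(c(1, 0, 0)), empty = NULL))
    expect_equal(unname(dt2@dropped["empty"]), 1L)
    expect_error(distanceToTissueCells(c(0, 0, 0), list(a = NULL)),
        "no tissue contains")

    ## uniform queries in a slab of thickness h over a dense plane: h/2
    set.seed(121)
    h <- 20
    grid <- as.matrix(expand.grid(x = 0:100, y = 0:100))
    plane <- cbind(grid, 0)
    q <- cbind(runif(2000, 20, 80), runif(2000, 20, 80), runif(2000, 0, h))
    dt3 <- distanceToTissueCells(q, list(plane = plane))
    expect_lt(abs(mean(distanceSamples(dt3)$distance_um) - h / 2), 0.5)
})

test_that("surface distances use exact closest-point formulas", {
    expect_equal(distanceToSurface(c(0, 0, 10),
        list(kind = "plane", axis = "z", value = 0)), 10)
    cyl <- list(kind = "cylinder", axis = "x", center = c(0, 0),
        radius = 20)
    expect_equal(distanceToSurface(c(5, 0, 0), cyl), 20) # on the axis
    expect_equal(distanceToSurface(c(0, 50, 0), cyl), 30) # |50 - 20|
    expect_equal(distanceToSurface(c(0, 0, 10), cyl), 10) # inside tube
    sph <- list(kind = "sphere", center = c(0, 0, 0), radius = 5)
    expect_equal(distanceToSurface(c(12, 0, 0), sph), 7) # d - r
    expect_equal(distanceToSurface(c(1, 0, 0), sph), 0)  # solid inside
    seg <- list(kind = "segment", p1 = c(0, 0, 0), p2 = c(10, 0, 0))
    expect_equal(distanceToSurface(c(5, 3, 4), seg), 5)
    expect_equal(distanceToSurface(c(13, 4, 0), seg), 5) # beyond the end
    expect_error(distanceToSurface(c(0, 0, 0), list(kind = "blob")),
        "unknown primitive")
    expect_error(buildTissueGeometry(list()), "empty geometry")
})

test_that("pharynx routing follows borders around the cavity", {
    cav <- list(kind = "cavity", xmin = -1, xmax = 1, ymin = -1,
        ymax = 1, entry = c(0, 1))
    ## unobstructed anterior query: straight line to the esophagus
    expect_equal(pharynxPathDistance(c(0, 3, 0), cav), 2)
    expect_equal(pharynxPathDistance(c(2, 1, 0), cav), 2)
    ## posterior query routes around a corner: sqrt(2) + 2 + 1
    expect_equal(pharynxPathDistance(c(0, -2, 0), cav),
        sqrt(2) + 3)
    expect_error(pharynxPathDistance(c(0, 0, 0), cav), "inside")

    ## a geometry object with one cavity also works
    geom <- buildTissueGeometry(list(ph = cav))
    expect_equal(pharynxPathDistance(c(0, -2, 0), geom), sqrt(2) + 3)

    ## metric sanity on random queries: never below the straight line
    set.seed(131)
    q <- cbind(runif(1000, -10, 10), runif(1000, -10, 10), 0)
    keep <- !(q[, 1L] > -1 & q[, 1L] < 1 & q[, 2L] > -1 & q[, 2L] < 1)
    q <- q[keep, , drop = FALSE]
    d <- pharynxPathDistance(q, cav)
    straight <- sqrt((q[, 1L] - 0)^2 + (q[, 2L] - 1)^2)
    expect_true(all(d >= straight - 1e-9))

    ## brute-force route-enumeration oracle on random cavities
    set.seed(132)
    for (rep in 1:5) {
        x0 <- runif(1, -5, 0); x1 <- x0 + runif(1, 1, 6)
        y0 <- runif(1, -5, 0); y1 <- y0 + runif(1, 1, 6)
        cav2 <- list(kind = "cavity", xmin = x0, xmax = x1, ymin = y0,
            ymax = y1, entry = c(runif(1, x0, x1), y1))
        for (k in 1:8) {
            repeat {
                qq <- c(runif(1, x0 - 8, x1 + 8), runif(1, y0 - 8, y1 + 8))
                if (!(qq[1L] > x0 && qq[1L] < x1 && qq[2L] > y0 &&
                      qq[2L] < y1)) break
            }
            expect_equal(pharynxPathDistance(c(qq, 0), cav2),
                routeOracle(qq, cav2), tolerance = 1e-6)
        }
    }
})

test_that("distance summaries aggregate with dropped-cell accounting", {
    dt <- distanceToTissueCells(matrix(c(0, 0, 0), 1L),
        list(gut = rbind(c(7, 0, 0))))
    s <- summarizeDistances(dt)
    expect_equal(s$mean, 7)
    expect_equal(s$sd, 0)
    expect_equal(s$n, 1)

    dt2 <- distanceToTissueCells(rbind(c(3, 0, 0), c(5, 0, 0)),
        list(gut = rbind(c(0, 0, 0))))
    s2 <- summarizeDistances(dt2)
    expect_equal(s2$mean, 4)
    expect_equal(s2$sd, sqrt(2))

    g <- summarizeDistances(dt2, groups = c("a", "b"))
    expect_equal(nrow(g), 2L)
    expect_warning(summarizeDistances(dt2, groups = c("a", NA)),
        "omitted")
})

test_that("target-biased classes end up closer to their target tissue", {
    geom <- buildTissueGeometry(list(
        gut = list(kind = "plane", axis = "z", value = 0)))
    freqs <- c(`neoblast:intestine` = 0.2, `neoblast:epidermis` = 0.3,
        `neoblast:unassigned` = 0.5)
    set.seed(141)
    hits <- replicate(100, {
        p <- matrix(runif(600) * 100, ncol = 3L)
        labs <- assignLabelsTargetBiased(p, freqs, geom, list(
            `neoblast:intestine` = list(target = "gut", lambda = 15,
                enrichment = 30)))
        d <- distanceToSurface(p, geom, "gut")
        mean(d[labs == "neoblast:intestine"]) <
            mean(d[labs == "neoblast:epidermis"])
    })
    expect_gte(sum(hits), 95)
})
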