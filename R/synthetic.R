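## Synthetic 3D tissue generation: hard-core cell fields, labeling regimes
## (intermingled, clustered, target-biased) and calibrated count emission.

#' Sample hard-core cell positions in a bounded volume
#'
#' Uniform dart-throwing with rejection: candidate points are drawn
#' uniformly in the volume and accepted if at least \code{minSep} from all
#' previously accepted points, emulating the roughly hard-core packing of
#' segmented nuclei centroids.
#'
#' @param n number of cells.
#' @param volume a \linkS4class{VolumeSpec}.
#' @param minSep minimum pairwise centroid separation in micrometres
#'   (default 10, one neoblast cell diameter); 0 disables the hard core.
#' @param seed integer seed, or NULL.
#' @param maxAttempts dart budget before giving up (default 10000 * n).
#' @return n x 3 matrix of positions (um).
#' @export
#' @examples
#' p <- sampleCellPositions(50, VolumeSpec(100), minSep = 8, seed = 1)
#' min(dist(p)) >= 8
sampleCellPositions <- function(n, volume, minSep = 10, seed = NULL,
        maxAttempts = 10000 * n) {
    stopifnot(n >= 0, minSep >= 0, is(volume, "VolumeSpec"))
    b <- .volumeBounds(volume)
    ext <- b$hi - b$lo
    if (n == 0L)
        return(matrix(numeric(0), ncol = 3L,
            dimnames = list(NULL, c("x_um", "y_um", "z_um"))))
    if (minSep > 0) {
        packing <- n * (4 / 3) * pi * (minSep / 2)^3 / prod(ext)
        if (packing >= 0.55)
            stop(sprintf(
                "infeasible packing: %d spheres of radius %.3g fill %.0f%% of the volume",
                n, minSep / 2, 100 * packing))
    }
    pos <- matrix(NA_real_, nrow = n, ncol = 3L)
    .withSeed(seed, {
        accepted <- 0L
        attempts <- 0L
        minSep2 <- minSep^2
        while (accepted < n) {
            if (attempts >= maxAttempts)
                stop(sprintf(
                    "packing failure: placed %d of %d points in %d attempts",
                    accepted, n, attempts))
            attempts <- attempts + 1L
            p <- b$lo + stats::runif(3L) * ext
            ok <- TRUE
            if (minSep > 0 && accepted > 0L) {
                d2 <- (pos[seq_len(accepted), 1L] - p[1L])^2 +
                      (pos[seq_len(accepted), 2L] - p[2L])^2 +
                      (pos[seq_len(accepted), 3L] - p[3L])^2
                ok <- all(d2 >= minSep2)
            }
            if (ok) {
                accepted <- accepted + 1L
                pos[accepted, ] <- p
            }
        }
    })
    colnames(pos) <- c("x_um", "y_um", "z_um")
    pos
}

## Shared inverse-CDF categorical sampler: one uniform per cell, so regimes
## that reduce to i.i.d. sampling reproduce it draw for draw.
.sampleCategorical <- function(u, weights) {
    ## weights: n x K matrix (rows need not be normalized)
    cw <- t(apply(weights, 1L, cumsum))
    if (nrow(weights) == 1L) cw <- matrix(cw, nrow = 1L)
    tot <- cw[, ncol(cw)]
    if (any(tot <= 0))
        stop("all class weights are zero for some cell")
    rowSums(cw < u * tot) + 1L
}

#' Assign labels independently at fixed class frequencies
#'
#' The intermingled ("salt-and-pepper") null regime: every cell draws its
#' label independently from the homeostatic class frequencies, regardless
#' of position.
#'
#' @param positions n x 3 matrix (or \linkS4class{CellField}); only the
#'   number of cells is used.
#' @param freqs named numeric vector of class frequencies (>= 0, summing
#'   to 1 within 1e-9).
#' @param seed integer seed, or NULL.
#' @return character vector of labels.
#' @export
#' @examples
#' table(assignLabelsIID(matrix(0, 100, 3),
#'       c(A = 0.5, B = 0.5), seed = 1))
assignLabelsIID <- function(positions, freqs, seed = NULL) {
    positions <- .positionsMatrix(positions)
    freqs <- .checkFreqs(freqs)
    n <- nrow(positions)
    if (n == 0L)
        return(character(0))
    .withSeed(seed, {
        u <- stats::runif(n)
        names(freqs)[.sampleCategorical(u, matrix(freqs, nrow = n,
            ncol = length(freqs), byrow = TRUE))]
    })
}

#' Assign spatially clustered labels (the alternative regime)
#'
#' Generates spatial fate domains to power-test the neighborhood statistics
#' against. In \code{"nearest-parent"} mode (default), parent points are
#' scattered uniformly in the bounding volume with per-class parent counts
#' apportioned proportionally to the class frequencies, and every cell
#' takes the label of its nearest parent, producing contiguous single-fate
#' domains (a Voronoi-of-parents labeling). In \code{"gaussian-weight"}
#' mode, each cell draws its label with probability proportional to a
#' Gaussian kernel (length scale \code{sigma}) summed over the parents of
#' each class, giving soft clusters that approach the i.i.d. regime as
#' \code{sigma} grows.
#'
#' @param positions n x 3 matrix or \linkS4class{CellField}.
#' @param freqs named class frequencies (sum to 1).
#' @param params list with \code{parentsPerClass} (>= 1; average number of
#'   parent points per class), \code{sigma} (um, > 0; used by the
#'   gaussian-weight mode), \code{mode} (\code{"nearest-parent"} or
#'   \code{"gaussian-weight"}), and optionally explicit \code{parents} (a
#'   data frame with \code{x_um}, \code{y_um}, \code{z_um}, \code{label})
#'   overriding parent generation.
#' @param seed integer seed, or NULL.
#' @param volume optional \linkS4class{VolumeSpec} for parent placement;
#'   defaults to the bounding box of \code{positions}.
#' @return character vector of labels.
#' @export
assignLabelsClustered <- function(positions, freqs, params, seed = NULL,
        volume = NULL) {
    positions <- .positionsMatrix(positions)
    freqs <- .checkFreqs(freqs)
    mode <- match.arg(params[["mode"]] %||% "nearest-parent",
        c("nearest-parent", "gaussian-weight"))
    sigma <- params[["sigma"]] %||% 1
    if (sigma <= 0)
        stop("'sigma' must be > 0")
    n <- nrow(positions)
    if (n == 0L)
        return(character(0))
    classes <- names(freqs)
    .withSeed(seed, {
        if (!is.null(params[["parents"]])) {
            parents <- params[["parents"]]
            ppos <- .positionsMatrix(parents)
            plab <- as.character(parents$label)
        } else {
            ppc <- params[["parentsPerClass"]] %||% 1
            if (is.null(ppc) || ppc < 1)
                stop("'parentsPerClass' must be >= 1")
            total <- max(1L, as.integer(round(ppc * sum(freqs > 0))))
            nParents <- .apportion(total, freqs)
            plab <- rep(classes, nParents)
            if (is.null(volume)) {
                lo <- apply(positions, 2L, min)
                hi <- apply(positions, 2L, max)
            } else {
                b <- .volumeBounds(volume)
                lo <- b$lo; hi <- b$hi
            }
            ppos <- cbind(stats::runif(length(plab), lo[1L], hi[1L]),
                          stats::runif(length(plab), lo[2L], hi[2L]),
                          stats::runif(length(plab), lo[3L], hi[3L]))
        }
        if (nrow(ppos) == 0L)
            stop("no parent points")
        if (mode == "nearest-parent") {
            nearest <- apply(positions, 1L, function(p)
                which.min(colSums((t(ppos) - p)^2)))
            plab[nearest]
        } else {
            u <- stats::runif(n)
            w <- matrix(0, nrow = n, ncol = length(classes))
            for (k in seq_along(classes)) {
                sel <- which(plab == classes[k])
                if (!length(sel)) next
                for (j in sel) {
                    d2 <- (positions[, 1L] - ppos[j, 1L])^2 +
                          (positions[, 2L] - ppos[j, 2L])^2 +
                          (positions[, 3L] - ppos[j, 3L])^2
                    w[, k] <- w[, k] + exp(-d2 / (2 * sigma^2))
                }
            }
            ## guard against numerically empty rows far from all parents
            w <- w + 1e-300
            classes[.sampleCategorical(u, w)]
        }
    })
}

## Largest-remainder apportionment of 'total' parents across classes,
## proportional to freqs, at least one per class with positive frequency.
.apportion <- function(total, freqs) {
    pos <- freqs > 0
    raw <- freqs * total
    base <- floor(raw)
    base[pos & base == 0] <- 1
    left <- total - sum(base)
    if (left > 0) {
        ord <- order(raw - floor(raw), decreasing = TRUE)
        ord <- ord[pos[ord]]
        take <- head(ord, left)
        base[take] <- base[take] + 1
    }
    as.integer(base)
}

#' Assign labels with bias toward a target tissue
#'
#' Each cell draws its label from the homeostatic frequencies reweighted by
#' proximity to class-specific target tissues: the weight of a biased class
#' at distance d from its target is
#' \code{freq * (1 + (enrichment - 1) * exp(-d / lambda))}, renormalized
#' per cell. At \code{enrichment = 1} this reduces exactly to the i.i.d.
#' regime (draw for draw, given the same seed).
#'
#' @param positions n x 3 matrix or \linkS4class{CellField}.
#' @param freqs named class frequencies (sum to 1).
#' @param geometry a \linkS4class{TissueGeometry} holding the target
#'   primitives.
#' @param params named list: one entry per biased class, each a list with
#'   \code{target} (primitive name), \code{lambda} (decay length, um > 0)
#'   and \code{enrichment} (maximum enrichment factor, >= 0; values > 1
#'   enrich near the target).
#' @param seed integer seed, or NULL.
#' @return character vector of labels.
#' @export
assignLabelsTargetBiased <- function(positions, freqs, geometry, params,
        seed = NULL) {
    positions <- .positionsMatrix(positions)
    freqs <- .checkFreqs(freqs)
    stopifnot(is(geometry, "TissueGeometry"))
    n <- nrow(positions)
    if (n == 0L)
        return(character(0))
    classes <- names(freqs)
    bad <- setdiff(names(params), classes)
    if (length(bad))
        stop("bias parameters for unknown classes: ",
            paste(bad, collapse = ", "))
    w <- matrix(freqs, nrow = n, ncol = length(classes), byrow = TRUE)
    for (cls in names(params)) {
        p <- params[[cls]]
        if (is.null(p$target) ||
            !p$target %in% names(geometry@primitives))
            stop("class '", cls, "': target primitive not found in geometry")
        if (is.null(p$lambda) || p$lambda <= 0)
            stop("class '", cls, "': 'lambda' must be > 0")
        enr <- p$enrichment %||% 1
        if (enr < 0)
            stop("class '", cls, "': 'enrichment' must be >= 0")
        d <- distanceToSurface(positions, geometry, p$target)
        k <- match(cls, classes)
        w[, k] <- w[, k] * (1 + (enr - 1) * exp(-d / p$lambda))
    }
    .withSeed(seed, {
        u <- stats::runif(n)
        classes[.sampleCategorical(u, w)]
    })
}

#' Simulate a complete labeled cell field with transcript counts
#'
#' Convenience wrapper composing position sampling, a labeling regime and
#' count emission into a \linkS4class{CellField}. Per-stage seeds are
#' derived from the master seed with \code{\link{deriveSeed}}, so adding or
#' removing a stage never perturbs the others.
#'
#' @param n number of cells.
#' @param volume a \linkS4class{VolumeSpec} (default a 300^3 um box).
#' @param freqs class frequencies (default
#'   \code{\link{defaultClassFrequencies}}).
#' @param regime labeling regime: \code{"iid"}, \code{"clustered"} or
#'   \code{"biased"}.
#' @param regimeParams parameters for the clustered / biased regimes (see
#'   \code{\link{assignLabelsClustered}},
#'   \code{\link{assignLabelsTargetBiased}}).
#' @param geometry \linkS4class{TissueGeometry}, required for the biased
#'   regime.
#' @param panel,emission marker panel and emission model; set
#'   \code{emission = NULL} to skip count simulation. Labels produced by
#'   the frequency table must be rows of the emission model.
#' @param minSep hard-core separation (um).
#' @param radius cell radius (um) recorded per cell (default 5, half a
#'   neoblast cell diameter).
#' @param seed master seed.
#' @return a \linkS4class{CellField} with \code{label} in its colData and,
#'   unless \code{emission} is NULL, a \code{"counts"} assay.
#' @export
#' @examples
#' cf <- simulateCellField(200, seed = 1)
#' table(cellLabels(cf))[1:3]
simulateCellField <- function(n, volume = VolumeSpec(300),
        freqs = defaultClassFrequencies(),
        regime = c("iid", "clustered", "biased"), regimeParams = list(),
        geometry = NULL, panel = defaultMarkerPanel(),
        emission = defaultEmissionModel(panel), minSep = 10, radius = 5,
        seed = NULL) {
    regime <- match.arg(regime)
    pos <- sampleCellPositions(n, volume, minSep = minSep,
        seed = if (is.null(seed)) NULL else deriveSeed(seed, "positions"))
    labSeed <- if (is.null(seed)) NULL else deriveSeed(seed, "labels")
    labels <- switch(regime,
        iid = assignLabelsIID(pos, freqs, seed = labSeed),
        clustered = assignLabelsClustered(pos, freqs, regimeParams,
            seed = labSeed, volume = volume),
        biased = assignLabelsTargetBiased(pos, freqs, geometry,
            regimeParams, seed = labSeed))
    counts <- if (!is.null(emission))
        simulateCounts(labels, panel, emission,
            seed = if (is.null(seed)) NULL else deriveSeed(seed, "counts"))
    CellField(pos, labels = labels, radii = radius, counts = counts,
        volume = volume)
}
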