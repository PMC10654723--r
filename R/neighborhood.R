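## Nearest-neighbor identity, Voronoi neighborhood composition and the
## label-permutation null.

#' Euclidean nearest neighbors
#'
#' For every cell, finds the closest other cell. In \code{"centroid"} mode
#' the distance is the Euclidean centroid distance; in \code{"surface"}
#' mode it is \code{max(0, centroid distance - r_i - r_j)}. Ties are broken
#' by the smallest cell index.
#'
#' @param positions n x 3 matrix, data frame or \linkS4class{CellField}
#'   (n >= 2).
#' @param radii numeric cell radii (um); required for surface mode (taken
#'   from the \code{CellField} if present).
#' @param mode \code{"centroid"} (default) or \code{"surface"}.
#' @return a \code{DataFrame} with \code{cell_id}, \code{nn_index},
#'   \code{nn_id} and \code{nn_dist_um}.
#' @export
#' @examples
#' p <- cbind(c(0, 1, 3), 0, 0)
#' nearestNeighbors(p)$nn_index  # 2, 1, 2
nearestNeighbors <- function(positions, radii = NULL,
        mode = c("centroid", "surface")) {
    mode <- match.arg(mode)
    if (is(positions, "CellField") && is.null(radii))
        radii <- cellRadii(positions)
    pos <- .positionsMatrix(positions)
    n <- nrow(pos)
    if (n < 2L)
        stop("nearest neighbors need at least 2 cells")
    if (mode == "surface") {
        if (is.null(radii))
            stop("surface mode requires cell radii")
        if (length(radii) == 1L) radii <- rep(radii, n)
        stopifnot(length(radii) == n)
    }
    ids <- rownames(pos)
    if (is.null(ids)) ids <- sprintf("cell_%05d", seq_len(n))
    nnIdx <- integer(n)
    nnDist <- numeric(n)
    blk <- max(1L, floor(2e6 / n))
    for (start in seq(1L, n, by = blk)) {
        rows <- start:min(start + blk - 1L, n)
        ## squared cross-distances rows x all
        cross <- outer(rowSums(pos[rows, , drop = FALSE]^2), rowSums(pos^2),
            "+") - 2 * pos[rows, , drop = FALSE] %*% t(pos)
        cross[cross < 0] <- 0
        d <- sqrt(cross)
        if (mode == "surface") {
            d <- d - outer(radii[rows], radii, "+")
            d[d < 0] <- 0
        }
        d[cbind(seq_along(rows), rows)] <- Inf
        nnIdx[rows] <- apply(d, 1L, which.min)
        nnDist[rows] <- d[cbind(seq_along(rows), nnIdx[rows])]
    }
    S4Vectors::DataFrame(cell_id = ids, nn_index = nnIdx,
        nn_id = ids[nnIdx], nn_dist_um = nnDist, row.names = ids)
}

## Accept a nearest-neighbor DataFrame, NeighborGraph or positions input
## and return the integer nn index vector.
.nnIndex <- function(x) {
    if (is(x, "NeighborGraph")) return(x@nnIndex)
    if (is(x, "DataFrame") && "nn_index" %in% colnames(x))
        return(x$nn_index)
    nearestNeighbors(x)$nn_index
}

#' Nearest-neighbor identity composition for a query class
#'
#' For all cells of the query class, tabulates the class labels of their
#' nearest neighbors as stacked percentages, including the self percentage
#' (fraction of query cells whose nearest neighbor shares their class).
#'
#' @param nn a nearest-neighbor table from \code{\link{nearestNeighbors}},
#'   a \linkS4class{NeighborGraph}, or raw positions.
#' @param labels character vector of cell labels.
#' @param queryClass character(1), must be present in \code{labels}.
#' @return a \linkS4class{CompositionResult} (mode \code{"nn"}).
#' @export
nnComposition <- function(nn, labels, queryClass) {
    idx <- .nnIndex(nn)
    labels <- as.character(labels)
    stopifnot(length(labels) == length(idx))
    q <- which(labels == queryClass)
    if (!length(q))
        stop("query class '", queryClass, "' not present")
    lev <- sort(unique(labels))
    nbLab <- labels[idx[q]]
    agg <- 100 * as.numeric(table(factor(nbLab, levels = lev))) / length(q)
    per <- S4Vectors::DataFrame(cell_index = q, nn_label = nbLab)
    new("CompositionResult", perCell = per,
        aggregate = setNames(agg, lev),
        histogram = matrix(numeric(0), nrow = 0L, ncol = length(lev),
            dimnames = list(NULL, lev)),
        bins = numeric(0), mode = "nn", queryClass = queryClass,
        dropped = 0L)
}

#' Self-neighbor percentage of a composition
#' @param x a \linkS4class{CompositionResult} or
#'   \linkS4class{NullDistribution}.
#' @return numeric(1), the percentage of query cells whose nearest neighbor
#'   (or, for Voronoi mode, mean neighborhood fraction) shares the query
#'   class; for a null distribution, the observed statistic.
#' @export
selfPercentage <- function(x) {
    if (is(x, "NullDistribution")) return(x@observed)
    stopifnot(is(x, "CompositionResult"))
    unname(x@aggregate[x@queryClass])
}

#' Null-distribution accessors
#' @param x a \linkS4class{NullDistribution}.
#' @return \code{nullShuffles}: the per-shuffle statistic values;
#'   \code{nullPercentile}: the observed value's percentile rank;
#'   \code{nullComposition}: the per-shuffle neighbor-label composition
#'   matrix (percent).
#' @name nullShuffles
#' @export
nullShuffles <- function(x) { stopifnot(is(x, "NullDistribution")); x@shuffles }

#' @rdname nullShuffles
#' @export
nullPercentile <- function(x) {
    stopifnot(is(x, "NullDistribution")); x@percentile
}

#' @rdname nullShuffles
#' @export
nullComposition <- function(x) {
    stopifnot(is(x, "NullDistribution")); x@shuffleComposition
}

#' Label-permutation null for nearest-neighbor identity
#'
#' Holding positions (and therefore the nearest-neighbor map) fixed,
#' permutes the cell labels \code{nShuffles} times (without replacement, so
#' the label multiset is conserved) and recomputes the query class's
#' self-nearest-neighbor percentage for each shuffle, together with the
#' full neighbor-label composition. The observed statistic's percentile
#' rank within the null is reported.
#'
#' @param positions n x 3 matrix, data frame or \linkS4class{CellField}; a
#'   precomputed nearest-neighbor table may be supplied via \code{nn}.
#' @param labels character labels (defaults to the \code{CellField}
#'   labels).
#' @param queryClass the query label, or NULL to query all cells (each
#'   cell's "self" is then its own label; the composition columns give the
#'   percentage of all nearest neighbors carrying each label).
#' @param nShuffles number of label permutations (default 1000).
#' @param seed integer seed, or NULL.
#' @param nn optional precomputed result of \code{\link{nearestNeighbors}}.
#' @return a \linkS4class{NullDistribution}.
#' @export
#' @examples
#' p <- sampleCellPositions(200, VolumeSpec(150), minSep = 8, seed = 1)
#' labs <- assignLabelsIID(p, c(A = 0.3, B = 0.7), seed = 2)
#' shuffleNull(p, labs, "A", nShuffles = 100, seed = 3)
shuffleNull <- function(positions, labels = NULL, queryClass = NULL,
        nShuffles = 1000, seed = NULL, nn = NULL) {
    if (nShuffles < 1)
        stop("'nShuffles' must be >= 1")
    if (is(positions, "CellField") && is.null(labels))
        labels <- cellLabels(positions)
    if (is.null(nn))
        nn <- nearestNeighbors(positions)
    idx <- .nnIndex(nn)
    labels <- as.character(labels)
    stopifnot(length(labels) == length(idx))
    lev <- sort(unique(labels))
    codes <- match(labels, lev)
    qcode <- 0L
    if (!is.null(queryClass)) {
        qcode <- match(queryClass, lev)
        if (is.na(qcode))
            stop("query class '", queryClass, "' not present")
    }
    ## observed statistic on the unshuffled labels
    q <- if (qcode == 0L) seq_along(labels) else which(codes == qcode)
    nbLab <- labels[idx[q]]
    selfLab <- if (qcode == 0L) labels[q] else rep(queryClass, length(q))
    observed <- 100 * mean(nbLab == selfLab)
    obsComp <- 100 * as.numeric(table(factor(nbLab, levels = lev))) /
        length(q)
    res <- .withSeed(seed,
        cpp_shuffle_null(as.integer(idx), as.integer(codes),
            as.integer(qcode), length(lev), as.integer(nShuffles)))
    shuffles <- res$self
    comp <- res$comp
    colnames(comp) <- lev
    new("NullDistribution",
        statistic = "self nearest-neighbor percentage",
        queryClass = if (is.null(queryClass)) "" else queryClass,
        observed = observed, shuffles = shuffles,
        percentile = 100 * mean(shuffles <= observed),
        observedComposition = setNames(obsComp, lev),
        shuffleComposition = comp)
}

#' Voronoi facet-sharing neighbor graph
#'
#' Computes the 3D Voronoi tessellation of the cell centroids, with regions
#' clipped to a bounding box, and records as neighbors every pair of cells
#' whose regions share a facet of area greater than \code{facetTol}. Cells
#' whose region touches the clipping box are flagged as boundary cells
#' (their regions are truncation artifacts and are excluded from
#' neighborhood composition by default). Facets are obtained by clipping
#' each candidate pair's bisector plane against the box and the bisectors
#' of nearby cells.
#'
#' @param positions n x 3 matrix, data frame or \linkS4class{CellField}
#'   (n >= 2; fields of 5 or more cells must not be fully coplanar or
#'   collinear).
#' @param volume optional \linkS4class{VolumeSpec} clipping box; by
#'   default the data bounding box padded by one mean nearest-neighbor
#'   spacing.
#' @param facetTol minimum shared facet area (um^2) to count as neighbors.
#' @param maxCandidates number of nearest cells considered as potential
#'   neighbors of each cell (all cells when n - 1 <= maxCandidates, which
#'   makes the computation exact; the default 40 is well above the maximum
#'   Voronoi degree seen in hard-core fields).
#' @return a \linkS4class{NeighborGraph}.
#' @export
#' @examples
#' p <- sampleCellPositions(50, VolumeSpec(100), minSep = 8, seed = 1)
#' voronoiNeighbors(p)
voronoiNeighbors <- function(positions, volume = NULL, facetTol = 1e-9,
        maxCandidates = 40) {
    pos <- .positionsMatrix(positions)
    n <- nrow(pos)
    if (n < 2L)
        stop("a tessellation needs at least 2 cells")
    if (anyDuplicated(round(pos, 12)))
        stop("coincident cell positions")
    ## clipped bisector regions are well defined for any 2-4 points; for
    ## larger sets a fully coplanar/collinear cloud signals broken input
    if (n >= 5L) {
        ctr <- sweep(pos, 2L, colMeans(pos))
        if (qr(ctr)$rank < 3L)
            stop("degenerate geometry: positions are coplanar or collinear")
    }
    ids <- rownames(pos)
    if (is.null(ids)) ids <- sprintf("cell_%05d", seq_len(n))
    nn <- nearestNeighbors(pos)
    if (is.null(volume)) {
        pad <- mean(nn$nn_dist_um)
        lo <- apply(pos, 2L, min) - pad
        hi <- apply(pos, 2L, max) + pad
    } else {
        b <- .volumeBounds(volume)
        lo <- b$lo
        hi <- b$hi
        if (!all(.insideVolume(pos, volume)))
            stop("all positions must lie inside the clipping volume")
    }
    k <- min(n - 1L, as.integer(maxCandidates))
    ## candidate neighbor lists (0-based for C++)
    cand <- vector("list", n)
    blk <- max(1L, floor(2e6 / n))
    for (start in seq(1L, n, by = blk)) {
        rows <- start:min(start + blk - 1L, n)
        cross <- outer(rowSums(pos[rows, , drop = FALSE]^2), rowSums(pos^2),
            "+") - 2 * pos[rows, , drop = FALSE] %*% t(pos)
        cross[cbind(seq_along(rows), rows)] <- Inf
        for (r in seq_along(rows))
            cand[[rows[r]]] <- as.integer(
                order(cross[r, ])[seq_len(k)] - 1L)
    }
    res <- cpp_voronoi_adjacency(pos, lo, hi, cand, facetTol)
    edges <- cbind(i = res$i, j = res$j)
    storage.mode(edges) <- "integer"
    new("NeighborGraph", ids = ids, edges = edges,
        facetAreas = as.numeric(res$area),
        nnIndex = as.integer(nn$nn_index),
        nnDist = as.numeric(nn$nn_dist_um),
        boundary = as.logical(res$boundary))
}

#' Default ridgeline histogram bin edges
#'
#' An exact-zero bin followed by ten equal bins on (0, 1].
#' @return numeric vector of bin edges starting at 0.
#' @export
defaultFractionBins <- function() c(0, seq(0.1, 1, by = 0.1))

#' Voronoi neighborhood identity composition
#'
#' For every query-class cell, the fraction of its Voronoi facet-sharing
#' neighbors carrying each label; aggregated both as mean percentages and
#' as binned histograms of the per-cell fractions (the ridgeline data).
#' Boundary cells are excluded by default because their clipped regions
#' produce artifactual adjacencies; isolated cells (no neighbors after
#' exclusions) are dropped and counted.
#'
#' @param graph a \linkS4class{NeighborGraph} from
#'   \code{\link{voronoiNeighbors}}.
#' @param labels character labels, one per graph node.
#' @param queryClass character(1) query label.
#' @param bins histogram bin edges for the per-cell fractions; the first
#'   bin counts exact zeros (default \code{\link{defaultFractionBins}}).
#' @param includeBoundary include boundary cells as query cells
#'   (default FALSE; boundary cells always remain available as neighbors).
#' @return a \linkS4class{CompositionResult} (mode \code{"voronoi"}).
#' @export
neighborhoodComposition <- function(graph, labels, queryClass,
        bins = defaultFractionBins(), includeBoundary = FALSE) {
    stopifnot(is(graph, "NeighborGraph"))
    labels <- as.character(labels)
    n <- length(graph@ids)
    stopifnot(length(labels) == n)
    if (!queryClass %in% labels)
        stop("query class '", queryClass, "' not present")
    adj <- adjacencyList(graph)
    q <- which(labels == queryClass)
    dropped <- 0L
    if (!includeBoundary) {
        dropped <- dropped + sum(graph@boundary[q])
        q <- q[!graph@boundary[q]]
    }
    iso <- lengths(adj[q]) == 0L
    if (any(iso)) {
        warning(sum(iso), " isolated query cell(s) dropped")
        dropped <- dropped + sum(iso)
        q <- q[!iso]
    }
    if (!length(q))
        stop("no usable query cells for class '", queryClass, "'")
    lev <- sort(unique(labels))
    frac <- vapply(adj[q], function(nb) {
        tab <- table(factor(labels[nb], levels = lev))
        as.numeric(tab) / length(nb)
    }, numeric(length(lev)))
    frac <- matrix(frac, ncol = length(lev), byrow = TRUE,
        dimnames = list(NULL, lev))
    agg <- 100 * colMeans(frac)
    agg <- 100 * agg / sum(agg) # guard rounding; fractions each sum to 1
    ## histogram: exact-zero bin + bins on (0, 1]
    hist <- vapply(lev, function(l) {
        f <- frac[, l]
        zero <- sum(f == 0)
        inner <- table(cut(f[f > 0], breaks = bins, include.lowest = FALSE))
        c(zero, as.numeric(inner))
    }, numeric(length(bins)))
    rownames(hist) <- c("0",
        sprintf("(%g,%g]", bins[-length(bins)], bins[-1L]))
    per <- S4Vectors::DataFrame(cell_index = q,
        n_neighbors = lengths(adj[q]), row.names = graph@ids[q])
    per$fractions <- frac
    new("CompositionResult", perCell = per, aggregate = agg,
        histogram = hist, bins = bins, mode = "voronoi",
        queryClass = queryClass, dropped = dropped)
}

#' Self and non-self nearest distances for a query class
#'
#' For every cell of the query class, the distance to its closest
#' same-class cell and to its closest different-class cell
#' (surface-to-surface when radii are available, i.e.
#' \code{max(0, centroid distance - r_i - r_j)}).
#'
#' @param positions n x 3 matrix, data frame or \linkS4class{CellField}.
#' @param radii cell radii (um); 0 measures centroid-to-centroid. Taken
#'   from the \code{CellField} when available.
#' @param labels character labels (defaults to \code{CellField} labels).
#' @param queryClass character(1) query label.
#' @return a list with \code{perCell} (DataFrame: cell_id, self_um,
#'   nonself_um), the \code{self} and \code{nonself} distance samples
#'   (NAs removed), and \code{dropped} counts.
#' @export
selfNonselfDistances <- function(positions, radii = NULL, labels = NULL,
        queryClass) {
    if (is(positions, "CellField")) {
        if (is.null(labels)) labels <- cellLabels(positions)
        if (is.null(radii)) radii <- cellRadii(positions)
    }
    pos <- .positionsMatrix(positions)
    n <- nrow(pos)
    labels <- as.character(labels)
    stopifnot(length(labels) == n)
    if (is.null(radii)) radii <- 0
    if (length(radii) == 1L) radii <- rep(radii, n)
    q <- which(labels == queryClass)
    if (!length(q))
        stop("query class '", queryClass, "' not present")
    same <- labels == queryClass
    d <- .pairwiseDistances(pos) - outer(radii, radii, "+")
    d[d < 0] <- 0
    diag(d) <- Inf
    selfD <- vapply(q, function(i) {
        others <- same
        others[i] <- FALSE
        if (any(others)) min(d[i, others]) else NA_real_
    }, 0)
    nonselfD <- vapply(q, function(i) {
        if (any(!same)) min(d[i, !same]) else NA_real_
    }, 0)
    ids <- rownames(pos)
    if (is.null(ids)) ids <- sprintf("cell_%05d", seq_len(n))
    per <- S4Vectors::DataFrame(cell_id = ids[q], self_um = selfD,
        nonself_um = nonselfD)
    list(perCell = per,
        self = selfD[!is.na(selfD)],
        nonself = nonselfD[!is.na(nonselfD)],
        dropped = c(self = sum(is.na(selfD)),
                    nonself = sum(is.na(nonselfD))))
}
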