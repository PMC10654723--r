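## Distances from classified cells to mature tissues.

#' Distance to the nearest mature cell of each tissue
#'
#' Euclidean centroid-to-centroid distance from every query cell to the
#' nearest member of each mature-cell point set. Also serves generic
#' nearest-cell measurements (e.g. EdU-labeled post-mitotic cells to the
#' nearest neoblast).
#'
#' @param query n x 3 matrix, data frame or \linkS4class{CellField} of
#'   query cell centroids.
#' @param tissues named list; each element an m x 3 matrix (or data frame)
#'   of mature-cell centroids for one tissue.
#' @return a \linkS4class{DistanceTable}; tissues with no cells are
#'   reported in \code{dropped} (one entry per query) and omitted from the
#'   distances.
#' @export
#' @examples
#' distanceToTissueCells(c(0, 0, 0),
#'     list(muscle = rbind(c(3, 4, 0), c(10, 0, 0))))
distanceToTissueCells <- function(query, tissues) {
    if (is.numeric(query) && is.null(dim(query)) && length(query) == 3L)
        query <- matrix(query, nrow = 1L)
    q <- .positionsMatrix(query)
    ids <- rownames(q)
    if (is.null(ids)) ids <- sprintf("cell_%05d", seq_len(nrow(q)))
    if (is.null(names(tissues)) || any(!nzchar(names(tissues))))
        stop("'tissues' must be a named list")
    rows <- list()
    dropped <- integer(0)
    for (tn in names(tissues)) {
        pts <- tissues[[tn]]
        if (is.null(pts) || NROW(pts) == 0L) {
            dropped[tn] <- nrow(q)
            next
        }
        pts <- .positionsMatrix(pts)
        d <- vapply(seq_len(nrow(q)), function(i)
            sqrt(min(colSums((t(pts) - q[i, ])^2))), 0)
        rows[[tn]] <- data.frame(cell_id = ids, tissue = tn,
            distance_um = d, stringsAsFactors = FALSE)
    }
    if (!length(rows))
        stop("no tissue contains any cells")
    long <- do.call(rbind, rows)
    rownames(long) <- NULL
    new("DistanceTable", distances = long,
        summary = .distanceSummary(long), dropped = dropped)
}

.distanceSummary <- function(long, groups = NULL) {
    key <- if (is.null(groups)) list(tissue = long$tissue)
        else list(tissue = long$tissue, group = groups)
    agg <- aggregate(long$distance_um, by = key, FUN = function(v)
        c(mean = mean(v), sd = stats::sd(v), n = length(v)))
    out <- cbind(agg[, -ncol(agg), drop = FALSE],
        as.data.frame(agg$x))
    out$sd[out$n == 1] <- 0
    out
}

#' Summarize a distance table by tissue and group
#'
#' Per-tissue (and optionally per-group) mean, standard deviation and n of
#' the distance samples, with dropped-cell accounting. The raw samples stay
#' available in the table for external statistical testing.
#'
#' @param table a \linkS4class{DistanceTable}.
#' @param groups optional vector of group labels, one per row of the
#'   table's distances (e.g. the specialized class of each query cell).
#' @return a data frame with columns tissue, (group,) mean, sd, n.
#' @export
summarizeDistances <- function(table, groups = NULL) {
    stopifnot(is(table, "DistanceTable"))
    long <- table@distances
    if (!nrow(long))
        stop("empty distance table")
    if (!is.null(groups)) {
        stopifnot(length(groups) == nrow(long))
        keep <- !is.na(groups)
        if (!all(keep)) {
            warning(sum(!keep), " measurement(s) without a group omitted")
            long <- long[keep, , drop = FALSE]
            groups <- groups[keep]
        }
    }
    .distanceSummary(long, groups)
}

#' Distance samples of a DistanceTable
#' @param table a \linkS4class{DistanceTable}.
#' @return the long-format data frame (cell_id, tissue, distance_um).
#' @export
distanceSamples <- function(table) {
    stopifnot(is(table, "DistanceTable"))
    table@distances
}

## ---- pharynx border routing ----------------------------------------------

## Does the open segment p--q cross the open rectangle interior?
.crossesCavity <- function(p, q, xmin, xmax, ymin, ymax) {
    ## Liang-Barsky clip of the segment to the closed rectangle
    d <- q - p
    t0 <- 0
    t1 <- 1
    for (side in 1:4) {
        pk <- switch(side, -d[1L], d[1L], -d[2L], d[2L])
        qk <- switch(side, p[1L] - xmin, xmax - p[1L],
                           p[2L] - ymin, ymax - p[2L])
        if (pk == 0) {
            if (qk < 0) return(FALSE)
        } else {
            r <- qk / pk
            if (pk < 0) t0 <- max(t0, r) else t1 <- min(t1, r)
            if (t0 > t1) return(FALSE)
        }
    }
    if (t1 - t0 <= 1e-12) return(FALSE) # touches at a point / corner only
    mid <- p + ((t0 + t1) / 2) * d
    mid[1L] > xmin + 1e-12 && mid[1L] < xmax - 1e-12 &&
        mid[2L] > ymin + 1e-12 && mid[2L] < ymax - 1e-12
}

#' Border-routed path distance to the esophagus around the pharynx
#'
#' All pharyngeal progenitors enter the pharynx through a single anterior
#' connection (the esophagus) and do not traverse the pharyngeal cavity,
#' so the relevant distance is the shortest path that avoids the cavity:
#' the straight-line distance when the segment from the query to the
#' esophagus does not cross the cavity footprint, and otherwise the
#' minimum over routes that go straight to a cavity corner and then follow
#' the cavity borders to the esophagus — i.e. the shortest path on the
#' visibility graph whose obstacle is the cavity rectangle. The
#' construction is planar: the dorsoventral (z) coordinate is ignored and
#' anterior is +y.
#'
#' @param query query positions (n x 3 or n x 2 matrix, data frame or
#'   \linkS4class{CellField}); queries inside the open cavity are invalid.
#' @param cavity the cavity primitive: a list (or the single \code{cavity}
#'   primitive of a \linkS4class{TissueGeometry}) with \code{xmin},
#'   \code{xmax}, \code{ymin}, \code{ymax} and the esophagus \code{entry}
#'   point on the anterior face.
#' @return numeric vector of path distances (um).
#' @export
#' @examples
#' cav <- list(kind = "cavity", xmin = -1, xmax = 1, ymin = -1, ymax = 1,
#'             entry = c(0, 1))
#' pharynxPathDistance(c(0, -2, 0), cav)  # sqrt(2) + 2 + 1
pharynxPathDistance <- function(query, cavity) {
    if (is(cavity, "TissueGeometry")) {
        kinds <- vapply(cavity@primitives, function(p) p$kind, "")
        hit <- which(kinds == "cavity")
        if (length(hit) != 1L)
            stop("geometry must contain exactly one cavity primitive")
        cavity <- cavity@primitives[[hit]]
    }
    for (f in c("xmin", "xmax", "ymin", "ymax", "entry"))
        if (is.null(cavity[[f]]))
            stop("cavity primitive lacks '", f, "'")
    if (is.numeric(query) && is.null(dim(query)) && length(query) %in% 2:3)
        query <- matrix(query, nrow = 1L)
    q <- as.matrix(query)
    if (is(query, "CellField")) q <- cellPositions(query)
    if (ncol(q) >= 3L) q <- q[, 1:2, drop = FALSE]
    storage.mode(q) <- "double"
    xmin <- cavity$xmin; xmax <- cavity$xmax
    ymin <- cavity$ymin; ymax <- cavity$ymax
    e <- as.numeric(cavity$entry)
    inside <- q[, 1L] > xmin & q[, 1L] < xmax &
              q[, 2L] > ymin & q[, 2L] < ymax
    if (any(inside))
        stop(sum(inside), " query point(s) lie inside the pharyngeal cavity")
    corners <- rbind(A1 = c(xmin, ymax), A2 = c(xmax, ymax),
                     P1 = c(xmin, ymin), P2 = c(xmax, ymin))
    W <- xmax - xmin
    D <- ymax - ymin
    ## border path length from each corner to the esophagus entry
    dA1 <- e[1L] - xmin
    dA2 <- xmax - e[1L]
    border <- c(A1 = dA1, A2 = dA2,
        P1 = min(D + dA1, W + D + dA2),
        P2 = min(D + dA2, W + D + dA1))
    vapply(seq_len(nrow(q)), function(i) {
        p <- q[i, ]
        best <- Inf
        if (!.crossesCavity(p, e, xmin, xmax, ymin, ymax))
            best <- sqrt(sum((p - e)^2))
        for (cn in rownames(corners)) {
            cp <- corners[cn, ]
            if (!.crossesCavity(p, cp, xmin, xmax, ymin, ymax)) {
                d <- sqrt(sum((p - cp)^2)) + border[[cn]]
                if (d < best) best <- d
            }
        }
        best
    }, 0)
}
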