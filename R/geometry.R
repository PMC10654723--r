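#' Build a tissue geometry from primitive specifications
#'
#' Supported primitive kinds and parameters (all lengths in micrometres):
#' \describe{
#'   \item{plane}{\code{axis} ("x"/"y"/"z"), \code{value}: the axis-aligned
#'     plane \code{axis == value} (e.g. the epidermal shell).}
#'   \item{cylinder}{\code{axis}, \code{center} (2 values: coordinates on
#'     the remaining two axes, in xyz order), \code{radius}, optional
#'     \code{range} (2 values: axial extent). Distance is to the tube
#'     surface (an intestine branch).}
#'   \item{segment}{\code{p1}, \code{p2} (3D endpoints; a nerve cord).}
#'   \item{sphere}{\code{center} (3D), \code{radius}; solid (queries inside
#'     are at distance 0; an eye).}
#'   \item{points}{\code{coords}: an n x 3 matrix or data frame of mature
#'     cell centroids.}
#'   \item{cavity}{\code{xmin}, \code{xmax}, \code{ymin}, \code{ymax}
#'     (pharyngeal cavity footprint in the body plane, anterior = +y) and
#'     \code{entry} (2D esophagus point on the anterior face
#'     \code{y == ymax}). Used by \code{\link{pharynxPathDistance}}.}
#' }
#'
#' @param primitives named list of primitive specifications, each a list
#'   with a \code{kind} entry plus the parameters above.
#' @param volume optional \linkS4class{VolumeSpec}.
#' @return a \linkS4class{TissueGeometry}.
#' @export
#' @examples
#' geom <- buildTissueGeometry(list(
#'     epidermis = list(kind = "plane", axis = "z", value = 0),
#'     intestine = list(kind = "cylinder", axis = "y",
#'                      center = c(50, 50), radius = 20)))
#' distanceToSurface(c(0, 0, 10), geom, "epidermis")
buildTissueGeometry <- function(primitives, volume = NULL) {
    if (length(primitives) == 0L)
        stop("empty geometry specification")
    primitives <- lapply(primitives, function(pr) {
        if (!is.null(pr$coords))
            pr$coords <- .positionsMatrix(pr$coords)
        for (f in c("value", "radius", "center", "range", "p1", "p2",
                    "xmin", "xmax", "ymin", "ymax", "entry"))
            if (!is.null(pr[[f]])) pr[[f]] <- as.numeric(pr[[f]])
        pr
    })
    new("TissueGeometry", primitives = primitives, volume = volume)
}

#' Read / write tissue geometry as JSON
#'
#' JSON layout: a list of objects \code{{"name": ..., "kind": ...,
#' <parameters>}} (see \code{\link{buildTissueGeometry}}).
#'
#' @param path file path.
#' @param geometry a \linkS4class{TissueGeometry}.
#' @return \code{readTissueGeometry} returns a
#'   \linkS4class{TissueGeometry}; the writer invisibly returns
#'   \code{path}.
#' @export
readTissueGeometry <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE,
        simplifyDataFrame = FALSE)
    if (length(x) == 0L)
        stop("empty geometry specification")
    nms <- vapply(x, function(e) as.character(e$name %||% ""), "")
    prims <- lapply(x, function(e) e[setdiff(names(e), "name")])
    names(prims) <- nms
    buildTissueGeometry(prims)
}

#' @rdname readTissueGeometry
#' @export
writeTissueGeometry <- function(geometry, path) {
    stopifnot(is(geometry, "TissueGeometry"))
    out <- lapply(names(geometry@primitives), function(nm) {
        pr <- geometry@primitives[[nm]]
        if (!is.null(pr$coords))
            pr$coords <- unname(as.data.frame(pr$coords))
        c(list(name = nm), pr)
    })
    jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
        digits = NA)
    invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Straight-line distance from each query point to one primitive's surface.
.primitiveDistance <- function(q, pr) {
    switch(pr$kind,
        plane = abs(q[, .axisIndex(pr$axis)] - pr$value),
        cylinder = {
            ax <- .axisIndex(pr$axis)
            perp <- setdiff(1:3, ax)
            rp <- sqrt((q[, perp[1L]] - pr$center[1L])^2 +
                       (q[, perp[2L]] - pr$center[2L])^2)
            radial <- abs(rp - pr$radius)
            if (!is.null(pr$range)) {
                a <- q[, ax]
                da <- pmax(pr$range[1L] - a, a - pr$range[2L], 0)
                sqrt(da^2 + radial^2)
            } else radial
        },
        segment = {
            d <- pr$p2 - pr$p1
            len2 <- sum(d^2)
            rel <- sweep(q, 2L, pr$p1)
            t <- if (len2 > 0)
                pmin(pmax(as.vector(rel %*% d) / len2, 0), 1) else 0
            closest <- outer(t, d) # n x 3
            sqrt(rowSums((rel - closest)^2))
        },
        sphere = {
            d <- sqrt(rowSums(sweep(q, 2L, pr$center)^2))
            pmax(0, d - pr$radius)
        },
        points = {
            pts <- pr$coords
            apply(q, 1L, function(p)
                sqrt(min(colSums((t(pts) - p)^2))))
        },
        cavity = {
            dx <- pmax(pr$xmin - q[, 1L], q[, 1L] - pr$xmax, 0)
            dy <- pmax(pr$ymin - q[, 2L], q[, 2L] - pr$ymax, 0)
            sqrt(dx^2 + dy^2)
        },
        stop("unknown primitive kind: ", pr$kind))
}

#' Straight-line distance to a tissue surface
#'
#' Euclidean distance from each query point to the closest point of a
#' geometric primitive's surface. Solid primitives (sphere, cavity
#' footprint) return 0 for queries inside them.
#'
#' @param query 3D positions: an n x 3 matrix, a data frame with
#'   \code{x_um}/\code{y_um}/\code{z_um}, a \linkS4class{CellField}, or a
#'   single length-3 vector.
#' @param geometry a \linkS4class{TissueGeometry} (or a single primitive
#'   list with a \code{kind} entry).
#' @param primitive character(1): which named primitive to measure to
#'   (required when \code{geometry} holds more than one).
#' @return numeric vector of distances in micrometres.
#' @export
distanceToSurface <- function(query, geometry, primitive = NULL) {
    if (is.numeric(query) && is.null(dim(query)) && length(query) == 3L)
        query <- matrix(query, nrow = 1L)
    q <- .positionsMatrix(query)
    pr <- if (is(geometry, "TissueGeometry")) {
        if (is.null(primitive)) {
            if (length(geometry@primitives) != 1L)
                stop("specify which primitive to measure to")
            geometry@primitives[[1L]]
        } else {
            if (!primitive %in% names(geometry@primitives))
                stop("unknown primitive: ", primitive)
            geometry@primitives[[primitive]]
        }
    } else geometry
    if (is.null(pr$kind))
        stop("primitive must have a 'kind'")
    .primitiveDistance(q, pr)
}
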