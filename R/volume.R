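#' Construct a bounded tissue volume
#'
#' @param extents numeric(3), box edge lengths in micrometres
#'   (x = mediolateral, y = anteroposterior, z = dorsoventral), or a single
#'   value recycled to a cube.
#' @param origin numeric(3), lower box corner (default the origin).
#' @param slab optional \code{list(axis =, min =, max =)} restricting the
#'   volume to a slab along one axis, e.g. a thin optical section.
#' @return a \linkS4class{VolumeSpec}.
#' @export
#' @examples
#' VolumeSpec(300)                     # 300^3 um cube
#' VolumeSpec(c(200, 400, 100))
VolumeSpec <- function(extents, origin = c(0, 0, 0), slab = NULL) {
    if (length(extents) == 1L)
        extents <- rep(extents, 3L)
    stopifnot(length(extents) == 3L, length(origin) == 3L)
    new("VolumeSpec", lo = as.numeric(origin),
        hi = as.numeric(origin) + as.numeric(extents),
        slab = if (is.null(slab)) list() else slab)
}

## Effective sampling bounds: box corners after applying the slab.
.volumeBounds <- function(volume) {
    lo <- volume@lo
    hi <- volume@hi
    if (length(volume@slab)) {
        i <- .axisIndex(volume@slab$axis)
        lo[i] <- volume@slab$min
        hi[i] <- volume@slab$max
    }
    list(lo = lo, hi = hi)
}

#' Volume of a VolumeSpec in cubic micrometres
#' @param volume a \linkS4class{VolumeSpec}.
#' @return numeric(1), the (slab-restricted) volume in um^3.
#' @export
volumeSize <- function(volume) {
    b <- .volumeBounds(volume)
    prod(b$hi - b$lo)
}

## Is each row of an n x 3 matrix inside the (slab-restricted) volume?
.insideVolume <- function(positions, volume, tol = 1e-9) {
    b <- .volumeBounds(volume)
    ok <- rep(TRUE, nrow(positions))
    for (i in 1:3)
        ok <- ok & positions[, i] >= b$lo[i] - tol &
            positions[, i] <= b$hi[i] + tol
    ok
}
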