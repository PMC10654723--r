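#' Construct a CellField
#'
#' @param positions n x 3 numeric matrix (or data frame with
#'   \code{x_um}/\code{y_um}/\code{z_um}) of cell centroids in micrometres.
#' @param labels optional character vector of cell labels.
#' @param radii optional numeric vector of cell radii (um), or a single
#'   value recycled to all cells.
#' @param counts optional genes x cells integer matrix of transcript
#'   counts.
#' @param volume optional \linkS4class{VolumeSpec}.
#' @param ids cell identifiers; defaults to \code{cell_00001}-style ids or
#'   the rownames of \code{positions}.
#' @return a \linkS4class{CellField}.
#' @export
#' @examples
#' cf <- CellField(matrix(runif(30), ncol = 3) * 100,
#'                 labels = rep(c("A", "B"), 5))
#' cellPositions(cf)[1:2, ]
CellField <- function(positions, labels = NULL, radii = NULL,
        counts = NULL, volume = NULL, ids = NULL) {
    pos <- .positionsMatrix(positions)
    n <- nrow(pos)
    if (is.null(ids)) {
        ids <- rownames(pos)
        if (is.null(ids))
            ids <- sprintf("cell_%05d", seq_len(n))
    }
    if (anyDuplicated(ids))
        stop("duplicate cell ids")
    cd <- S4Vectors::DataFrame(x_um = pos[, 1L], y_um = pos[, 2L],
        z_um = pos[, 3L], row.names = ids)
    if (!is.null(radii)) {
        if (length(radii) == 1L) radii <- rep(radii, n)
        cd$radius_um <- as.numeric(radii)
    }
    if (!is.null(labels)) {
        if (length(labels) != n)
            stop("'labels' must have one entry per cell")
        cd$label <- as.character(labels)
    }
    if (is.null(counts)) {
        counts <- matrix(integer(0), nrow = 0L, ncol = n)
    } else {
        counts <- as.matrix(counts)
        if (ncol(counts) != n)
            stop("'counts' must have one column per cell")
        storage.mode(counts) <- "integer"
    }
    colnames(counts) <- ids
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = S4Vectors::SimpleList(counts = counts), colData = cd)
    new("CellField", se, volume = volume)
}

#' Transcript counts of a CellField
#' @param x a \linkS4class{CellField}.
#' @return genes x cells integer matrix.
#' @export
cellCounts <- function(x) {
    stopifnot(is(x, "CellField"))
    SummarizedExperiment::assay(x, "counts")
}
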