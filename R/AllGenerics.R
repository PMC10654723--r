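## Generics, accessors and show methods.

#' Cell positions, labels and radii
#'
#' Accessors for the spatial annotation of a \linkS4class{CellField}.
#' \code{cellPositions} returns the n x 3 centroid matrix (um) with columns
#' \code{x_um}, \code{y_um}, \code{z_um}; \code{cellLabels} the categorical
#' labels (or NULL); \code{cellRadii} the radii (um, or NULL);
#' \code{spatialVolume} the bounded volume the cells live in.
#'
#' @param x a \linkS4class{CellField}.
#' @param value replacement value.
#' @return see description.
#' @name cellPositions
#' @aliases cellPositions cellLabels cellLabels<- cellRadii spatialVolume
#' @export cellPositions cellLabels cellRadii spatialVolume
#' @exportMethod cellPositions cellLabels cellLabels<- cellRadii spatialVolume
NULL

setGeneric("cellPositions", function(x) standardGeneric("cellPositions"))
setGeneric("cellLabels", function(x) standardGeneric("cellLabels"))
setGeneric("cellLabels<-", function(x, value) standardGeneric("cellLabels<-"))
setGeneric("cellRadii", function(x) standardGeneric("cellRadii"))
setGeneric("spatialVolume", function(x) standardGeneric("spatialVolume"))

setMethod("cellPositions", "CellField", function(x) {
    cd <- SummarizedExperiment::colData(x)
    m <- cbind(x_um = cd$x_um, y_um = cd$y_um, z_um = cd$z_um)
    rownames(m) <- colnames(x)
    m
})

setMethod("cellLabels", "CellField", function(x) {
    cd <- SummarizedExperiment::colData(x)
    if ("label" %in% colnames(cd)) as.character(cd$label) else NULL
})

setMethod("cellLabels<-", "CellField", function(x, value) {
    SummarizedExperiment::colData(x)$label <- as.character(value)
    validObject(x)
    x
})

setMethod("cellRadii", "CellField", function(x) {
    cd <- SummarizedExperiment::colData(x)
    if ("radius_um" %in% colnames(cd)) cd$radius_um else NULL
})

setMethod("spatialVolume", "CellField", function(x) x@volume)

#' Marker panel accessors
#'
#' \code{poolNames} lists the pools; \code{poolGenes} returns the genes of
#' one pool; \code{panGene} the designated pan-neoblast gene;
#' \code{fstfPools}/\code{maturePools} the names of the fate-specific and
#' mature pools; \code{fateClasses} the fate class names (pool names with
#' the \code{"fstf:"} prefix stripped).
#'
#' @param x a \linkS4class{MarkerPanel}.
#' @param pool character(1) pool name.
#' @return character vector (see description).
#' @name poolNames
#' @aliases poolNames poolGenes panGene fstfPools maturePools fateClasses
#' @export poolNames poolGenes panGene fstfPools maturePools fateClasses
#' @exportMethod poolNames poolGenes panGene
NULL

setGeneric("poolNames", function(x) standardGeneric("poolNames"))
setGeneric("poolGenes", function(x, pool) standardGeneric("poolGenes"))
setGeneric("panGene", function(x) standardGeneric("panGene"))

setMethod("poolNames", "MarkerPanel", function(x) names(x@pools))
setMethod("poolGenes", "MarkerPanel", function(x, pool) {
    if (!pool %in% names(x@pools))
        stop("unknown pool: ", pool)
    x@pools[[pool]]
})
setMethod("panGene", "MarkerPanel", function(x) x@panGene)

#' @rdname poolNames
#' @export
fstfPools <- function(x) grep("^fstf:", poolNames(x), value = TRUE)

#' @rdname poolNames
#' @export
maturePools <- function(x) grep("^mature:", poolNames(x), value = TRUE)

#' @rdname poolNames
#' @export
fateClasses <- function(x) sub("^fstf:", "", fstfPools(x))

#' Neighbor graph accessors
#'
#' \code{adjacencyList} returns, for each cell, the integer indices of its
#' Voronoi facet-sharing neighbors; \code{nnMap} a \code{DataFrame} with
#' each cell's nearest-neighbor index, id and distance;
#' \code{boundaryCells} the logical flag marking cells whose Voronoi region
#' touches the clipping box.
#'
#' @param x a \linkS4class{NeighborGraph}.
#' @return see description.
#' @name adjacencyList
#' @aliases adjacencyList nnMap boundaryCells
#' @export adjacencyList nnMap boundaryCells
#' @exportMethod adjacencyList nnMap boundaryCells
NULL

setGeneric("adjacencyList", function(x) standardGeneric("adjacencyList"))
setGeneric("nnMap", function(x) standardGeneric("nnMap"))
setGeneric("boundaryCells", function(x) standardGeneric("boundaryCells"))

setMethod("adjacencyList", "NeighborGraph", function(x) {
    n <- length(x@ids)
    out <- vector("list", n)
    e <- x@edges
    if (nrow(e)) {
        nb <- split(c(e[, 2L], e[, 1L]), factor(c(e[, 1L], e[, 2L]),
            levels = seq_len(n)))
        out <- lapply(nb, function(v) sort(as.integer(v)))
    }
    names(out) <- x@ids
    out
})

setMethod("nnMap", "NeighborGraph", function(x) {
    S4Vectors::DataFrame(cell_id = x@ids, nn_index = x@nnIndex,
        nn_id = x@ids[x@nnIndex], nn_dist_um = x@nnDist, row.names = x@ids)
})

setMethod("boundaryCells", "NeighborGraph", function(x) {
    setNames(x@boundary, x@ids)
})

## show methods -------------------------------------------------------------

setMethod("show", "VolumeSpec", function(object) {
    ext <- object@hi - object@lo
    cat(sprintf("VolumeSpec: %.4g x %.4g x %.4g um box\n",
        ext[1L], ext[2L], ext[3L]))
    if (length(object@slab))
        cat(sprintf("  slab: %s in [%.4g, %.4g]\n", object@slab$axis,
            object@slab$min, object@slab$max))
})

setMethod("show", "MarkerPanel", function(object) {
    cat(sprintf("MarkerPanel: %d genes in %d pools (pan-neoblast gene: %s)\n",
        length(unlist(object@pools)), length(object@pools), object@panGene))
    for (nm in names(object@pools))
        cat(sprintf("  %-22s %d gene(s)\n", nm, length(object@pools[[nm]])))
})

setMethod("show", "TissueGeometry", function(object) {
    cat(sprintf("TissueGeometry: %d primitive(s)\n",
        length(object@primitives)))
    for (nm in names(object@primitives))
        cat(sprintf("  %-15s %s\n", nm, object@primitives[[nm]]$kind))
})

setMethod("show", "EmissionModel", function(object) {
    cat(sprintf(
        "EmissionModel: %d label(s) x %d component(s), dispersion = %g\n",
        nrow(object@means), ncol(object@means), object@dispersion))
    print(round(object@means, 3))
})

setMethod("show", "CellField", function(object) {
    callNextMethod()
    if (!is.null(object@volume)) {
        ext <- object@volume@hi - object@volume@lo
        cat(sprintf("volume: %.4g x %.4g x %.4g um\n",
            ext[1L], ext[2L], ext[3L]))
    }
})

setMethod("show", "NeighborGraph", function(object) {
    cat(sprintf(
        "NeighborGraph: %d cells, %d Voronoi adjacencies, %d boundary cell(s)\n",
        length(object@ids), nrow(object@edges), sum(object@boundary)))
    if (length(object@nnDist))
        cat(sprintf("  median NN distance: %.3g um\n",
            stats::median(object@nnDist)))
})

setMethod("show", "NullDistribution", function(object) {
    qc <- if (nzchar(object@queryClass)) object@queryClass else "<all cells>"
    cat(sprintf("NullDistribution: %s (query: %s)\n", object@statistic, qc))
    cat(sprintf("  observed %.2f%%; null mean %.2f%% [%d shuffles]\n",
        object@observed, mean(object@shuffles), length(object@shuffles)))
    cat(sprintf("  observed percentile within null: %.1f\n",
        object@percentile))
})

setMethod("show", "CompositionResult", function(object) {
    cat(sprintf(
        "CompositionResult (%s mode): query '%s', %d cell(s), %d dropped\n",
        object@mode, object@queryClass, nrow(object@perCell),
        object@dropped))
    print(round(object@aggregate, 2))
})

setMethod("show", "DistanceTable", function(object) {
    cat(sprintf("DistanceTable: %d measurement(s), %d tissue(s)\n",
        nrow(object@distances), length(unique(object@distances$tissue))))
    print(object@summary)
})
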