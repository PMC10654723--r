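## Class definitions and validity. Constructors live with their modules.

#' VolumeSpec: an axis-aligned bounded tissue volume
#'
#' Describes the box (in micrometres) inside which cells live, with an
#' optional slab restriction along one axis (e.g. an optical section).
#' Axes follow the package convention x = mediolateral, y = anteroposterior
#' (anterior = +y), z = dorsoventral.
#'
#' @slot lo,hi numeric(3), lower and upper box corners in micrometres.
#' @slot slab empty list, or \code{list(axis=, min=, max=)} restricting
#'   sampling to a slab along one axis ("x", "y" or "z").
#' @aliases VolumeSpec-class
#' @exportClass VolumeSpec
setClass("VolumeSpec",
    representation(lo = "numeric", hi = "numeric", slab = "list"))

setValidity("VolumeSpec", function(object) {
    msg <- NULL
    if (length(object@lo) != 3L || length(object@hi) != 3L)
        msg <- c(msg, "'lo' and 'hi' must have length 3")
    else {
        if (!all(is.finite(object@lo)) || !all(is.finite(object@hi)))
            msg <- c(msg, "box corners must be finite")
        else if (!all(object@hi > object@lo))
            msg <- c(msg, "all box extents must be > 0")
    }
    if (length(object@slab)) {
        s <- object@slab
        if (!all(c("axis", "min", "max") %in% names(s)))
            msg <- c(msg, "slab needs 'axis', 'min' and 'max'")
        else {
            ax <- match(s$axis, c("x", "y", "z"))
            if (is.na(ax))
                msg <- c(msg, "slab axis must be one of 'x', 'y', 'z'")
            else if (s$min >= s$max ||
                     s$min < object@lo[ax] || s$max > object@hi[ax])
                msg <- c(msg, "slab bounds must be ordered and inside the box")
        }
    }
    if (is.null(msg)) TRUE else msg
})

setClassUnion("VolumeSpecOrNULL", c("VolumeSpec", "NULL"))

#' MarkerPanel: partition of genes into marker pools
#'
#' A panel maps every gene to exactly one pool. Pools are named
#' \code{"neoblast_core"} (the pan-neoblast gene \emph{smedwi-1} plus
#' additional neoblast-enriched markers), \code{"fstf:<fate>"} (one pool of
#' fate-specific transcription factors per fate class) and
#' \code{"mature:<tissue>"} (mature tissue markers).
#'
#' @slot pools named list of character vectors of gene identifiers.
#' @slot panGene character(1), the designated pan-neoblast gene; must be a
#'   member of the \code{neoblast_core} pool.
#' @aliases MarkerPanel-class
#' @exportClass MarkerPanel
setClass("MarkerPanel",
    representation(pools = "list", panGene = "character"))

setValidity("MarkerPanel", function(object) {
    msg <- NULL
    p <- object@pools
    if (is.null(names(p)) || any(!nzchar(names(p))))
        msg <- c(msg, "all pools must be named")
    if (!"neoblast_core" %in% names(p))
        msg <- c(msg, "panel must contain a 'neoblast_core' pool")
    if (any(lengths(p) == 0L))
        msg <- c(msg, "every pool must contain at least one gene")
    genes <- unlist(p, use.names = FALSE)
    if (anyDuplicated(genes))
        msg <- c(msg, sprintf("genes assigned to more than one pool: %s",
            paste(unique(genes[duplicated(genes)]), collapse = ", ")))
    if (length(object@panGene) != 1L)
        msg <- c(msg, "exactly one pan-neoblast gene must be designated")
    else if ("neoblast_core" %in% names(p) &&
             !object@panGene %in% p[["neoblast_core"]])
        msg <- c(msg, "the pan-neoblast gene must belong to 'neoblast_core'")
    if (is.null(msg)) TRUE else msg
})

#' EmissionModel: per-label Poisson transcript emission
#'
#' Mean transcript counts per cell for each label, split into emission
#' components: \code{"pan"} (the pan-neoblast gene), \code{"core_other"}
#' (total over the remaining neoblast-core genes) and one component per
#' FSTF or mature pool (total over the pool's genes, split uniformly across
#' them at simulation time). Cross-pool leakage is expressed simply as
#' nonzero means in off-target pool columns.
#'
#' @slot means numeric matrix, rows = labels, columns = emission components.
#' @slot dispersion numeric(1); 0 gives Poisson counts, values > 0 give
#'   negative-binomial counts with size = 1/dispersion (same means).
#' @aliases EmissionModel-class
#' @exportClass EmissionModel
setClass("EmissionModel",
    representation(means = "matrix", dispersion = "numeric"))

setValidity("EmissionModel", function(object) {
    msg <- NULL
    m <- object@means
    if (is.null(rownames(m)) || is.null(colnames(m)))
        msg <- c(msg, "'means' must have label rownames and component colnames")
    if (!is.numeric(m) || any(m < 0) || any(!is.finite(m)))
        msg <- c(msg, "all emission means must be finite and >= 0")
    if (length(object@dispersion) != 1L || object@dispersion < 0)
        msg <- c(msg, "'dispersion' must be a single value >= 0")
    if (is.null(msg)) TRUE else msg
})

#' TissueGeometry: named geometric primitives for mature anatomy
#'
#' A queryable collection of simple primitives standing in for mature
#' tissues: \code{plane} (epidermal shell), \code{cylinder} (intestine
#' branch), \code{segment} (nerve cord), \code{sphere} (eye), \code{points}
#' (arbitrary mature-cell centroids) and \code{cavity} (the pharyngeal
#' cavity: an axis-aligned box with a designated esophagus entry point on
#' its anterior face).
#'
#' @slot primitives named list; each element has \code{$kind} plus
#'   kind-specific parameters (see \code{\link{buildTissueGeometry}}).
#' @slot volume a \linkS4class{VolumeSpec} or NULL.
#' @aliases TissueGeometry-class
#' @exportClass TissueGeometry
setClass("TissueGeometry",
    representation(primitives = "list", volume = "VolumeSpecOrNULL"))

setValidity("TissueGeometry", function(object) {
    msg <- NULL
    p <- object@primitives
    if (length(p) == 0L)
        msg <- c(msg, "geometry must contain at least one primitive")
    if (is.null(names(p)) || any(!nzchar(names(p))) || anyDuplicated(names(p)))
        msg <- c(msg, "primitives must have unique non-empty names")
    kinds <- c("plane", "cylinder", "segment", "sphere", "points", "cavity")
    for (nm in names(p)) {
        pr <- p[[nm]]
        if (is.null(pr$kind) || !pr$kind %in% kinds) {
            msg <- c(msg, sprintf("primitive '%s' has unknown kind", nm))
            next
        }
        if (pr$kind == "cavity") {
            e <- pr$entry
            if (is.null(e) || length(e) != 2L)
                msg <- c(msg, sprintf(
                    "cavity '%s' needs a 2D 'entry' (esophagus) point", nm))
            else if (abs(e[2L] - pr$ymax) > 1e-9 ||
                     e[1L] < pr$xmin - 1e-9 || e[1L] > pr$xmax + 1e-9)
                msg <- c(msg, sprintf(
                    "cavity '%s': entry point must lie on the anterior (y = ymax) face",
                    nm))
            if (!is.null(pr$xmin) && (pr$xmin >= pr$xmax || pr$ymin >= pr$ymax))
                msg <- c(msg, sprintf("cavity '%s' has empty footprint", nm))
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' CellField: cells with 3D positions, labels and transcript counts
#'
#' The central container: a \linkS4class{SummarizedExperiment} whose columns
#' are cells. \code{colData} carries the centroid coordinates
#' (\code{x_um}, \code{y_um}, \code{z_um}), an optional \code{radius_um}
#' and an optional categorical \code{label}; the \code{"counts"} assay
#' (genes x cells, possibly zero genes) carries integer transcript counts.
#'
#' @slot volume a \linkS4class{VolumeSpec} or NULL, the bounded volume the
#'   cells were sampled from or imaged in.
#' @aliases CellField-class
#' @exportClass CellField
setClass("CellField",
    contains = "SummarizedExperiment",
    representation(volume = "VolumeSpecOrNULL"))

setValidity("CellField", function(object) {
    msg <- NULL
    cd <- SummarizedExperiment::colData(object)
    need <- c("x_um", "y_um", "z_um")
    if (!all(need %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'x_um', 'y_um' and 'z_um'")
    else {
        xyz <- as.matrix(cd[, need])
        if (!is.numeric(xyz) || any(!is.finite(xyz)))
            msg <- c(msg, "cell coordinates must be finite numbers")
    }
    if ("radius_um" %in% colnames(cd) && any(cd$radius_um < 0, na.rm = TRUE))
        msg <- c(msg, "cell radii must be >= 0")
    if (anyDuplicated(colnames(object)))
        msg <- c(msg, "duplicate cell ids")
    if (length(SummarizedExperiment::assayNames(object)) &&
        "counts" %in% SummarizedExperiment::assayNames(object)) {
        cts <- SummarizedExperiment::assay(object, "counts")
        if (nrow(cts) > 0) {
            if (any(cts < 0) || any(cts != round(cts)))
                msg <- c(msg, "counts must be non-negative integers")
        }
    }
    if (is.null(msg)) TRUE else msg
})

#' NeighborGraph: Voronoi adjacency and nearest-neighbor map
#'
#' Symmetric Voronoi facet-sharing adjacency over a cell set (regions
#' clipped to a bounding box), together with the (asymmetric) Euclidean
#' nearest-neighbor map and a per-cell boundary flag marking cells whose
#' Voronoi region touches the clipping box.
#'
#' @slot ids character, cell identifiers (nodes).
#' @slot edges integer matrix with two columns, each row one unordered
#'   adjacent pair (i < j, indices into \code{ids}).
#' @slot facetAreas numeric, shared Voronoi facet area (um^2) per edge.
#' @slot nnIndex integer, index of each cell's nearest neighbor.
#' @slot nnDist numeric, distance to the nearest neighbor (um).
#' @slot boundary logical, TRUE if the cell's region touches the box.
#' @aliases NeighborGraph-class
#' @exportClass NeighborGraph
setClass("NeighborGraph",
    representation(ids = "character", edges = "matrix",
        facetAreas = "numeric", nnIndex = "integer",
        nnDist = "numeric", boundary = "logical"))

setValidity("NeighborGraph", function(object) {
    msg <- NULL
    n <- length(object@ids)
    e <- object@edges
    if (ncol(e) != 2L)
        msg <- c(msg, "'edges' must have two columns")
    else if (nrow(e)) {
        if (any(e < 1L) || any(e > n))
            msg <- c(msg, "edge indices out of range")
        if (any(e[, 1L] >= e[, 2L]))
            msg <- c(msg, "edges must be stored with i < j (irreflexive)")
        if (anyDuplicated(e))
            msg <- c(msg, "duplicate edges")
    }
    if (length(object@facetAreas) != nrow(e))
        msg <- c(msg, "one facet area per edge required")
    if (length(object@nnIndex) != n || length(object@nnDist) != n ||
        length(object@boundary) != n)
        msg <- c(msg, "per-cell slots must match the number of ids")
    if (n > 0 && length(object@nnIndex) == n &&
        any(object@nnIndex == seq_len(n), na.rm = TRUE))
        msg <- c(msg, "a cell cannot be its own nearest neighbor")
    if (is.null(msg)) TRUE else msg
})

#' NullDistribution: a permutation null for a neighborhood statistic
#'
#' Holds the observed self-neighbor percentage for a query class, its values
#' over label shuffles (labels permuted over fixed positions, preserving the
#' label multiset), the observed percentile rank within the null, and the
#' full per-shuffle nearest-neighbor label composition.
#'
#' @slot statistic character(1), description of the statistic.
#' @slot queryClass character(1), the query label ("" = all cells).
#' @slot observed numeric(1), observed statistic (percent).
#' @slot shuffles numeric, the statistic over label shuffles (percent).
#' @slot percentile numeric(1), percentile rank of the observed value.
#' @slot observedComposition named numeric, observed neighbor-label
#'   percentages for the query class.
#' @slot shuffleComposition numeric matrix (shuffles x labels) of
#'   neighbor-label percentages per shuffle.
#' @aliases NullDistribution-class
#' @exportClass NullDistribution
setClass("NullDistribution",
    representation(statistic = "character", queryClass = "character",
        observed = "numeric", shuffles = "numeric", percentile = "numeric",
        observedComposition = "numeric", shuffleComposition = "matrix"))

setValidity("NullDistribution", function(object) {
    msg <- NULL
    if (length(object@observed) != 1L || length(object@percentile) != 1L)
        msg <- c(msg, "'observed' and 'percentile' must be single values")
    if (length(object@shuffles) < 1L)
        msg <- c(msg, "at least one shuffle value required")
    if (length(object@percentile) == 1L &&
        (object@percentile < 0 || object@percentile > 100))
        msg <- c(msg, "percentile must lie in [0, 100]")
    if (is.null(msg)) TRUE else msg
})

#' CompositionResult: neighborhood identity composition for a query class
#'
#' Per-query-cell neighbor counts and per-label neighbor fractions, plus the
#' aggregate representation: stacked percentages over neighbor labels
#' (nearest-neighbor mode) and binned histograms of per-cell fractions
#' (Voronoi mode, the ridgeline data).
#'
#' @slot perCell a \code{DataFrame}: one row per query cell with its
#'   neighbor count and per-label neighbor fractions.
#' @slot aggregate named numeric, per-label percentage (sums to 100).
#' @slot histogram numeric matrix (bins x labels) of per-cell fraction
#'   histograms, or a 0-row matrix in nearest-neighbor mode.
#' @slot bins numeric, histogram bin edges.
#' @slot mode character(1), \code{"nn"} or \code{"voronoi"}.
#' @slot queryClass character(1).
#' @slot dropped integer(1), query cells excluded (isolated / boundary).
#' @aliases CompositionResult-class
#' @exportClass CompositionResult
setClass("CompositionResult",
    representation(perCell = "DataFrame", aggregate = "numeric",
        histogram = "matrix", bins = "numeric", mode = "character",
        queryClass = "character", dropped = "integer"))

setValidity("CompositionResult", function(object) {
    msg <- NULL
    if (!object@mode %in% c("nn", "voronoi"))
        msg <- c(msg, "mode must be 'nn' or 'voronoi'")
    if (length(object@aggregate) &&
        abs(sum(object@aggregate) - 100) > 1e-6)
        msg <- c(msg, "aggregate percentages must sum to 100")
    if (is.null(msg)) TRUE else msg
})

#' DistanceTable: distances from query cells to mature tissues
#'
#' @slot distances data.frame in long format: \code{cell_id},
#'   \code{tissue}, \code{distance_um}.
#' @slot summary data.frame of per-tissue (optionally per-group) mean, SD
#'   and n.
#' @slot dropped named integer, per-tissue count of dropped queries.
#' @aliases DistanceTable-class
#' @exportClass DistanceTable
setClass("DistanceTable",
    representation(distances = "data.frame", summary = "data.frame",
        dropped = "integer"))

setValidity("DistanceTable", function(object) {
    d <- object@distances
    msg <- NULL
    if (!all(c("cell_id", "tissue", "distance_um") %in% colnames(d)))
        msg <- c(msg, "distances need columns cell_id, tissue, distance_um")
    else if (any(d$distance_um < 0, na.rm = TRUE))
        msg <- c(msg, "distances must be >= 0")
    if (is.null(msg)) TRUE else msg
})
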