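## Internal helpers.

## Run code under a fixed RNG seed without disturbing the caller's RNG state.
.withSeed <- function(seed, code) {
    if (is.null(seed))
        return(code)
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    withr::with_seed(as.integer(seed), code,
        .rng_kind = "Mersenne-Twister", .rng_normal_kind = "Inversion",
        .rng_sample_kind = "Rejection")
}

#' Derive a per-stage seed from a master seed
#'
#' Stable 31-bit hash of (master seed, stage name), so that adding or
#' reordering pipeline stages never perturbs the random streams of other
#' stages. Pure arithmetic, identical across platforms and sessions.
#'
#' @param master integer master seed.
#' @param stage character(1) stage name.
#' @return a single integer in [0, 2^31 - 2] usable with \code{set.seed}.
#' @export
#' @examples
#' deriveSeed(1, "simulate") != deriveSeed(1, "classify")
deriveSeed <- function(master, stage) {
    stopifnot(length(stage) == 1L, is.character(stage))
    m <- 2147483647 # 2^31 - 1, prime
    h <- (as.numeric(master) %% m + m) %% m
    for (code in utf8ToInt(stage))
        h <- (h * 31 + code) %% m
    as.integer(h)
}

## Coerce positions input (matrix / data.frame / CellField) to an n x 3
## numeric matrix with rownames as cell ids.
.positionsMatrix <- function(positions) {
    if (is(positions, "CellField"))
        return(cellPositions(positions))
    if (is.data.frame(positions)) {
        cols <- intersect(c("x_um", "y_um", "z_um"), colnames(positions))
        if (length(cols) == 3L) {
            ids <- if ("cell_id" %in% colnames(positions))
                as.character(positions$cell_id) else rownames(positions)
            positions <- as.matrix(positions[, cols])
            rownames(positions) <- ids
        } else positions <- as.matrix(positions)
    }
    positions <- as.matrix(positions)
    if (ncol(positions) != 3L)
        stop("positions must be an n x 3 matrix of 3D coordinates")
    storage.mode(positions) <- "double"
    if (any(!is.finite(positions)))
        stop("positions must be finite")
    positions
}

## Validate a class-frequency table: named, >= 0, sums to 1 within 1e-9.
.checkFreqs <- function(freqs) {
    if (is.null(names(freqs)) || any(!nzchar(names(freqs))))
        stop("class frequencies must be a named numeric vector")
    if (any(freqs < 0))
        stop("class frequencies must be >= 0")
    if (abs(sum(freqs) - 1) > 1e-9)
        stop(sprintf("class frequencies must sum to 1 (got %.12g)",
            sum(freqs)))
    freqs
}

## Full pairwise Euclidean distance matrix (small n); diagonal = Inf.
.pairwiseDistances <- function(positions) {
    d <- as.matrix(stats::dist(positions))
    diag(d) <- Inf
    d
}

.axisIndex <- function(axis) {
    i <- match(axis, c("x", "y", "z"))
    if (is.na(i))
        stop("axis must be one of 'x', 'y', 'z'")
    i
}
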