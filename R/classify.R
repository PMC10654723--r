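## Rule-based cell calling from per-cell transcript counts: neoblasts,
## specialized neoblasts, smedwi-1-low progenitors and mature cells.

#' Classifier thresholds
#'
#' Threshold rules for the transcript-count classifier. Defaults follow the
#' published calling rules: a neoblast requires >= 5 pan-neoblast
#' (\emph{smedwi-1}) transcripts and >= 6 transcripts pooled over the other
#' neoblast-core markers (thresholds originally set by median splitting); a
#' specialized call requires a total FSTF count >= 5 with a strict majority
#' (> 50 percent) for a single fate pool; smedwi-1-low progenitors carry
#' 1-4 pan-neoblast transcripts plus a passing fate signature; mature calls
#' mirror the specialized rule over mature pools.
#'
#' @param smedwiMin minimum pan-neoblast transcripts for a neoblast call.
#' @param neoblastOtherMin minimum pooled other neoblast-core transcripts.
#' @param fstfTotalMin minimum total FSTF transcripts for a fate signature.
#' @param fstfMajority strict-majority fraction for the top fate pool.
#' @param smedwiLowMax upper pan-neoblast bound (inclusive) of the
#'   progenitor band; the lower bound is 1.
#' @param matureMin minimum own-pool transcripts for a mature call.
#' @return a validated list of thresholds.
#' @export
#' @examples
#' classifierConfig()
classifierConfig <- function(smedwiMin = 5, neoblastOtherMin = 6,
        fstfTotalMin = 5, fstfMajority = 0.5, smedwiLowMax = 4,
        matureMin = 5) {
    cfg <- list(smedwiMin = smedwiMin, neoblastOtherMin = neoblastOtherMin,
        fstfTotalMin = fstfTotalMin, fstfMajority = fstfMajority,
        smedwiLowMax = smedwiLowMax, matureMin = matureMin)
    if (any(vapply(cfg, function(v) !is.numeric(v) || length(v) != 1L ||
            v < 0, TRUE)))
        stop("all thresholds must be single values >= 0")
    if (cfg$fstfMajority <= 0 || cfg$fstfMajority >= 1)
        stop("'fstfMajority' must lie strictly between 0 and 1")
    cfg
}

## counts as genes x cells matrix from matrix / CellField input
.countsMatrix <- function(x) {
    if (is(x, "CellField")) x <- cellCounts(x)
    x <- as.matrix(x)
    if (nrow(x) == 0L)
        stop("no transcript counts available")
    x
}

## cells x pools matrix of pooled counts (genes absent from the counts are
## treated as unmeasured and contribute 0)
.poolTotals <- function(counts, panel, pools) {
    out <- matrix(0, nrow = ncol(counts), ncol = length(pools),
        dimnames = list(colnames(counts), pools))
    for (pool in pools) {
        g <- intersect(poolGenes(panel, pool), rownames(counts))
        if (length(g) == 1L) out[, pool] <- counts[g, ]
        else if (length(g) > 1L) out[, pool] <- colSums(counts[g, ,
            drop = FALSE])
    }
    out
}

#' Call neoblasts from transcript counts
#'
#' A cell is called a neoblast iff its pan-neoblast gene count is at least
#' \code{smedwiMin} and its pooled count over the remaining neoblast-core
#' markers is at least \code{neoblastOtherMin}.
#'
#' @param x genes x cells count matrix or a \linkS4class{CellField} with a
#'   counts assay.
#' @param panel a \linkS4class{MarkerPanel}; its pan-neoblast gene must be
#'   present in the counts.
#' @param cfg thresholds from \code{\link{classifierConfig}}.
#' @return named logical vector, one entry per cell.
#' @export
#' @examples
#' panel <- defaultMarkerPanel()
#' cts <- simulateCounts(c(a = "neoblast:unassigned", b = "other"),
#'     panel, defaultEmissionModel(panel), seed = 1)
#' callNeoblasts(cts, panel)
callNeoblasts <- function(x, panel, cfg = classifierConfig()) {
    counts <- .countsMatrix(x)
    pan <- panGene(panel)
    if (!pan %in% rownames(counts))
        stop("pan-neoblast gene '", pan, "' missing from counts")
    others <- intersect(.coreOtherGenes(panel), rownames(counts))
    if (!length(others))
        stop("no non-pan neoblast-core marker genes in counts")
    smedwi <- counts[pan, ]
    otherTotal <- if (length(others) == 1L) counts[others, ]
        else colSums(counts[others, , drop = FALSE])
    setNames(smedwi >= cfg$smedwiMin & otherTotal >= cfg$neoblastOtherMin,
        colnames(counts))
}

## Fate-signature rule shared by specialized and progenitor calling:
## total FSTF count >= fstfTotalMin and a strict unique majority pool.
.fateSignature <- function(fstf, cfg) {
    total <- rowSums(fstf)
    topVal <- apply(fstf, 1L, max)
    nTop <- rowSums(fstf == topVal & topVal > 0)
    pass <- total >= cfg$fstfTotalMin &
        topVal > cfg$fstfMajority * total & nTop == 1L
    cls <- rep(NA_character_, nrow(fstf))
    if (any(pass)) {
        top <- apply(fstf[pass, , drop = FALSE], 1L, which.max)
        cls[pass] <- sub("^fstf:", "", colnames(fstf)[top])
    }
    list(pass = pass, class = cls, total = total)
}

#' Assign specialized-neoblast fate classes
#'
#' Among cells called neoblast, assigns the fate class whose FSTF pool
#' holds a strict majority (> \code{fstfMajority}) of the cell's total FSTF
#' transcripts, provided that total is at least \code{fstfTotalMin}. Cells
#' with a low FSTF total, no strict single-class majority, or an exact tie
#' between top pools remain \code{"unassigned"}.
#'
#' @inheritParams callNeoblasts
#' @param neoblastCalls logical vector from \code{\link{callNeoblasts}}.
#' @return named character vector: a fate class or \code{"unassigned"} for
#'   neoblasts, \code{NA} for non-neoblasts.
#' @export
callSpecialized <- function(x, neoblastCalls, panel,
        cfg = classifierConfig()) {
    counts <- .countsMatrix(x)
    stopifnot(length(neoblastCalls) == ncol(counts))
    fstf <- .poolTotals(counts, panel, fstfPools(panel))
    sig <- .fateSignature(fstf, cfg)
    out <- rep(NA_character_, ncol(counts))
    out[neoblastCalls] <- ifelse(sig$pass[neoblastCalls],
        sig$class[neoblastCalls], "unassigned")
    setNames(out, colnames(counts))
}

#' Call smedwi-1-low progenitors
#'
#' Early post-mitotic progenitors retain a low pan-neoblast signal (1 to
#' \code{smedwiLowMax} transcripts, below the neoblast band) while carrying
#' a passing fate signature (same rule as specialized neoblasts). Cells
#' with zero pan-neoblast transcripts are never called.
#'
#' @inheritParams callNeoblasts
#' @return a \code{DataFrame} with per-cell \code{is_progenitor} and
#'   \code{progenitor_class} (\code{NA} when not called).
#' @export
callSmedwiLowProgenitors <- function(x, panel, cfg = classifierConfig()) {
    counts <- .countsMatrix(x)
    pan <- panGene(panel)
    if (!pan %in% rownames(counts))
        stop("pan-neoblast gene '", pan, "' missing from counts")
    smedwi <- counts[pan, ]
    fstf <- .poolTotals(counts, panel, fstfPools(panel))
    sig <- .fateSignature(fstf, cfg)
    isLow <- smedwi >= 1 & smedwi <= cfg$smedwiLowMax
    called <- isLow & sig$pass
    S4Vectors::DataFrame(
        is_progenitor = unname(called),
        progenitor_class = unname(ifelse(called, sig$class,
            NA_character_)),
        row.names = colnames(counts))
}

#' Call mature cells
#'
#' Among cells not called neoblast, assigns the mature tissue whose pool
#' holds at least \code{matureMin} transcripts and a strict majority of the
#' cell's mature-pool transcripts (the count-only analogue of marker-pool
#' plus anatomical-position assignment).
#'
#' @inheritParams callSpecialized
#' @return named character vector: a mature tissue or \code{NA}; always
#'   \code{NA} for cells called neoblast (the calls are exclusive).
#' @export
callMature <- function(x, neoblastCalls, panel, cfg = classifierConfig()) {
    counts <- .countsMatrix(x)
    stopifnot(length(neoblastCalls) == ncol(counts))
    pools <- maturePools(panel)
    out <- rep(NA_character_, ncol(counts))
    if (length(pools)) {
        mat <- .poolTotals(counts, panel, pools)
        total <- rowSums(mat)
        topVal <- apply(mat, 1L, max)
        nTop <- rowSums(mat == topVal & topVal > 0)
        pass <- !neoblastCalls & topVal >= cfg$matureMin &
            topVal > 0.5 * total & nTop == 1L
        if (any(pass)) {
            top <- apply(mat[pass, , drop = FALSE], 1L, which.max)
            out[pass] <- sub("^mature:", "", pools[top])
        }
    }
    setNames(out, colnames(counts))
}

#' Run the full transcript-count classifier
#'
#' Applies neoblast, specialized, progenitor and mature calling and
#' collects the results in one call table.
#'
#' @inheritParams callNeoblasts
#' @return a \code{DataFrame} with columns \code{is_neoblast},
#'   \code{specialized_class}, \code{is_progenitor},
#'   \code{progenitor_class}, \code{mature_tissue} and a matrix column
#'   \code{fstf_counts} of per-fate-pool transcript totals.
#' @export
#' @examples
#' cf <- simulateCellField(100, seed = 1)
#' calls <- classifyCells(cf)
#' table(calls$specialized_class, useNA = "ifany")
classifyCells <- function(x, panel = defaultMarkerPanel(),
        cfg = classifierConfig()) {
    counts <- .countsMatrix(x)
    nb <- callNeoblasts(counts, panel, cfg)
    spec <- callSpecialized(counts, nb, panel, cfg)
    prog <- callSmedwiLowProgenitors(counts, panel, cfg)
    mat <- callMature(counts, nb, panel, cfg)
    fstf <- .poolTotals(counts, panel, fstfPools(panel))
    out <- S4Vectors::DataFrame(
        is_neoblast = unname(nb),
        specialized_class = unname(spec),
        is_progenitor = prog$is_progenitor,
        progenitor_class = prog$progenitor_class,
        mature_tissue = unname(mat),
        row.names = colnames(counts))
    out$fstf_counts <- fstf
    out
}

#' Specialized-class frequencies among neoblasts
#'
#' Fraction of all called neoblasts assigned to each specialized class,
#' plus the unassigned remainder; the fractions sum to 1.
#'
#' @param calls a call table from \code{\link{classifyCells}}, or a
#'   character vector of per-neoblast classes.
#' @return named numeric vector of fractions.
#' @export
classFrequencies <- function(calls) {
    cls <- if (is.character(calls)) calls[!is.na(calls)]
        else as.character(calls$specialized_class[calls$is_neoblast])
    if (!length(cls))
        stop("no neoblast calls: class frequencies are undefined")
    tab <- table(cls)
    setNames(as.numeric(tab) / length(cls), names(tab))
}
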