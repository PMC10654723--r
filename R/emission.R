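#' Construct an emission model
#'
#' @param means numeric matrix of mean transcript counts per cell; rows are
#'   labels, columns are emission components: \code{"pan"} (pan-neoblast
#'   gene), \code{"core_other"} (total over remaining neoblast-core genes)
#'   and pool names (\code{"fstf:<fate>"}, \code{"mature:<tissue>"}; each a
#'   pool total, split uniformly over the pool's genes when simulating).
#' @param dispersion numeric(1) >= 0; 0 (default) gives Poisson counts,
#'   values > 0 give negative-binomial counts with size = 1/dispersion.
#' @return an \linkS4class{EmissionModel}.
#' @seealso \code{\link{defaultEmissionModel}}, \code{\link{simulateCounts}}
#' @export
EmissionModel <- function(means, dispersion = 0) {
    new("EmissionModel", means = means, dispersion = as.numeric(dispersion))
}

#' Default emission model calibrated to reported call statistics
#'
#' Neoblast-labeled cells emit on average 8 pan-neoblast (\emph{smedwi-1})
#' transcripts and 37 transcripts pooled over the other neoblast-core
#' markers; all non-neoblast labels emit 1 and 8 respectively — matching
#' the reported conditional means of positive and negative neoblast calls.
#' A specialized neoblast additionally emits a mean of \code{fstfMean}
#' transcripts in its own FSTF pool and \code{leakage} in each other FSTF
#' pool (markers enriched in, but not exclusive to, one class). Mature
#' cells emit \code{matureMean} transcripts in their own mature pool.
#'
#' @param panel a \linkS4class{MarkerPanel}; labels and pools are taken
#'   from it.
#' @param fstfMean mean on-target FSTF pool total for specialized
#'   neoblasts (default 10).
#' @param leakage mean off-target FSTF pool total for specialized
#'   neoblasts (default 0.5).
#' @param matureMean mean own-pool total for mature cells (default 20).
#' @param dispersion see \code{\link{EmissionModel}} (default 0, Poisson).
#' @return an \linkS4class{EmissionModel} whose row labels are
#'   \code{neoblast:<fate>} for every fate class in the panel,
#'   \code{neoblast:unassigned}, \code{mature:<tissue>} for every mature
#'   pool, and \code{other}.
#' @export
#' @examples
#' defaultEmissionModel(defaultMarkerPanel())
defaultEmissionModel <- function(panel = defaultMarkerPanel(),
        fstfMean = 10, leakage = 0.5, matureMean = 20, dispersion = 0) {
    fp <- fstfPools(panel)
    mp <- maturePools(panel)
    comps <- c("pan", "core_other", fp, mp)
    labels <- unique(c(paste0("neoblast:", sub("^fstf:", "", fp)),
        "neoblast:unassigned", mp, "other"))
    m <- matrix(0, nrow = length(labels), ncol = length(comps),
        dimnames = list(labels, comps))
    nb <- startsWith(labels, "neoblast:")
    m[nb, "pan"] <- 8
    m[nb, "core_other"] <- 37
    m[!nb, "pan"] <- 1
    m[!nb, "core_other"] <- 8
    for (pool in fp) {
        fate <- sub("^fstf:", "", pool)
        row <- paste0("neoblast:", fate)
        if (row %in% labels) {
            m[row, fp] <- leakage
            m[row, pool] <- fstfMean
        }
    }
    for (pool in mp)
        m[pool, pool] <- matureMean
    EmissionModel(m, dispersion = dispersion)
}

#' Simulate per-cell transcript counts
#'
#' Draws independent counts per gene for each cell according to its label's
#' emission means: each component mean is split uniformly across the genes
#' of the corresponding pool and counts are drawn as Poisson (or
#' negative-binomial when the model has dispersion > 0).
#'
#' @param labels character vector of cell labels; every label must be a row
#'   of \code{model}.
#' @param panel a \linkS4class{MarkerPanel}.
#' @param model an \linkS4class{EmissionModel}.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return integer matrix of counts, genes x cells.
#' @export
#' @examples
#' panel <- defaultMarkerPanel()
#' cts <- simulateCounts(rep("neoblast:epidermis", 5), panel,
#'     defaultEmissionModel(panel), seed = 1)
#' dim(cts)
simulateCounts <- function(labels, panel, model, seed = NULL) {
    stopifnot(is(panel, "MarkerPanel"), is(model, "EmissionModel"))
    labels <- as.character(labels)
    bad <- setdiff(unique(labels), rownames(model@means))
    if (length(bad))
        stop("labels absent from the emission model: ",
            paste(bad, collapse = ", "))
    genes <- unlist(panel@pools, use.names = FALSE)
    n <- length(labels)
    ## per-gene mean for each label row
    geneMeans <- function(row) {
        mu <- setNames(numeric(length(genes)), genes)
        comps <- colnames(model@means)
        for (comp in comps) {
            val <- model@means[row, comp]
            if (val == 0) next
            g <- switch(comp,
                pan = panGene(panel),
                core_other = .coreOtherGenes(panel),
                { if (!comp %in% poolNames(panel))
                      stop("emission component '", comp,
                          "' is not a panel pool")
                  poolGenes(panel, comp) })
            mu[g] <- mu[g] + val / length(g)
        }
        mu
    }
    counts <- matrix(0L, nrow = length(genes), ncol = n,
        dimnames = list(genes, names(labels)))
    .withSeed(seed, {
        for (lab in rownames(model@means)) {
            idx <- which(labels == lab)
            if (!length(idx)) next
            mu <- geneMeans(lab)
            k <- length(idx)
            draws <- if (model@dispersion > 0)
                stats::rnbinom(length(mu) * k, size = 1 / model@dispersion,
                    mu = rep(mu, times = k))
            else
                stats::rpois(length(mu) * k, rep(mu, times = k))
            counts[, idx] <- matrix(as.integer(draws), nrow = length(mu))
        }
    })
    counts
}
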