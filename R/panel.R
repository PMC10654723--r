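#' Construct a marker panel
#'
#' @param pools named list of character vectors assigning genes to pools.
#'   Pool names follow the convention \code{"neoblast_core"},
#'   \code{"fstf:<fate>"} and \code{"mature:<tissue>"}.
#' @param panGene character(1), the designated pan-neoblast gene; must be in
#'   the \code{neoblast_core} pool. Default \code{"smedwi-1"}.
#' @return a \linkS4class{MarkerPanel}.
#' @seealso \code{\link{defaultMarkerPanel}}
#' @export
MarkerPanel <- function(pools, panGene = "smedwi-1") {
    pools <- lapply(pools, as.character)
    new("MarkerPanel", pools = pools, panGene = panGene)
}

#' Default planarian marker panel
#'
#' The neoblast core pool holds \emph{smedwi-1} plus 12 further
#' neoblast-enriched markers. One FSTF pool per fate class carries the
#' published fate-signature genes: epidermis (\emph{soxP-3}), intestine
#' (\emph{hnf-4}, \emph{gata4/5/6-1}), protonephridia (\emph{POU2/3},
#' \emph{six-1/2-2}), muscle (\emph{myoD}, \emph{snail}), CNS
#' (\emph{pax6A}), eye (\emph{ovo}) and pharynx (\emph{foxA}). Mature pools
#' carry one representative tissue marker each (epidermis \emph{PRSS12},
#' intestine \emph{mat}, muscle \emph{colF-2}, protonephridia
#' \emph{cubilin}, CNS \emph{ChAT}, pharynx \emph{VIT}).
#'
#' @return a \linkS4class{MarkerPanel}.
#' @export
#' @examples
#' defaultMarkerPanel()
defaultMarkerPanel <- function() {
    MarkerPanel(pools = list(
        neoblast_core = c("smedwi-1", "bruli", "soxP-1", "vasa-1", "mcm-7",
            "soxP-2", "rtel-1", "znf333", "nanos", "fgfr-4", "smedwi-2",
            "H2B", "fgfr-1"),
        `fstf:epidermis` = "soxP-3",
        `fstf:intestine` = c("hnf-4", "gata4/5/6-1"),
        `fstf:protonephridia` = c("POU2/3", "six-1/2-2"),
        `fstf:muscle` = c("myoD", "snail"),
        `fstf:CNS` = "pax6A",
        `fstf:eye` = "ovo",
        `fstf:pharynx` = "foxA",
        `mature:epidermis` = "PRSS12",
        `mature:intestine` = "mat",
        `mature:muscle` = "colF-2",
        `mature:protonephridia` = "cubilin",
        `mature:CNS` = "ChAT",
        `mature:pharynx` = "VIT"),
        panGene = "smedwi-1")
}

#' Read / write a marker panel as JSON
#'
#' The JSON layout is \code{{"pan_gene": "...", "pools": {"<pool>":
#' ["gene", ...]}}}.
#'
#' @param path file path.
#' @param panel a \linkS4class{MarkerPanel}.
#' @return \code{readMarkerPanel} returns a \linkS4class{MarkerPanel};
#'   \code{writeMarkerPanel} invisibly returns \code{path}.
#' @export
readMarkerPanel <- function(path) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(x$pools) || is.null(x$pan_gene))
        stop("panel JSON must contain 'pools' and 'pan_gene'")
    MarkerPanel(pools = as.list(x$pools), panGene = x$pan_gene)
}

#' @rdname readMarkerPanel
#' @export
writeMarkerPanel <- function(panel, path) {
    stopifnot(is(panel, "MarkerPanel"))
    jsonlite::write_json(
        list(pan_gene = panel@panGene, pools = panel@pools),
        path, auto_unbox = TRUE, pretty = TRUE)
    invisible(path)
}

## Genes of the neoblast core pool other than the pan-neoblast gene.
.coreOtherGenes <- function(panel) {
    setdiff(poolGenes(panel, "neoblast_core"), panGene(panel))
}

#' Default homeostatic class frequencies
#'
#' Label frequencies used by the synthetic labeling regimes, expressed over
#' neoblast fate classes plus the unassigned pool. The epidermal (0.30) and
#' muscle (0.05) proportions are the published homeostatic frequencies of
#' those specialized classes among all neoblasts; the remaining mass is
#' split across the other classes and the unassigned pool (a configuration
#' choice, since only those two frequencies are printed).
#'
#' @return named numeric vector summing to 1.
#' @export
#' @examples
#' sum(defaultClassFrequencies()) == 1
defaultClassFrequencies <- function() {
    c(`neoblast:epidermis` = 0.30,
      `neoblast:muscle` = 0.05,
      `neoblast:intestine` = 0.10,
      `neoblast:CNS` = 0.10,
      `neoblast:protonephridia` = 0.05,
      `neoblast:eye` = 0.02,
      `neoblast:pharynx` = 0.03,
      `neoblast:unassigned` = 0.35)
}

#' Default whole-tissue label frequencies
#'
#' A mixed-cell-field composition for end-to-end simulations: neoblasts (at
#' \code{neoblastFraction} of all cells, split internally by
#' \code{\link{defaultClassFrequencies}}), mature tissue cells, and an
#' \code{"other"} remainder with no panel markers beyond background.
#'
#' @param neoblastFraction fraction of cells that are neoblasts
#'   (default 0.25).
#' @return named numeric vector summing to 1.
#' @export
defaultTissueFrequencies <- function(neoblastFraction = 0.25) {
    stopifnot(neoblastFraction >= 0, neoblastFraction <= 1)
    nb <- defaultClassFrequencies() * neoblastFraction
    rest <- 1 - neoblastFraction
    mature <- c(`mature:epidermis` = 0.22, `mature:intestine` = 0.18,
        `mature:muscle` = 0.18, `mature:CNS` = 0.14,
        `mature:protonephridia` = 0.04, `mature:pharynx` = 0.04,
        other = 0.20) * rest
    .checkFreqs(c(nb, mature))
}
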