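## File formats, run configuration and the end-to-end pipeline runner.

#' Read a per-cell table (wide CSV)
#'
#' Expects a comma-separated file with a header; required columns
#' \code{cell_id}, \code{x_um}, \code{y_um}, \code{z_um}; optional
#' \code{radius_um} and \code{label} (or \code{true_label}); every
#' remaining column is parsed as a gene's transcript counts and must hold
#' non-negative integers.
#'
#' @param path CSV file path.
#' @return a \linkS4class{CellField}.
#' @export
readCellTable <- function(path) {
    df <- utils::read.csv(path, check.names = FALSE,
        stringsAsFactors = FALSE)
    need <- c("cell_id", "x_um", "y_um", "z_um")
    miss <- setdiff(need, colnames(df))
    if (length(miss))
        stop(basename(path), ": missing required column(s) ",
            paste(miss, collapse = ", "))
    dup <- duplicated(df$cell_id)
    if (any(dup))
        stop(basename(path), ": duplicate cell_id '",
            df$cell_id[dup][1L], "' (line ", which(dup)[1L] + 1L, ")")
    labCol <- intersect(c("label", "true_label"), colnames(df))[1L]
    geneCols <- setdiff(colnames(df),
        c(need, "radius_um", "label", "true_label"))
    counts <- NULL
    if (length(geneCols)) {
        for (g in geneCols) {
            v <- df[[g]]
            if (!is.numeric(v))
                stop(basename(path), ": column '", g,
                    "' is not numeric (line ",
                    which(!grepl("^\\s*-?[0-9.]+\\s*$", v))[1L] + 1L, ")")
            bad <- which(v < 0 | v != round(v))
            if (length(bad))
                stop(basename(path), ": column '", g,
                    "': count '", v[bad[1L]], "' on line ", bad[1L] + 1L,
                    " is not a non-negative integer")
        }
        counts <- t(as.matrix(df[, geneCols, drop = FALSE]))
        rownames(counts) <- geneCols
    }
    CellField(as.matrix(df[, c("x_um", "y_um", "z_um")]),
        labels = if (!is.na(labCol)) df[[labCol]] else NULL,
        radii = if ("radius_um" %in% colnames(df)) df$radius_um else NULL,
        counts = counts, ids = as.character(df$cell_id))
}

#' Write a per-cell table (wide CSV)
#'
#' Inverse of \code{\link{readCellTable}}: one row per cell with
#' coordinates, optional radius and label, and one column per gene.
#' Re-reading and re-writing a file produced by this function reproduces
#' it byte for byte.
#'
#' @param x a \linkS4class{CellField}.
#' @param path output CSV path.
#' @return invisibly, \code{path}.
#' @export
writeCellTable <- function(x, path) {
    stopifnot(is(x, "CellField"))
    pos <- cellPositions(x)
    df <- data.frame(cell_id = colnames(x), x_um = pos[, 1L],
        y_um = pos[, 2L], z_um = pos[, 3L], check.names = FALSE,
        stringsAsFactors = FALSE)
    if (!is.null(cellRadii(x))) df$radius_um <- cellRadii(x)
    if (!is.null(cellLabels(x))) df$label <- cellLabels(x)
    cts <- cellCounts(x)
    if (nrow(cts))
        df <- cbind(df, as.data.frame(t(cts), check.names = FALSE))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read / write a run configuration (YAML)
#'
#' A run configuration describes one end-to-end pipeline run: the master
#' \code{seed}, the simulated volume and cell number, class frequencies,
#' labeling regime, emission and classifier settings, and which analyses
#' to run (see \code{\link{runPipeline}}). \code{readRunConfig} applies
#' defaults and validates; configurations round-trip through
#' \code{writeRunConfig} unchanged.
#'
#' @param path YAML file path.
#' @param config a configuration list.
#' @return \code{readRunConfig}: a validated configuration list.
#' @export
readRunConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    validateRunConfig(cfg)
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
    yaml::write_yaml(config, path, precision = 17)
    invisible(path)
}

#' @rdname readRunConfig
#' @export
validateRunConfig <- function(config) {
    defaults <- list(seed = 1L, n = 1000L, extents = c(300, 300, 300),
        min_sep = 10, radius = 5, regime = "iid", regime_params = list(),
        frequencies = as.list(defaultClassFrequencies()),
        analyses = list("classify", "nn", "null"),
        query_class = "neoblast:epidermis", shuffles = 1000L)
    for (nm in names(defaults))
        if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
    ## canonical types, so configurations round-trip through YAML
    config$seed <- as.integer(config$seed)
    config$n <- as.integer(config$n)
    config$shuffles <- as.integer(config$shuffles)
    for (nm in c("extents", "min_sep", "radius"))
        config[[nm]] <- as.numeric(unlist(config[[nm]]))
    config$analyses <- as.list(as.character(unlist(config$analyses)))
    config$frequencies <- as.list(unlist(config$frequencies))
    freqs <- unlist(config$frequencies)
    .checkFreqs(freqs)
    if (!config$regime %in% c("iid", "clustered", "biased"))
        stop("unknown labeling regime: ", config$regime)
    qc <- config$query_class
    if (!is.null(qc) && !qc %in% names(freqs))
        stop("query class '", qc, "' is not a configured class")
    config
}

## Stable hash of a configuration for the manifest.
.configHash <- function(config) {
    js <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
    sprintf("%08x", deriveSeed(0, as.character(js)))
}

#' Run the full pipeline
#'
#' Simulates a labeled cell field with transcript counts, classifies the
#' cells, and runs the selected spatial analyses, writing all outputs plus
#' a run manifest to \code{outdir}. All randomness derives from the single
#' master seed via \code{\link{deriveSeed}}, so a rerun with the same
#' configuration reproduces identical outputs.
#'
#' Outputs: \code{cells.csv} (positions, radii, generator labels and
#' counts), \code{calls.csv}, \code{class_frequencies.tsv};
#' when selected, \code{nn_composition.tsv},
#' \code{voronoi_composition.tsv}, \code{null_distribution.tsv} (one
#' shuffle value per line, with the observed value and percentile in
#' header comments) and \code{distances.csv}/\code{distance_summary.tsv};
#' and \code{manifest.json}.
#'
#' @param config configuration list (see \code{\link{readRunConfig}});
#'   recognised analyses: \code{"classify"}, \code{"nn"},
#'   \code{"voronoi"}, \code{"null"}, \code{"distances"}.
#' @param outdir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(config, outdir) {
    config <- validateRunConfig(config)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list(config_hash = .configHash(config),
        version = as.character(utils::packageVersion("fateSpace")),
        stages = list(), warnings = character(0))
    outfile <- function(nm) file.path(outdir, nm)
    record <- function(stage, file, rows) {
        manifest$stages[[stage]] <<- list(file = basename(file),
            rows = rows)
    }
    freqs <- unlist(config$frequencies)
    panel <- defaultMarkerPanel()
    emission <- defaultEmissionModel(panel)
    geometry <- if (!is.null(config$geometry_file))
        readTissueGeometry(config$geometry_file) else NULL

    ## simulate
    cf <- simulateCellField(config$n,
        volume = VolumeSpec(unlist(config$extents)), freqs = freqs,
        regime = config$regime, regimeParams = config$regime_params,
        geometry = geometry, panel = panel, emission = emission,
        minSep = config$min_sep, radius = config$radius,
        seed = config$seed)
    writeCellTable(cf, outfile("cells.csv"))
    record("simulate", outfile("cells.csv"), ncol(cf))

    analyses <- unlist(config$analyses)
    labels <- cellLabels(cf)

    if ("classify" %in% analyses) {
        calls <- classifyCells(cf, panel)
        df <- data.frame(cell_id = rownames(calls),
            is_neoblast = calls$is_neoblast,
            specialized_class = calls$specialized_class,
            is_progenitor = calls$is_progenitor,
            mature_tissue = calls$mature_tissue)
        utils::write.csv(df, outfile("calls.csv"), row.names = FALSE,
            quote = FALSE)
        record("classify", outfile("calls.csv"), nrow(df))
        fr <- classFrequencies(calls)
        utils::write.table(
            data.frame(class = names(fr), fraction = as.numeric(fr)),
            outfile("class_frequencies.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
    }
    if ("nn" %in% analyses) {
        comp <- nnComposition(cellPositions(cf), labels,
            config$query_class)
        utils::write.table(
            data.frame(label = names(comp@aggregate),
                percent = as.numeric(comp@aggregate)),
            outfile("nn_composition.tsv"), sep = "\t", row.names = FALSE,
            quote = FALSE)
        record("nn", outfile("nn_composition.tsv"),
            length(comp@aggregate))
    }
    if ("voronoi" %in% analyses) {
        g <- voronoiNeighbors(cellPositions(cf),
            volume = spatialVolume(cf))
        comp <- neighborhoodComposition(g, labels, config$query_class)
        h <- comp@histogram
        utils::write.table(cbind(bin = rownames(h),
            as.data.frame(h, check.names = FALSE)),
            outfile("voronoi_composition.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
        record("voronoi", outfile("voronoi_composition.tsv"), nrow(h))
    }
    if ("null" %in% analyses) {
        nd <- shuffleNull(cellPositions(cf), labels, config$query_class,
            nShuffles = config$shuffles,
            seed = deriveSeed(config$seed, "null"))
        con <- file(outfile("null_distribution.tsv"), "w")
        writeLines(c(
            sprintf("# statistic: %s", nd@statistic),
            sprintf("# query_class: %s", nd@queryClass),
            sprintf("# observed: %.10g", nd@observed),
            sprintf("# percentile: %.10g", nd@percentile),
            "self_percent"), con)
        writeLines(sprintf("%.10g", nd@shuffles), con)
        close(con)
        record("null", outfile("null_distribution.tsv"),
            length(nd@shuffles))
    }
    if ("distances" %in% analyses) {
        ## distances from specialized classes to mature-cell point sets
        tissues <- unique(sub("^mature:", "",
            grep("^mature:", labels, value = TRUE)))
        mature <- lapply(tissues, function(tn)
            cellPositions(cf)[labels == paste0("mature:", tn), ,
                drop = FALSE])
        names(mature) <- tissues
        qsel <- startsWith(labels, "neoblast:")
        if (length(mature) && any(qsel)) {
            dt <- distanceToTissueCells(
                cellPositions(cf)[qsel, , drop = FALSE], mature)
            utils::write.csv(dt@distances, outfile("distances.csv"),
                row.names = FALSE, quote = FALSE)
            groups <- rep(labels[qsel], times = length(mature))
            utils::write.table(summarizeDistances(dt, groups),
                outfile("distance_summary.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
            record("distances", outfile("distances.csv"),
                nrow(dt@distances))
        } else {
            manifest$warnings <- c(manifest$warnings,
                "distances requested but no mature cells or no neoblasts")
        }
    }
    jsonlite::write_json(manifest, outfile("manifest.json"),
        auto_unbox = TRUE, pretty = TRUE)
    invisible(manifest)
}
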