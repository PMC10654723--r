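## Independent oracles and small fixture builders used across tests.

## Brute-force nearest neighbors: explicit double loop over all pairs,
## ties broken by the smallest index.
bruteNN <- function(pos, radii = NULL) {
    n <- nrow(pos)
    idx <- integer(n)
    dst <- numeric(n)
    for (i in seq_len(n)) {
        best <- Inf
        bestj <- NA_integer_
        for (j in seq_len(n)) {
            if (j == i) next
            d <- sqrt(sum((pos[i, ] - pos[j, ])^2))
            if (!is.null(radii)) d <- max(0, d - radii[i] - radii[j])
            if (d < best) {
                best <- d
                bestj <- j
            }
        }
        idx[i] <- bestj
        dst[i] <- best
    }
    list(index = idx, dist = dst)
}

## Delaunay adjacency oracle via scipy (independent of the package's
## bisector-clipping implementation). Takes a list of point matrices and
## returns a list of two-column (i < j, 1-based) edge matrices.
scipyDelaunay <- function(fields) {
    dir <- withr::local_tempdir(.local_envir = parent.frame())
    infile <- file.path(dir, "fields.csv")
    outfile <- file.path(dir, "edges.txt")
    df <- do.call(rbind, lapply(seq_along(fields), function(f)
        data.frame(field = f, x = fields[[f]][, 1L],
            y = fields[[f]][, 2L], z = fields[[f]][, 3L])))
    utils::write.csv(df, infile, row.names = FALSE)
    script <- paste(
        "import sys, numpy as np",
        "from scipy.spatial import Delaunay",
        "d = np.loadtxt(sys.argv[1], delimiter=',', skiprows=1)",
        "lines = []",
        "for f in np.unique(d[:, 0]):",
        "    pts = d[d[:, 0] == f][:, 1:4]",
        "    tri = Delaunay(pts)",
        "    pairs = set()",
        "    for s in tri.simplices:",
        "        for a in range(4):",
        "            for b in range(a + 1, 4):",
        "                i, j = sorted((s[a], s[b]))",
        "                pairs.add((i + 1, j + 1))",
        "    for i, j in sorted(pairs):",
        "        lines.append('%d %d %d' % (f, i, j))",
        "open(sys.argv[2], 'w').write('\\n'.join(lines))",
        sep = "\n")
    scriptfile <- file.path(dir, "delaunay.py")
    writeLines(script, scriptfile)
    status <- system2("python", c(scriptfile, infile, outfile))
    stopifnot(status == 0L)
    ed <- utils::read.table(outfile, col.names = c("field", "i", "j"))
    lapply(seq_along(fields), function(f) {
        m <- as.matrix(ed[ed$field == f, c("i", "j")])
        dimnames(m) <- NULL
        m
    })
}

## Neighbor index set of cell i in a NeighborGraph / edge matrix.
edgeNeighbors <- function(edges, i) {
    sort(unique(c(edges[edges[, 1L] == i, 2L],
                  edges[edges[, 2L] == i, 1L])))
}

## Brute-force pharynx routing oracle: enumerate every route
## query -> (ordered subset of cavity corners) -> esophagus whose segments
## all avoid the open cavity interior, and take the shortest.
routeOracle <- function(q, cav) {
    corners <- rbind(c(cav$xmin, cav$ymax), c(cav$xmax, cav$ymax),
                     c(cav$xmin, cav$ymin), c(cav$xmax, cav$ymin))
    e <- cav$entry
    crosses <- function(p1, p2) {
        ## exact slab-interval test for the open rectangle interior
        d <- p2 - p1
        lohi <- function(p, d, a, b) {
            if (d == 0) {
                if (p <= a || p >= b) c(Inf, -Inf) else c(-Inf, Inf)
            } else sort(c((a - p) / d, (b - p) / d))
        }
        ix <- lohi(p1[1L], d[1L], cav$xmin, cav$xmax)
        iy <- lohi(p1[2L], d[2L], cav$ymin, cav$ymax)
        t0 <- max(ix[1L], iy[1L], 0)
        t1 <- min(ix[2L], iy[2L], 1)
        if (t1 - t0 <= 1e-12) return(FALSE)
        mid <- p1 + ((t0 + t1) / 2) * d
        mid[1L] > cav$xmin + 1e-12 && mid[1L] < cav$xmax - 1e-12 &&
            mid[2L] > cav$ymin + 1e-12 && mid[2L] < cav$ymax - 1e-12
    }
    seglen <- function(p1, p2) sqrt(sum((p1 - p2)^2))
    best <- Inf
    subsets <- unlist(lapply(0:4, function(k)
        combn(4, k, simplify = FALSE)), recursive = FALSE)
    for (s in subsets) {
        perms <- if (length(s) <= 1) list(s) else {
            pp <- list()
            for (ord in asplit(permutations(length(s)), 1L))
                pp[[length(pp) + 1L]] <- s[ord]
            pp
        }
        for (route in perms) {
            pts <- rbind(q, corners[route, , drop = FALSE], e)
            ok <- TRUE
            len <- 0
            for (k in seq_len(nrow(pts) - 1L)) {
                if (crosses(pts[k, ], pts[k + 1L, ])) { ok <- FALSE; break }
                len <- len + seglen(pts[k, ], pts[k + 1L, ])
            }
            if (ok && len < best) best <- len
        }
    }
    best
}

## All permutations of 1..n as an (n!) x n matrix (tiny n only).
permutations <- function(n) {
    if (n == 1L) return(matrix(1L))
    sub <- permutations(n - 1L)
    out <- NULL
    for (i in seq_len(n)) {
        rest <- setdiff(seq_len(n), i)
        out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
    }
    unname(out)
}

## Counts matrix for hand-built classifier cases: named totals are spread
## over pool genes (first gene gets the remainder).
makeCounts <- function(panel, cells) {
    genes <- unlist(lapply(poolNames(panel), poolGenes, x = panel))
    m <- matrix(0L, nrow = length(genes), ncol = length(cells),
        dimnames = list(genes, names(cells)))
    for (ci in seq_along(cells)) {
        spec <- cells[[ci]]
        for (nm in names(spec)) {
            if (nm == "pan") {
                m[panGene(panel), ci] <- spec[[nm]]
            } else if (nm == "core_other") {
                g <- setdiff(poolGenes(panel, "neoblast_core"),
                    panGene(panel))
                m[g[1L], ci] <- spec[[nm]]
            } else {
                g <- poolGenes(panel, nm)
                m[g[1L], ci] <- spec[[nm]]
            }
        }
    }
    m
}
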