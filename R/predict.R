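#' Predict library-type composition for query profiles
#'
#' The end-to-end query path: each profile is flattened to its percentage
#' features (uncovered positions imputed from the model's training mean),
#' projected onto the reference map, assigned to a tile, and annotated with
#' that tile's library-type percentages. A query landing in an empty tile
#' or outside the grid is redirected to the nearest occupied tile and
#' flagged (\code{fallback_used}) so the report can be read with
#' appropriate caution.
#'
#' The percentages describe how the query's map tile is populated by
#' reference library types — a similarity readout for quality control, not
#' a calibrated classifier posterior. A strong mismatch with the expected
#' library type is a signal to investigate, not an automatic verdict.
#'
#' Profiles whose position count does not match the model raise a warning
#' naming the profile and are dropped; the remaining reports keep input
#' order (batches are processed independently per sample, so
#' \code{predict(c(A, B))} equals \code{predict(A)} followed by
#' \code{predict(B)}).
#'
#' @param profiles a [CompositionProfile-class] or list of them.
#' @param model a [ReferenceMap-class].
#' @param grid a [TileGrid-class] built from the same reference map.
#' @return a [S4Vectors::DataFrame] with one row per query: sample_id, x,
#'   y, tile_x, tile_y, fallback_used, then one percentage column per
#'   library type; metadata records the model parameters.
#' @export
predictLibraryType <- function(profiles, model, grid) {
    if (methods::is(profiles, "CompositionProfile"))
        profiles <- list(profiles)
    stopifnot(length(profiles) >= 1L)
    d <- length(model@featureMeans)
    ok <- vapply(profiles, function(p) {
        good <- nrow(counts(p)) * 4L == d
        if (!good)
            warning("profile ", sampleId(p), " covers ", nrow(counts(p)),
                    " positions but the model expects ", d / 4L,
                    "; profile skipped")
        good
    }, logical(1))
    profiles <- profiles[ok]
    if (length(profiles) == 0L)
        stop("no profile matches the model's position count")
    feat <- t(vapply(profiles,
                     function(p) profileFeatures(p, fill = model@featureMeans),
                     numeric(d)))
    rownames(feat) <- unname(vapply(profiles, sampleId, character(1)))
    coords <- projectSamples(model, feat)
    tl <- tileOf(grid, coords)
    types <- grid@typeNames
    pct <- matrix(NA_real_, nrow(coords), length(types),
                  dimnames = list(NULL, types))
    fallback <- logical(nrow(coords))
    for (q in seq_len(nrow(coords))) {
        ix <- tl$tile_x[q]; iy <- tl$tile_y[q]
        empty <- !is.na(ix) && sum(grid@counts[ix, iy, ]) == 0L
        if (is.na(ix) || empty) {
            near <- nearestOccupiedTile(grid, coords[q, ])
            ix <- near[1]; iy <- near[2]
            fallback[q] <- TRUE
        }
        tl$tile_x[q] <- ix; tl$tile_y[q] <- iy
        pct[q, ] <- grid@percent[ix, iy, ]
    }
    out <- S4Vectors::DataFrame(
        sample_id = rownames(coords),
        x = unname(coords[, 1]), y = unname(coords[, 2]),
        tile_x = tl$tile_x, tile_y = tl$tile_y,
        fallback_used = fallback,
        pct, check.names = FALSE)
    S4Vectors::metadata(out) <- list(
        model_version = model@version,
        umap = model@params,
        seeds = vapply(profiles, function(p) p@seed, integer(1)))
    out
}

#' Top library type per query
#'
#' Convenience accessor: the library type with the highest tile percentage
#' for each row of a prediction report (ties broken alphabetically).
#'
#' @param report the [S4Vectors::DataFrame] from [predictLibraryType()].
#' @param grid the [TileGrid-class] the report was made with.
#' @return character vector of type labels.
#' @export
topType <- function(report, grid) {
    pm <- as.matrix(report[, grid@typeNames, drop = FALSE])
    grid@typeNames[apply(pm, 1, which.max)]
}

#' Render prediction reports to figures and a table
#'
#' Writes, for a batch of queries: (1) the reference-map scatter with the
#' query positions overplotted, (2) the per-type tile probability maps
#' with query positions, (3) a query x library-type percentage heatmap,
#' each as SVG and PNG, plus the machine-readable TSV report
#' (\code{report.tsv}: sample_id, x, y, tile_x, tile_y, fallback_used,
#' one column per type).
#'
#' @param report the DataFrame from [predictLibraryType()].
#' @param model the [ReferenceMap-class].
#' @param grid the [TileGrid-class].
#' @param outDir output directory (created if needed).
#' @param formats image formats to write, subset of c("svg", "png").
#' @param width,height device size in inches.
#' @return invisibly, the paths written.
#' @export
renderReport <- function(report, model, grid, outDir,
                         formats = c("svg", "png"),
                         width = 9, height = 7) {
    if (nrow(report) == 0L)
        stop("nothing to render: the report has no queries")
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    if (file.access(outDir, mode = 2) != 0L)
        stop("output directory not writable: ", outDir)
    types <- grid@typeNames
    qdf <- as.data.frame(report[, c("sample_id", "x", "y")])

    refdf <- data.frame(x = model@coords[, 1], y = model@coords[, 2],
                        library_type = model@labels)
    pMap <- ggplot2::ggplot(refdf, ggplot2::aes(x = .data$x, y = .data$y)) +
        ggplot2::geom_point(ggplot2::aes(colour = .data$library_type),
                            size = 0.8, alpha = 0.7) +
        ggplot2::geom_point(data = qdf, shape = 4, size = 3,
                            stroke = 1.2, colour = "black") +
        ggplot2::geom_text(data = qdf,
                           ggplot2::aes(label = .data$sample_id),
                           vjust = -1, size = 3) +
        ggplot2::labs(title = "Reference map with query libraries",
                      colour = "library type") +
        ggplot2::theme_minimal()

    ctr <- tileCenters(grid)
    tiles <- expand.grid(ix = seq_len(grid@nx), iy = seq_len(grid@ny))
    tldf <- do.call(rbind, lapply(types, function(ty) {
        data.frame(tiles,
                   x = ctr$x[tiles$ix], y = ctr$y[tiles$iy],
                   percent = grid@percent[cbind(tiles$ix, tiles$iy,
                                                match(ty, types))],
                   library_type = ty)
    }))
    pTiles <- ggplot2::ggplot(tldf,
            ggplot2::aes(x = .data$x, y = .data$y,
                         fill = .data$percent)) +
        ggplot2::geom_tile() +
        ggplot2::geom_point(data = qdf, shape = 4, size = 2,
                            stroke = 1, colour = "red",
                            inherit.aes = FALSE,
                            ggplot2::aes(x = .data$x, y = .data$y)) +
        ggplot2::facet_wrap(~library_type) +
        ggplot2::scale_fill_gradient(low = "white", high = "darkblue") +
        ggplot2::labs(title = "Per-type tile probability maps",
                      fill = "% of tile") +
        ggplot2::theme_minimal()

    hm <- do.call(rbind, lapply(seq_len(nrow(report)), function(q)
        data.frame(sample_id = report$sample_id[q],
                   library_type = types,
                   percent = as.numeric(as.matrix(
                       report[q, types, drop = FALSE])))))
    pHeat <- ggplot2::ggplot(hm,
            ggplot2::aes(x = .data$library_type, y = .data$sample_id,
                         fill = .data$percent)) +
        ggplot2::geom_tile() +
        ggplot2::geom_text(ggplot2::aes(
            label = sprintf("%.1f", .data$percent)), size = 3) +
        ggplot2::scale_fill_gradient(low = "white", high = "darkred",
                                     limits = c(0, 100)) +
        ggplot2::labs(title = "Library-type percentages in query tiles",
                      x = "library type", y = "query") +
        ggplot2::theme_minimal() +
        ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                           hjust = 1))

    paths <- character()
    writeDev <- function(plot, stem) {
        for (fmt in formats) {
            f <- file.path(outDir, paste0(stem, ".", fmt))
            if (fmt == "svg")
                grDevices::svg(f, width = width, height = height)
            else
                grDevices::png(f, width = width, height = height,
                               units = "in", res = 150)
            print(plot)
            grDevices::dev.off()
            paths <<- c(paths, f)
        }
    }
    writeDev(pMap, "reference_map")
    writeDev(pTiles, "tile_probability_maps")
    writeDev(pHeat, "query_heatmap")

    tsv <- file.path(outDir, "report.tsv")
    df <- as.data.frame(report)
    colnames(df) <- colnames(report)
    num <- vapply(df, is.numeric, logical(1)) &
        !colnames(df) %in% c("tile_x", "tile_y")
    df[num] <- lapply(df[num], function(v) sprintf("%.6f", v))
    utils::write.table(df, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(c(paths, tsv))
}

#' @importFrom ggplot2 .data
NULL
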