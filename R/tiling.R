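#' Partition the reference map into a tile grid
#'
#' Builds an \code{nx} x \code{ny} rectangular grid over the bounding box
#' of the reference coordinates, padded by \code{pad} (fraction of each
#' axis range, per side) so reference points never sit exactly on the
#' outer frame. For every tile the per-type sample counts and the
#' imbalance-normalised type percentages are computed (see
#' [TileGrid-class] for the formula); with the normalisation, duplicating
#' every sample of one type leaves the percentages unchanged, so types of
#' very different database sizes remain comparable.
#'
#' @param coords numeric S x 2 matrix of reference coordinates.
#' @param labels character(S) library-type labels.
#' @param nx,ny tiles per axis (default 24 x 24).
#' @param pad bounding-box padding per side as a fraction of the axis
#'   range (default 0.02).
#' @return a [TileGrid-class].
#' @export
buildGrid <- function(coords, labels, nx = 24L, ny = 24L, pad = 0.02) {
    stopifnot(nrow(coords) >= 1L, nx >= 1L, ny >= 1L,
              length(labels) == nrow(coords))
    rx <- range(coords[, 1]); ry <- range(coords[, 2])
    if (diff(rx) == 0 || diff(ry) == 0)
        stop("degenerate bounding box: all coordinates identical along ",
             if (diff(rx) == 0) "x" else "y")
    px <- diff(rx) * pad; py <- diff(ry) * pad
    xe <- seq(rx[1] - px, rx[2] + px, length.out = as.integer(nx) + 1L)
    ye <- seq(ry[1] - py, ry[2] + py, length.out = as.integer(ny) + 1L)
    types <- sort(unique(as.character(labels)))
    cnt <- array(0L, dim = c(nx, ny, length(types)),
                 dimnames = list(NULL, NULL, types))
    ix <- binIndex(coords[, 1], xe)
    iy <- binIndex(coords[, 2], ye)
    for (s in seq_len(nrow(coords))) {
        t <- match(labels[s], types)
        cnt[ix[s], iy[s], t] <- cnt[ix[s], iy[s], t] + 1L
    }
    totals <- as.numeric(table(factor(labels, levels = types)))
    names(totals) <- types
    pct <- normalizeTilePercent(cnt, totals)
    methods::new("TileGrid",
        xEdges = xe, yEdges = ye,
        nx = as.integer(nx), ny = as.integer(ny),
        counts = cnt, percent = pct,
        typeTotals = totals, typeNames = types)
}

# tile_percent[i,j,t] = 100 * (c_t/N_t) / sum_u (c_u/N_u); empty tiles 0
normalizeTilePercent <- function(cnt, totals) {
    w <- sweep(cnt, 3, totals, `/`)
    denom <- apply(w, c(1, 2), sum)
    pct <- 100 * sweep(w, c(1, 2), denom, `/`)
    pct[!is.finite(pct)] <- 0
    pct
}

# half-open bins [e_i, e_{i+1}) with the last edge closed; 0 = out of box
binIndex <- function(v, edges) {
    i <- findInterval(v, edges, rightmost.closed = TRUE)
    i[i == length(edges)] <- 0L         # beyond the top edge
    i
}

#' Locate the tile of a coordinate
#'
#' Deterministic binning of map coordinates into the grid. A point on an
#' interior edge belongs to the tile on its upper/right side (half-open
#' convention); a point exactly on the top/right boundary belongs to the
#' last tile. Coordinates outside the padded bounding box yield \code{NA}
#' (out of bounds).
#'
#' @param grid a [TileGrid-class].
#' @param coord numeric length-2 vector, or a Q x 2 matrix.
#' @return a data.frame with integer columns \code{tile_x}, \code{tile_y}
#'   (\code{NA} when out of bounds), one row per query.
#' @export
tileOf <- function(grid, coord) {
    if (is.null(dim(coord))) coord <- matrix(coord, ncol = 2)
    ix <- binIndex(coord[, 1], grid@xEdges)
    iy <- binIndex(coord[, 2], grid@yEdges)
    oob <- ix == 0L | iy == 0L
    ix[oob] <- NA_integer_; iy[oob] <- NA_integer_
    data.frame(tile_x = ix, tile_y = iy)
}

tileCenters <- function(grid) {
    cx <- (grid@xEdges[-1] + grid@xEdges[-length(grid@xEdges)]) / 2
    cy <- (grid@yEdges[-1] + grid@yEdges[-length(grid@yEdges)]) / 2
    list(x = cx, y = cy)
}

#' Nearest occupied tile
#'
#' Returns the occupied tile (at least one reference sample) whose centre
#' is closest, in Euclidean distance, to the given map coordinate or tile
#' centre — the fallback used when a query lands in an empty tile or
#' outside the grid. Ties are broken by row-major tile order (x varying
#' slowest).
#'
#' @param grid a [TileGrid-class].
#' @param coord numeric length-2 map coordinate, or integer length-2 tile
#'   index \code{c(tile_x, tile_y)} when \code{isTile = TRUE}.
#' @param isTile interpret \code{coord} as a tile index.
#' @return integer c(tile_x, tile_y) of the nearest occupied tile.
#' @export
nearestOccupiedTile <- function(grid, coord, isTile = FALSE) {
    occ <- which(apply(grid@counts, c(1, 2), sum) > 0, arr.ind = TRUE)
    if (nrow(occ) == 0L)
        stop("grid has no occupied tiles")
    ctr <- tileCenters(grid)
    if (isTile) coord <- c(ctr$x[coord[1]], ctr$y[coord[2]])
    d2 <- (ctr$x[occ[, 1]] - coord[1])^2 + (ctr$y[occ[, 2]] - coord[2])^2
    rowMajor <- (occ[, 1] - 1L) * grid@ny + occ[, 2]
    best <- order(d2, rowMajor)[1L]
    c(tile_x = occ[best, 1], tile_y = occ[best, 2])
}

#' Per-type tile-percentage self-consistency matrix
#'
#' Annotates every reference sample with its own tile and averages the
#' tile's type-percentage vectors across all samples of each library type.
#' Row \eqn{t} therefore answers: "when I look up a typical type-\eqn{t}
#' sample on the map, what mix of types does its tile report?" — a
#' self-consistency summary of how distinguishable the types are, not a
#' held-out classifier evaluation. Rows sum to 100.
#'
#' @param grid a [TileGrid-class] built from these same coordinates.
#' @param coords,labels the reference coordinates and labels.
#' @return numeric T x T matrix, rows and columns named by type.
#' @export
tileConfusionMatrix <- function(grid, coords, labels) {
    types <- grid@typeNames
    tl <- tileOf(grid, coords)
    if (anyNA(tl$tile_x))
        stop("some samples fall outside the grid; build the grid from ",
             "the same coordinates")
    pvec <- t(vapply(seq_len(nrow(coords)), function(s)
        grid@percent[tl$tile_x[s], tl$tile_y[s], ], numeric(length(types))))
    present <- types[types %in% unique(labels)]
    if (length(present) < length(types))
        warning("no samples for type(s): ",
                paste(setdiff(types, present), collapse = ", "),
                "; excluded from the matrix rows")
    cm <- t(vapply(present, function(ty)
        colMeans(pvec[labels == ty, , drop = FALSE]),
        numeric(length(types))))
    dimnames(cm) <- list(present, types)
    cm
}

setMethod("show", "TileGrid", function(object) {
    occ <- sum(apply(object@counts, c(1, 2), sum) > 0)
    cat("TileGrid:", object@nx, "x", object@ny, "tiles (",
        occ, "occupied ),", sum(object@counts), "samples,",
        length(object@typeNames), "types\n",
        " x: [", min(object@xEdges), ",", max(object@xEdges), "]",
        " y: [", min(object@yEdges), ",", max(object@yEdges), "]\n")
})

#' Export / import a tile grid
#'
#' Long-format TSV (\code{tile_x}, \code{tile_y}, \code{type},
#' \code{count}, \code{percent}; only tiles with at least one sample are
#' listed) plus a JSON sidecar with the grid geometry and per-type totals.
#'
#' @param grid a [TileGrid-class].
#' @param path TSV path; the sidecar is \code{<path>.json}.
#' @return \code{saveGrid}: \code{path} invisibly; \code{loadGrid}: a
#'   [TileGrid-class].
#' @export
saveGrid <- function(grid, path) {
    idx <- which(grid@counts > 0, arr.ind = TRUE)
    df <- data.frame(tile_x = idx[, 1], tile_y = idx[, 2],
                     type = grid@typeNames[idx[, 3]],
                     count = grid@counts[idx],
                     percent = sprintf("%.17g", grid@percent[idx]))
    df <- df[order(df$tile_x, df$tile_y, df$type), ]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    jsonlite::write_json(
        list(x_edges = grid@xEdges, y_edges = grid@yEdges,
             nx = grid@nx, ny = grid@ny,
             type_totals = as.list(grid@typeTotals)),
        paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname saveGrid
#' @export
loadGrid <- function(path) {
    side <- jsonlite::read_json(paste0(path, ".json"),
                                simplifyVector = TRUE)
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            colClasses = c("integer", "integer",
                                           "character", "integer",
                                           "character"))
    types <- sort(names(side$type_totals))
    totals <- unlist(side$type_totals)[types]
    cnt <- array(0L, dim = c(side$nx, side$ny, length(types)),
                 dimnames = list(NULL, NULL, types))
    cnt[cbind(df$tile_x, df$tile_y, match(df$type, types))] <- df$count
    methods::new("TileGrid",
        xEdges = side$x_edges, yEdges = side$y_edges,
        nx = as.integer(side$nx), ny = as.integer(side$ny),
        counts = cnt,
        percent = normalizeTilePercent(cnt, totals),
        typeTotals = totals, typeNames = types)
}
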