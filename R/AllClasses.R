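#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

BASES  <- c("A", "C", "G", "T")
BASESN <- c("A", "C", "G", "T", "N")

#' CompositionProfile: per-position base content of one sequencing library
#'
#' Holds the A/C/G/T/N counts at each of the leading read positions
#' (default 50) tabulated from a subsample of reads of a single library,
#' together with bookkeeping: how many reads were sampled, how many records
#' the file contained, and the sampling seed. Positions are reported 1-based.
#'
#' The count in row \code{p}, column \code{b} is the number of sampled reads
#' whose base at position \code{p} is \code{b}; reads shorter than \code{p}
#' contribute nothing at \code{p}, so column sums per position are at most
#' \code{readsSampled}.
#'
#' @slot sampleId character(1) identifier of the library.
#' @slot counts integer L x 5 matrix with columns A, C, G, T, N.
#' @slot readsSampled integer(1), number of reads tabulated.
#' @slot readsTotal integer(1), number of records seen in the source file.
#' @slot seed integer(1), seed used for read subsampling.
#'
#' @seealso [tabulateComposition()], [toPercentages()], [writeProfile()]
#' @exportClass CompositionProfile
setClass("CompositionProfile",
    slots = c(
        sampleId     = "character",
        counts       = "matrix",
        readsSampled = "integer",
        readsTotal   = "integer",
        seed         = "integer"
    )
)

setValidity("CompositionProfile", function(object) {
    msg <- character()
    if (length(object@sampleId) != 1L || is.na(object@sampleId))
        msg <- c(msg, "sampleId must be a single non-NA string")
    cnt <- object@counts
    if (!is.numeric(cnt) || ncol(cnt) != 5L ||
        !identical(colnames(cnt), BASESN))
        msg <- c(msg, "counts must be an L x 5 matrix with columns A,C,G,T,N")
    else {
        if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
        if (any(cnt != round(cnt))) msg <- c(msg, "counts must be integers")
        if (length(object@readsSampled) == 1L &&
            any(rowSums(cnt) > object@readsSampled))
            msg <- c(msg, "per-position counts cannot exceed readsSampled")
    }
    if (length(object@readsSampled) != 1L || object@readsSampled < 0)
        msg <- c(msg, "readsSampled must be a single non-negative integer")
    if (length(object@readsTotal) != 1L || object@readsTotal < 0)
        msg <- c(msg, "readsTotal must be a single non-negative integer")
    if (length(object@readsTotal) == 1L && length(object@readsSampled) == 1L &&
        object@readsSampled > object@readsTotal)
        msg <- c(msg, "readsSampled cannot exceed readsTotal")
    if (length(msg)) msg else TRUE
})

#' ReferenceDatabase: labelled composition profiles for the reference map
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose single assay,
#' \code{"percent"}, is the (4 x L) x S matrix of per-position base
#' percentages: for each sample (column), the 50 positions each contribute a
#' block of four values (A, C, G, T, in that order) summing to 100, with N
#' calls excluded from the denominator. \code{colData} carries
#' \code{library_type}, \code{species}, \code{reads_sampled} and
#' \code{reads_total}; \code{metadata} carries the number of positions and,
#' after [filterDatabase()], the filter log.
#'
#' @seealso [ReferenceDatabase()], [filterDatabase()], [featureMatrix()],
#'   [saveDatabase()]
#' @exportClass ReferenceDatabase
setClass("ReferenceDatabase", contains = "SummarizedExperiment")

setValidity("ReferenceDatabase", function(object) {
    msg <- character()
    if (!"percent" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'percent' is required")
    else {
        a <- SummarizedExperiment::assay(object, "percent")
        if (nrow(a) %% 4L != 0L)
            msg <- c(msg, "assay rows must be 4 per position (A,C,G,T)")
        else if (nrow(a) > 0L && ncol(a) > 0L) {
            L <- nrow(a) / 4L
            blk <- rowsum(a, rep(seq_len(L), each = 4L))
            if (max(abs(blk - 100)) > 1e-6)
                msg <- c(msg, "each per-position A/C/G/T block must sum to 100")
        }
    }
    cd <- SummarizedExperiment::colData(object)
    if (!all(c("library_type", "reads_sampled") %in% colnames(cd)))
        msg <- c(msg, "colData must contain library_type and reads_sampled")
    else if (nrow(cd) > 0L && any(is.na(cd$library_type) |
                                  cd$library_type == ""))
        msg <- c(msg, "library_type must be non-empty for every sample")
    if (length(msg)) msg else TRUE
})

#' ReferenceMap: fitted 2-D embedding of the reference database
#'
#' Wraps a fitted UMAP model: the embedding parameters, the 2-D coordinates
#' of every reference sample (1:1 with database columns), their library-type
#' labels, the training-set mean feature vector (used to impute positions a
#' query profile does not cover), and the transform state needed for
#' out-of-sample projection. Persist with [saveModel()] / [loadModel()];
#' the in-memory \code{uwot} state is not serialisable with \code{saveRDS}.
#'
#' @slot params list with n_neighbors, min_dist, spread, metric, seed.
#' @slot coords numeric S x 2 matrix of reference coordinates.
#' @slot labels character(S) library-type labels.
#' @slot featureMeans numeric(4L) column means of the training features.
#' @slot uwot fitted uwot model (opaque).
#' @slot version character(1) serialisation format version.
#'
#' @seealso [fitReferenceMap()], [projectSamples()]
#' @exportClass ReferenceMap
setClass("ReferenceMap",
    slots = c(
        params       = "list",
        coords       = "matrix",
        labels       = "character",
        featureMeans = "numeric",
        uwot         = "ANY",
        version      = "character"
    )
)

setValidity("ReferenceMap", function(object) {
    msg <- character()
    if (ncol(object@coords) != 2L)
        msg <- c(msg, "coords must have 2 columns")
    if (any(!is.finite(object@coords)))
        msg <- c(msg, "coords must be finite")
    if (length(object@labels) != nrow(object@coords))
        msg <- c(msg, "labels must match coords rows 1:1")
    need <- c("n_neighbors", "min_dist", "spread", "metric", "seed")
    if (!all(need %in% names(object@params)))
        msg <- c(msg, paste("params must contain",
                            paste(need, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' TileGrid: rectangular partition of the reference map
#'
#' Divides the (padded) bounding box of the reference coordinates into
#' \code{nx} x \code{ny} tiles and stores, per tile, the count of reference
#' samples of each library type and the imbalance-normalised type
#' percentages: with \eqn{N_t} samples of type \eqn{t} in the database and
#' \eqn{c_{\tau t}} of them in tile \eqn{\tau},
#' \deqn{P_{\tau t} = 100 \cdot \frac{c_{\tau t}/N_t}{\sum_u c_{\tau u}/N_u}.}
#' Dividing by \eqn{N_t} first makes the percentages invariant to how many
#' samples of each type the database happens to hold (e.g. the 500-sample
#' cap). Binning is half-open \code{[edge_i, edge_{i+1})} with the top/right
#' edge closed, so every in-box point maps to exactly one tile.
#'
#' @slot xEdges,yEdges numeric tile edges (length nx+1 / ny+1).
#' @slot nx,ny integer tiles per axis.
#' @slot counts integer array nx x ny x T of per-tile type counts.
#' @slot percent numeric array nx x ny x T of normalised percentages
#'   (all-zero for empty tiles).
#' @slot typeTotals named numeric(T), samples per type in the database.
#' @slot typeNames character(T).
#'
#' @seealso [buildGrid()], [tileOf()], [tileConfusionMatrix()]
#' @exportClass TileGrid
setClass("TileGrid",
    slots = c(
        xEdges     = "numeric",
        yEdges     = "numeric",
        nx         = "integer",
        ny         = "integer",
        counts     = "array",
        percent    = "array",
        typeTotals = "numeric",
        typeNames  = "character"
    )
)

setValidity("TileGrid", function(object) {
    msg <- character()
    if (length(object@xEdges) != object@nx + 1L ||
        length(object@yEdges) != object@ny + 1L)
        msg <- c(msg, "edge vectors must have nx+1 / ny+1 entries")
    if (is.unsorted(object@xEdges, strictly = TRUE) ||
        is.unsorted(object@yEdges, strictly = TRUE))
        msg <- c(msg, "edges must be strictly increasing")
    dm <- dim(object@counts)
    if (length(dm) != 3L || !all(dm == c(object@nx, object@ny,
                                         length(object@typeNames))))
        msg <- c(msg, "counts must be an nx x ny x T array")
    if (!identical(dim(object@percent), dim(object@counts)))
        msg <- c(msg, "percent must have the same shape as counts")
    occ <- apply(object@counts, c(1, 2), sum) > 0
    psum <- apply(object@percent, c(1, 2), sum)
    if (any(abs(psum[occ] - 100) > 1e-9))
        msg <- c(msg, "occupied-tile percentages must sum to 100")
    if (any(psum[!occ] != 0))
        msg <- c(msg, "empty tiles must have all-zero percentages")
    if (length(msg)) msg else TRUE
})
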