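MODEL_FORMAT_VERSION <- "1"

#' @describeIn fitReferenceMap fit from a feature matrix plus labels.
#'
#' @param labels library-type labels, one per feature row (matrix method
#'   only; the database method takes them from \code{colData}).
#' @param nNeighbors UMAP \code{n_neighbors} (default 15).
#' @param minDist UMAP \code{min_dist} (default 8). Controls how tightly
#'   points pack in the embedding; must not exceed \code{spread}.
#' @param spread UMAP \code{spread} (default 10, the smallest round value
#'   compatible with the default \code{minDist}).
#' @param metric distance metric on the percentage features (default
#'   Euclidean).
#' @param seed embedding seed (default 42); fits and projections are
#'   deterministic for a fixed seed (single-threaded optimisation).
#' @exportMethod fitReferenceMap
setMethod("fitReferenceMap", "matrix",
    function(x, labels, nNeighbors = 15L, minDist = 8, spread = 10,
             metric = "euclidean", seed = 42L) {
    S <- nrow(x)
    if (S <= nNeighbors)
        stop("cannot fit a map from ", S, " samples with n_neighbors = ",
             nNeighbors, "; lower nNeighbors or enlarge the database")
    if (minDist > spread)
        stop("minDist (", minDist, ") must not exceed spread (", spread, ")")
    stopifnot(length(labels) == S)
    set.seed(as.integer(seed))
    fit <- uwot::umap(x,
                      n_neighbors = as.integer(nNeighbors),
                      min_dist = minDist, spread = spread,
                      metric = metric,
                      n_threads = 1, n_sgd_threads = 0,
                      ret_model = TRUE)
    coords <- matrix(as.numeric(fit$embedding), ncol = 2,
                     dimnames = list(rownames(x), c("x", "y")))
    methods::new("ReferenceMap",
        params = list(n_neighbors = as.integer(nNeighbors),
                      min_dist = minDist, spread = spread,
                      metric = metric, seed = as.integer(seed)),
        coords = coords,
        labels = as.character(labels),
        featureMeans = colMeans(x),
        uwot = fit,
        version = MODEL_FORMAT_VERSION)
})

#' @describeIn fitReferenceMap fit from a [ReferenceDatabase-class].
#' @exportMethod fitReferenceMap
setMethod("fitReferenceMap", "ReferenceDatabase", function(x, ...) {
    fitReferenceMap(featureMatrix(x), labels = libraryType(x), ...)
})

#' @rdname ReferenceMap-class
#' @param x a \code{ReferenceMap}.
#' @export
mapCoords <- function(x) x@coords

#' @rdname ReferenceMap-class
#' @export
mapLabels <- function(x) x@labels

#' @rdname ReferenceMap-class
#' @export
mapParams <- function(x) x@params

setMethod("show", "ReferenceMap", function(object) {
    p <- object@params
    cat("ReferenceMap:", nrow(object@coords), "reference samples,",
        length(unique(object@labels)), "library types\n",
        " umap: n_neighbors =", p$n_neighbors,
        ", min_dist =", p$min_dist, ", spread =", p$spread,
        ", metric =", p$metric, ", seed =", p$seed, "\n")
    if (is.null(object@uwot))
        cat("  (transform state not loaded; projection unavailable)\n")
})

#' Project new samples onto a fitted reference map
#'
#' Places query feature vectors on the existing 2-D manifold via UMAP's
#' out-of-sample transform. The map itself is never refit: queries are
#' positioned relative to the fixed reference embedding, so adding queries
#' cannot move the map or each other's coordinates.
#'
#' @param model a [ReferenceMap-class] with transform state (freshly
#'   fitted, or restored by [loadModel()]).
#' @param features numeric Q x 4L matrix of percentage features (rows =
#'   queries); a single vector is treated as one query. Q = 0 returns an
#'   empty coordinate matrix.
#' @return numeric Q x 2 matrix of map coordinates.
#' @export
projectSamples <- function(model, features) {
    if (is.null(dim(features)))
        features <- matrix(features, nrow = 1,
                           dimnames = list(NULL, names(features)))
    d <- length(model@featureMeans)
    if (ncol(features) != d)
        stop("feature dimension mismatch: model expects ", d,
             " features, got ", ncol(features))
    if (nrow(features) == 0L)
        return(matrix(numeric(0), 0, 2, dimnames = list(NULL, c("x", "y"))))
    if (is.null(model@uwot))
        stop("model has no transform state; reload it with loadModel()")
    # one transform call per query, each from the same seed: queries are
    # placed independently, so batch composition cannot affect results
    coords <- do.call(rbind, lapply(seq_len(nrow(features)), function(q) {
        set.seed(model@params$seed)
        uwot::umap_transform(features[q, , drop = FALSE], model@uwot,
                             n_threads = 1, n_sgd_threads = 0)
    }))
    coords <- unname(coords)
    rownames(coords) <- rownames(features)
    colnames(coords) <- c("x", "y")
    coords
}

#' Save / load a fitted reference map
#'
#' Persists a [ReferenceMap-class] as a versioned directory: \code{params.json}
#' (embedding parameters and format version), \code{coords.tsv} (reference
#' coordinates and labels, full double precision), \code{feature_means.tsv},
#' and \code{uwot_model} (the transform state, via \code{uwot::save_uwot}).
#' Reloading restores coordinates exactly and projection behaviour to
#' within 1e-6.
#'
#' @param model a [ReferenceMap-class].
#' @param path directory to create (save) or read (load).
#' @return \code{saveModel}: \code{path} invisibly; \code{loadModel}: a
#'   [ReferenceMap-class].
#' @export
saveModel <- function(model, path) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
        c(model@params, list(format_version = model@version)),
        file.path(path, "params.json"), auto_unbox = TRUE, digits = NA)
    co <- data.frame(sample_id = rownames(model@coords),
                     library_type = model@labels,
                     x = sprintf("%.17g", model@coords[, 1]),
                     y = sprintf("%.17g", model@coords[, 2]))
    utils::write.table(co, file.path(path, "coords.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    fm <- data.frame(feature = names(model@featureMeans),
                     mean = sprintf("%.17g", model@featureMeans))
    utils::write.table(fm, file.path(path, "feature_means.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    uwot::save_uwot(model@uwot, file.path(path, "uwot_model"),
                    unload = FALSE, verbose = FALSE)
    invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
    pj <- file.path(path, "params.json")
    if (!file.exists(pj))
        stop("not a saved reference map (missing params.json): ", path)
    params <- jsonlite::read_json(pj, simplifyVector = TRUE)
    if (!identical(as.character(params$format_version),
                   MODEL_FORMAT_VERSION))
        stop("model at ", path, " has format version ",
             params$format_version, "; this package reads version ",
             MODEL_FORMAT_VERSION)
    params$format_version <- NULL
    co <- utils::read.table(file.path(path, "coords.tsv"), sep = "\t",
                            header = TRUE, colClasses = "character")
    coords <- cbind(x = as.numeric(co$x), y = as.numeric(co$y))
    rownames(coords) <- co$sample_id
    fm <- utils::read.table(file.path(path, "feature_means.tsv"), sep = "\t",
                            header = TRUE, colClasses = "character")
    means <- as.numeric(fm$mean)
    names(means) <- fm$feature
    uw <- tryCatch(
        uwot::load_uwot(file.path(path, "uwot_model")),
        error = function(e) stop("corrupt transform state in ", path, ": ",
                                 conditionMessage(e)))
    methods::new("ReferenceMap",
        params = lapply(params, function(p) p),
        coords = coords,
        labels = co$library_type,
        featureMeans = means,
        uwot = uw,
        version = MODEL_FORMAT_VERSION)
}
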