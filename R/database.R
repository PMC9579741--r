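#' Build a reference database from labelled composition profiles
#'
#' Assembles profiles into a [ReferenceDatabase-class] (a
#' SummarizedExperiment whose \code{"percent"} assay holds the 4-per-position
#' percentage features). All profiles must cover the same number of
#' positions. Positions a profile has no coverage for are imputed with the
#' across-sample mean of the covered profiles at that position, with a
#' warning; \code{strict = TRUE} errors instead.
#'
#' @param profiles list of [CompositionProfile-class] objects.
#' @param libraryType character vector of library-type labels, one per
#'   profile (e.g. \code{"RNA-Seq"}, \code{"Bisulfite-Seq"}).
#' @param species optional character vector (stored, never used by the
#'   model: composition signatures are protocol-driven, not species-driven
#'   for organisms of similar GC content).
#' @param strict error on zero-coverage positions instead of imputing.
#' @return a [ReferenceDatabase-class].
#' @export
ReferenceDatabase <- function(profiles, libraryType, species = NA_character_,
                              strict = FALSE) {
    stopifnot(length(profiles) >= 1L,
              length(libraryType) == length(profiles))
    Ls <- vapply(profiles, function(p) nrow(counts(p)), integer(1))
    if (length(unique(Ls)) != 1L)
        stop("profiles have inconsistent position counts: ",
             paste(unique(Ls), collapse = ", "))
    L <- Ls[1L]
    feat <- vapply(profiles, function(p) {
        pct <- toPercentages(p, includeN = FALSE, strict = strict)
        as.vector(t(pct))
    }, numeric(4L * L))
    if (anyNA(feat)) {
        mu <- rowMeans(feat, na.rm = TRUE)
        bad <- which(colSums(is.na(feat)) > 0)
        warning("imputed database-mean composition for uncovered positions ",
                "in sample(s) ",
                paste(vapply(profiles[bad], sampleId, character(1)),
                      collapse = ", "))
        for (j in bad) feat[is.na(feat[, j]), j] <- mu[is.na(feat[, j])]
    }
    rownames(feat) <- featureNames(L)
    ids <- vapply(profiles, sampleId, character(1))
    colnames(feat) <- ids
    referenceDatabaseFromFeatures(
        feat,
        libraryType = libraryType,
        species = rep_len(as.character(species), length(profiles)),
        readsSampled = vapply(profiles, readsSampled, integer(1)),
        readsTotal = vapply(profiles, readsTotal, integer(1)))
}

referenceDatabaseFromFeatures <- function(feat, libraryType, species,
                                          readsSampled,
                                          readsTotal = readsSampled) {
    if (anyDuplicated(colnames(feat)))
        warning("duplicate sample_id(s) in database: ",
                paste(unique(colnames(feat)[duplicated(colnames(feat))]),
                      collapse = ", "), " (all records kept)")
    L <- nrow(feat) / 4L
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(percent = feat),
        rowData = S4Vectors::DataFrame(
            position = rep(seq_len(L), each = 4L),
            base = rep(BASES, L)),
        colData = S4Vectors::DataFrame(
            library_type = as.character(libraryType),
            species = as.character(species),
            reads_sampled = as.integer(readsSampled),
            reads_total = as.integer(readsTotal),
            row.names = NULL))
    md <- list(positions = L, filter_log = NULL)
    db <- methods::new("ReferenceDatabase", se)
    S4Vectors::metadata(db) <- md
    db
}

#' @rdname ReferenceDatabase-class
#' @exportMethod libraryType
setMethod("libraryType", "ReferenceDatabase", function(x)
    SummarizedExperiment::colData(x)$library_type)

#' @rdname featureMatrix
#' @exportMethod featureMatrix
setMethod("featureMatrix", "ReferenceDatabase", function(x) {
    t(SummarizedExperiment::assay(x, "percent"))
})

setMethod("show", "ReferenceDatabase", function(object) {
    cat("ReferenceDatabase:", ncol(object), "samples,",
        S4Vectors::metadata(object)$positions, "positions\n")
    print(table(libraryType(object)))
    fl <- S4Vectors::metadata(object)$filter_log
    if (!is.null(fl)) cat("  (filtered; see metadata(x)$filter_log)\n")
})

#' Apply the reference-map inclusion rules to a database
#'
#' Filters the database the way the reference map's training set is
#' defined: records labelled \code{OTHER} (case-insensitive) are excluded,
#' library types with fewer than \code{minPerType} samples are dropped
#' entirely, and types with more than \code{capPerType} samples are reduced
#' to exactly \code{capPerType} by a seeded uniform random subsample. The
#' per-type before/after counts are recorded in
#' \code{metadata(x)$filter_log}.
#'
#' Filtering is idempotent: applying it to an already-filtered database
#' changes nothing (the cap draw only triggers for over-full types).
#'
#' @param db a [ReferenceDatabase-class].
#' @param minPerType minimum samples a type needs to be kept (default 25).
#' @param capPerType maximum samples retained per type (default 500).
#' @param seed seed for the capping subsample.
#' @return the filtered [ReferenceDatabase-class].
#' @export
filterDatabase <- function(db, minPerType = 25L, capPerType = 500L,
                           seed = 0L) {
    stopifnot(ncol(db) >= 1L)
    types <- libraryType(db)
    keep <- rep(TRUE, ncol(db))
    isOther <- toupper(types) == "OTHER"
    keep[isOther] <- FALSE
    tab <- table(types[!isOther])
    small <- names(tab)[tab < minPerType]
    keep[types %in% small] <- FALSE
    set.seed(as.integer(seed))
    capped <- names(tab)[tab > capPerType]
    for (ty in sort(capped)) {   # sorted: capping order independent of input
        idx <- which(types == ty & keep)
        drop <- sample(idx, length(idx) - capPerType)
        keep[drop] <- FALSE
    }
    if (!any(keep))
        stop("all ", ncol(db), " records removed by filtering; ",
             "nothing left to build a reference map from")
    after <- table(types[keep])
    log <- data.frame(
        library_type = names(tab),
        n_before = as.integer(tab),
        n_after = as.integer(ifelse(names(tab) %in% names(after),
                                    after[names(tab)], 0L)),
        row.names = NULL)
    log$action <- ifelse(log$n_after == 0L, "dropped_below_minimum",
                  ifelse(log$n_before > log$n_after, "capped", "kept"))
    if (any(isOther))
        log <- rbind(log, data.frame(
            library_type = "OTHER", n_before = sum(isOther),
            n_after = 0L, action = "excluded_OTHER"))
    out <- db[, keep]
    out <- methods::new("ReferenceDatabase", out)
    md <- S4Vectors::metadata(db)
    md$filter_log <- log
    md$filter_params <- list(min_per_type = as.integer(minPerType),
                             cap_per_type = as.integer(capPerType),
                             seed = as.integer(seed))
    S4Vectors::metadata(out) <- md
    out
}

#' Save / load a reference database
#'
#' Tab-separated, one row per sample: \code{sample_id}, \code{library_type},
#' \code{species}, the 4L percentage features \code{pos1_A ... posL_T}
#' (written at full double precision so the round trip is lossless), and
#' \code{reads_sampled}. A JSON sidecar \code{<path>.json} stores the
#' filter log and build parameters when present.
#'
#' @param db a [ReferenceDatabase-class].
#' @param path TSV file path.
#' @return \code{saveDatabase}: \code{path} invisibly;
#'   \code{loadDatabase}: a [ReferenceDatabase-class].
#' @export
saveDatabase <- function(db, path) {
    feat <- featureMatrix(db)
    cd <- SummarizedExperiment::colData(db)
    df <- data.frame(sample_id = colnames(db),
                     library_type = cd$library_type,
                     species = cd$species,
                     matrix(sprintf("%.17g", feat), nrow = nrow(feat),
                            dimnames = list(NULL, colnames(feat))),
                     reads_sampled = cd$reads_sampled,
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    md <- S4Vectors::metadata(db)
    side <- list(positions = md$positions)
    if (!is.null(md$filter_log)) {
        side$filter_log <- md$filter_log
        side$filter_params <- md$filter_params
    }
    jsonlite::write_json(side, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname saveDatabase
#' @export
loadDatabase <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            check.names = FALSE,
                            colClasses = "character")
    L <- (ncol(df) - 4L) / 4L
    need <- c("sample_id", "library_type", "species", featureNames(L),
              "reads_sampled")
    if (ncol(df) < 5L || !identical(colnames(df), need))
        stop("database file ", path, " does not match the expected header ",
             "(sample_id, library_type, species, pos1_A...pos", L,
             "_T, reads_sampled)")
    feat <- matrix(as.numeric(as.matrix(df[featureNames(L)])),
                   nrow = nrow(df))
    feat <- t(feat)
    dimnames(feat) <- list(featureNames(L), df$sample_id)
    db <- referenceDatabaseFromFeatures(
        feat, libraryType = df$library_type, species = df$species,
        readsSampled = as.integer(df$reads_sampled))
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
        side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
        md <- S4Vectors::metadata(db)
        if (!is.null(side$filter_log))
            md$filter_log <- as.data.frame(side$filter_log)
        md$filter_params <- side$filter_params
        S4Vectors::metadata(db) <- md
    }
    db
}
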