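#' Construct a CompositionProfile
#'
#' @param sampleId library identifier.
#' @param counts integer L x 5 matrix with columns A, C, G, T, N.
#' @param readsSampled number of reads tabulated.
#' @param readsTotal number of records in the source file (defaults to
#'   \code{readsSampled}).
#' @param seed subsampling seed recorded for reproducibility.
#' @return a [CompositionProfile-class] object.
#' @export
CompositionProfile <- function(sampleId, counts,
                               readsSampled = NULL,
                               readsTotal = NULL,
                               seed = 0L) {
    storage.mode(counts) <- "integer"
    colnames(counts) <- BASESN
    if (is.null(readsSampled)) readsSampled <- max(rowSums(counts))
    if (is.null(readsTotal)) readsTotal <- readsSampled
    new("CompositionProfile",
        sampleId = as.character(sampleId),
        counts = counts,
        readsSampled = as.integer(readsSampled),
        readsTotal = as.integer(readsTotal),
        seed = as.integer(seed))
}

#' @rdname CompositionProfile-class
#' @exportMethod sampleId
setMethod("sampleId", "CompositionProfile", function(x) x@sampleId)

#' @rdname CompositionProfile-class
#' @exportMethod readsSampled
setMethod("readsSampled", "CompositionProfile", function(x) x@readsSampled)

#' @rdname CompositionProfile-class
#' @exportMethod readsTotal
setMethod("readsTotal", "CompositionProfile", function(x) x@readsTotal)

#' @rdname CompositionProfile-class
#' @exportMethod counts
setMethod("counts", "CompositionProfile", function(object) object@counts)

#' @rdname CompositionProfile-class
#' @exportMethod length
setMethod("length", "CompositionProfile", function(x) nrow(x@counts))

setMethod("show", "CompositionProfile", function(object) {
    cat("CompositionProfile:", object@sampleId, "\n",
        " positions:", nrow(object@counts), "\n",
        " reads sampled:", object@readsSampled,
        "of", object@readsTotal, "(seed", paste0(object@seed, ")"), "\n")
    pct <- 100 * colSums(object@counts) / sum(object@counts)
    cat("  overall base content (%):",
        paste(sprintf("%s %.1f", BASESN, pct), collapse = ", "), "\n")
})

#' Tabulate per-position base content of a set of reads
#'
#' Counts, for each of the leading \code{maxPositions} positions, how many
#' reads carry each base A/C/G/T/N there. Reads shorter than
#' \code{maxPositions} contribute only up to their length, so positions a
#' read does not cover simply receive no count from it.
#'
#' @param reads character vector of read sequences (anything outside
#'   A/C/G/T, after uppercasing, counts as N), or the \code{records}
#'   data.frame returned by [reservoirSampleFastq()].
#' @param maxPositions number of leading positions to profile (default 50).
#' @param sampleId identifier stored in the profile.
#' @param readsTotal,seed bookkeeping recorded in the profile.
#' @return a [CompositionProfile-class].
#' @examples
#' p <- tabulateComposition(c("ACGT", "AAAA"), maxPositions = 4,
#'                          sampleId = "toy")
#' counts(p)
#' @export
tabulateComposition <- function(reads, maxPositions = 50L,
                                sampleId = "sample",
                                readsTotal = NULL, seed = 0L) {
    if (is.data.frame(reads)) reads <- reads$seq
    if (length(reads) == 0L)
        stop("no reads to tabulate")
    maxPositions <- as.integer(maxPositions)
    reads <- normalizeBases(reads)
    dna <- Biostrings::DNAStringSet(reads)
    w <- Biostrings::width(dna)
    dna <- Biostrings::subseq(dna, 1L, pmin(w, maxPositions))
    cm <- Biostrings::consensusMatrix(dna)
    cnt <- matrix(0L, nrow = maxPositions, ncol = 5L,
                  dimnames = list(NULL, BASESN))
    have <- min(ncol(cm), maxPositions)
    for (b in BASESN)
        if (b %in% rownames(cm))
            cnt[seq_len(have), b] <- as.integer(cm[b, seq_len(have)])
    CompositionProfile(sampleId, cnt,
                       readsSampled = length(reads),
                       readsTotal = readsTotal, seed = seed)
}

#' Subsample a FASTQ file and tabulate its composition in one step
#'
#' The standard extraction path: reservoir-sample up to \code{reads} reads
#' from read1 of a library and tabulate the base content of their first
#' \code{positions} positions.
#'
#' @param path FASTQ file (plain or gzip).
#' @param reads sampling cap (default 100,000).
#' @param positions leading positions to profile (default 50).
#' @param seed sampling seed.
#' @param sampleId identifier; defaults to the file name without
#'   FASTQ/gz extensions.
#' @return a [CompositionProfile-class].
#' @export
extractProfile <- function(path, reads = 100000L, positions = 50L,
                           seed = 0L, sampleId = NULL) {
    if (is.null(sampleId))
        sampleId <- sub("\\.(fastq|fq)(\\.gz)?$", "",
                        basename(path), ignore.case = TRUE)
    smp <- reservoirSampleFastq(path, k = reads, seed = seed)
    tabulateComposition(smp$records, maxPositions = positions,
                        sampleId = sampleId,
                        readsTotal = smp$readsTotal, seed = seed)
}

#' Convert per-position counts to percentages
#'
#' Each position's counts are scaled to percentages summing to 100. With
#' \code{includeN = FALSE} (the default, matching how composition curves
#' are conventionally plotted) N calls are dropped from the denominator and
#' the A/C/G/T percentages are renormalised.
#'
#' Positions no sampled read covers have an all-zero row: with
#' \code{strict = TRUE} this is an error naming the position; otherwise
#' those rows are returned as \code{NA} for the caller to impute (the
#' database layer fills them with the database-wide mean).
#'
#' @param profile a [CompositionProfile-class].
#' @param includeN keep N as a fifth column?
#' @param strict error on zero-coverage positions instead of returning NA?
#' @return numeric L x 4 (or L x 5) matrix; rows sum to 100 (or are NA).
#' @export
toPercentages <- function(profile, includeN = FALSE, strict = FALSE) {
    cnt <- counts(profile)
    if (!includeN) cnt <- cnt[, BASES, drop = FALSE]
    tot <- rowSums(cnt)
    if (any(tot == 0)) {
        if (strict)
            stop("no base calls at position", if (sum(tot == 0) > 1) "s" else "",
                 " ", paste(which(tot == 0), collapse = ", "),
                 " of sample ", sampleId(profile))
        tot[tot == 0] <- NA_real_
    }
    100 * cnt / tot
}

#' Flatten a profile to the embedding feature vector
#'
#' Concatenates the per-position A/C/G/T percentages (N excluded) into a
#' single vector of length 4L, in position-major order. Zero-coverage
#' positions are imputed from \code{fill} (a reference feature vector such
#' as a [ReferenceMap]'s training mean) with a warning, or raise an error
#' when no fill is supplied.
#'
#' @param profile a [CompositionProfile-class].
#' @param fill optional numeric(4L) fallback values for uncovered positions.
#' @return named numeric vector \code{pos1_A ... posL_T}.
#' @export
profileFeatures <- function(profile, fill = NULL) {
    pct <- toPercentages(profile, includeN = FALSE, strict = FALSE)
    L <- nrow(pct)
    v <- as.vector(t(pct))
    names(v) <- featureNames(L)
    if (anyNA(v)) {
        bad <- unique(ceiling(which(is.na(v)) / 4))
        if (is.null(fill))
            stop("sample ", sampleId(profile), " has no coverage at position",
                 if (length(bad) > 1) "s" else "", " ",
                 paste(bad, collapse = ", "),
                 " and no fill values were supplied")
        stopifnot(length(fill) == length(v))
        warning("sample ", sampleId(profile),
                ": imputing reference mean composition at position",
                if (length(bad) > 1) "s" else "", " ",
                paste(bad, collapse = ", "))
        v[is.na(v)] <- fill[is.na(v)]
    }
    v
}

featureNames <- function(L) {
    paste0("pos", rep(seq_len(L), each = 4L), "_", rep(BASES, L))
}

#' Write / read a composition profile
#'
#' Tab-separated round trip: `#`-prefixed metadata lines (sample_id,
#' reads_sampled, reads_total, seed) followed by a header
#' \code{position A C G T N} and one row of integer counts per position,
#' positions labelled 1..L. \code{readProfile(writeProfile(x))} is exact.
#'
#' @param profile a [CompositionProfile-class].
#' @param path output (input) file path.
#' @return \code{writeProfile}: \code{path}, invisibly.
#'   \code{readProfile}: a [CompositionProfile-class].
#' @export
writeProfile <- function(profile, path) {
    cnt <- counts(profile)
    hdr <- c(paste0("# sample_id: ", sampleId(profile)),
             paste0("# reads_sampled: ", readsSampled(profile)),
             paste0("# reads_total: ", readsTotal(profile)),
             paste0("# seed: ", profile@seed))
    df <- data.frame(position = seq_len(nrow(cnt)), cnt)
    con <- file(path, "wt")
    on.exit(close(con))
    writeLines(hdr, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' @rdname writeProfile
#' @export
readProfile <- function(path) {
    lines <- readLines(path)
    meta <- grep("^#", lines, value = TRUE)
    getMeta <- function(key) {
        m <- grep(paste0("^# ", key, ": "), meta, value = TRUE)
        if (length(m) != 1L)
            stop("profile file ", path, " lacks metadata line '", key, "'")
        sub(paste0("^# ", key, ": "), "", m)
    }
    body <- lines[!grepl("^#", lines)]
    df <- utils::read.table(text = body, header = TRUE, sep = "\t",
                            check.names = FALSE)
    need <- c("position", BASESN)
    if (!identical(colnames(df), need))
        stop("profile file ", path, ": expected columns ",
             paste(need, collapse = ", "), "; found ",
             paste(colnames(df), collapse = ", "))
    cnt <- as.matrix(df[, BASESN])
    if (any(cnt != round(cnt)))
        stop("profile file ", path, ": counts must be integers")
    CompositionProfile(getMeta("sample_id"), cnt,
                       readsSampled = as.integer(getMeta("reads_sampled")),
                       readsTotal = as.integer(getMeta("reads_total")),
                       seed = as.integer(getMeta("seed")))
}
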