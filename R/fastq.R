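#' Stream a FASTQ file in chunks
#'
#' Opens a plain or gzip-compressed FASTQ file (compression auto-detected
#' from the magic bytes) and returns a reader that yields successive chunks
#' of records without loading the whole file. Each call to \code{$read()}
#' returns a data.frame with columns \code{id}, \code{seq}, \code{qual}
#' (or \code{NULL} at end of file); \code{$close()} releases the
#' connection. Sequences are uppercased and any character outside A/C/G/T
#' is mapped to N.
#'
#' Malformed input is diagnosed against the standard 4-line record layout:
#' a trailing partial record or a sequence/quality length mismatch raises
#' an error naming the (1-based) record index.
#'
#' @param path path to a FASTQ file, optionally gzipped.
#' @param chunkSize number of records per chunk.
#' @return a list with functions \code{read}, \code{close}.
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
#' rd <- streamFastq(fq)
#' rd$read()
#' rd$close()
#' @export
streamFastq <- function(path, chunkSize = 10000L) {
    if (!file.exists(path))
        stop("FASTQ file not found: ", path)
    con <- gzfile(path, open = "rt")  # transparent for plain text too
    recordIndex <- 0L
    finished <- FALSE
    readChunk <- function() {
        if (finished) return(NULL)
        lines <- readLines(con, n = as.integer(chunkSize) * 4L)
        if (length(lines) == 0L) {
            finished <<- TRUE
            if (recordIndex == 0L)
                stop("empty FASTQ file: ", path)
            return(NULL)
        }
        if (length(lines) %% 4L != 0L) {
            bad <- recordIndex + length(lines) %/% 4L + 1L
            stop("malformed FASTQ record ", bad, " in ", path,
                 ": truncated record (line count not a multiple of 4)")
        }
        n <- length(lines) %/% 4L
        ids  <- lines[seq(1L, length(lines), by = 4L)]
        seqs <- lines[seq(2L, length(lines), by = 4L)]
        qual <- lines[seq(4L, length(lines), by = 4L)]
        bad <- which(nchar(seqs) != nchar(qual))
        if (length(bad))
            stop("malformed FASTQ record ", recordIndex + bad[1L], " in ",
                 path, ": sequence and quality lengths differ")
        recordIndex <<- recordIndex + n
        data.frame(id = sub("^@", "", ids),
                   seq = normalizeBases(seqs),
                   qual = qual)
    }
    list(
        read  = readChunk,
        close = function() try(close(con), silent = TRUE)
    )
}

# uppercase and collapse anything outside A/C/G/T to N
normalizeBases <- function(x) {
    x <- toupper(x)
    gsub("[^ACGT]", "N", x)
}

# Reservoir state (Vitter's algorithm R, vectorised per chunk): keeps a
# uniform without-replacement sample of k records from a stream of unknown
# length. Slots are parallel character vectors so chunk updates are single
# vectorised assignments; duplicated replacement targets within a chunk
# resolve left-to-right, matching the sequential algorithm.
reservoirInit <- function(k) {
    k <- as.integer(k)
    list(k = k, n = 0L,
         id = character(k), seq = character(k), qual = character(k))
}

reservoirUpdate <- function(state, records) {
    m <- nrow(records)
    if (m == 0L) return(state)
    idx <- state$n + seq_len(m)
    k <- state$k
    fill <- which(idx <= k)
    if (length(fill)) {
        pos <- idx[fill]
        state$id[pos]   <- records$id[fill]
        state$seq[pos]  <- records$seq[fill]
        state$qual[pos] <- records$qual[fill]
    }
    rest <- if (length(fill)) seq_len(m)[-fill] else seq_len(m)
    if (length(rest)) {
        u <- stats::runif(length(rest))
        accept <- rest[u < k / idx[rest]]
        if (length(accept)) {
            tgt <- sample.int(k, length(accept), replace = TRUE)
            state$id[tgt]   <- records$id[accept]
            state$seq[tgt]  <- records$seq[accept]
            state$qual[tgt] <- records$qual[accept]
        }
    }
    state$n <- state$n + m
    state
}

reservoirFinish <- function(state) {
    kept <- seq_len(min(state$n, state$k))
    list(records = data.frame(id = state$id[kept], seq = state$seq[kept],
                              qual = state$qual[kept]),
         readsTotal = state$n)
}

#' Uniformly subsample reads from a FASTQ file
#'
#' Draws up to \code{k} reads uniformly at random, without replacement, in
#' a single pass over the file (reservoir sampling), so files of any size
#' are handled in constant memory. If the file holds \code{k} records or
#' fewer, all are returned. Deterministic for a fixed \code{seed}.
#'
#' @param path FASTQ file (plain or gzip).
#' @param k maximum number of reads to keep (default 100,000).
#' @param seed RNG seed recorded downstream for reproducibility.
#' @param chunkSize records read per chunk (internal granularity; does not
#'   affect the result for a given seed).
#' @return list with \code{records} (data.frame id/seq/qual) and
#'   \code{readsTotal}, the number of records seen.
#' @seealso [tabulateComposition()], [extractProfile()]
#' @export
reservoirSampleFastq <- function(path, k = 100000L, seed = 0L,
                                 chunkSize = 10000L) {
    stopifnot(k >= 1L)
    reader <- streamFastq(path, chunkSize = chunkSize)
    on.exit(reader$close())
    set.seed(as.integer(seed))
    state <- reservoirInit(k)
    repeat {
        chunk <- reader$read()
        if (is.null(chunk)) break
        state <- reservoirUpdate(state, chunk)
    }
    reservoirFinish(state)
}

# Pure-index variant used to verify the sampler's distribution: runs the
# identical chunked reservoir over the indices 1..n.
reservoirIndices <- function(n, k, seed, chunkSize = 10000L) {
    set.seed(as.integer(seed))
    state <- reservoirInit(k)
    done <- 0L
    while (done < n) {
        m <- min(chunkSize, n - done)
        chunk <- data.frame(id = as.character(done + seq_len(m)),
                            seq = "", qual = "")
        state <- reservoirUpdate(state, chunk)
        done <- done + m
    }
    out <- reservoirFinish(state)
    as.integer(out$records$id)
}
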