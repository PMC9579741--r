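#' Library-type composition signatures
#'
#' Builds the expected per-position A/C/G/T probability matrix for a
#' stylised library-type signature. Five protocols are modelled, each a
#' verbal-description encoding of how its chemistry shapes read
#' composition, layered on a flat genomic baseline of the requested GC
#' content:
#'
#' \describe{
#'   \item{genomic}{ChIP-seq-like: most reads come from non-enriched
#'     genomic background, so every position carries the genome's base
#'     composition — A = T = (1 - gc/100)/2, C = G = (gc/100)/2.}
#'   \item{bisulfite}{unmethylated C reads as T after conversion: C is
#'     reduced to a small residual (\code{cResidual}, methylated CpG
#'     leftovers) at every position, the deficit added to T.}
#'   \item{atac}{Tn5 target-sequence preference imprints a positional
#'     bias at the read start: a perturbation towards a fixed preferred
#'     base, geometrically decaying over the first \code{atacSpan}
#'     positions and exactly zero beyond them.}
#'   \item{chiapet}{the ligated linker puts a near-deterministic base
#'     pattern (\code{linkerSeq}, probability \code{linkerStrength}) in
#'     the middle of the read, positions \code{linkerStart} onward.}
#'   \item{rnaseq}{random-priming bias: a milder decaying perturbation
#'     over the first \code{rnaSpan} positions.}
#' }
#'
#' @param type one of \code{"genomic"}, \code{"bisulfite"}, \code{"atac"},
#'   \code{"chiapet"}, \code{"rnaseq"}.
#' @param L number of read positions (default 50).
#' @param gcPercent genome GC content in percent; 41 (human) by default,
#'   42 for mouse.
#' @param cResidual residual C fraction after bisulfite conversion.
#' @param atacAmp,atacDecay,atacSpan start-bias amplitude, geometric decay
#'   per position and number of affected positions.
#' @param linkerStart,linkerSeq,linkerStrength linker window start
#'   (1-based), linker bases, and per-position linker-base probability.
#' @param rnaAmp,rnaDecay,rnaSpan random-priming perturbation parameters.
#' @return a list of class \code{"SignatureModel"} with elements
#'   \code{name}, \code{baseProbs} (L x 4 row-stochastic matrix, columns
#'   A, C, G, T) and \code{description}.
#' @examples
#' sig <- makeSignature("bisulfite")
#' range(sig$baseProbs[, "C"])
#' @export
makeSignature <- function(type, L = 50L, gcPercent = 41,
                          cResidual = 0.02,
                          atacAmp = 0.25, atacDecay = 0.65, atacSpan = 12L,
                          linkerStart = 17L, linkerSeq = "ACGCGATAT",
                          linkerStrength = 0.9,
                          rnaAmp = 0.10, rnaDecay = 0.8, rnaSpan = 10L) {
    valid <- c("genomic", "bisulfite", "atac", "chiapet", "rnaseq")
    if (!type %in% valid)
        stop("unknown signature type '", type, "'; valid types: ",
             paste(valid, collapse = ", "))
    gc <- gcPercent / 100
    base <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    probs <- matrix(rep(base, each = L), nrow = L,
                    dimnames = list(NULL, BASES))
    desc <- sprintf("flat genomic baseline at %.0f%% GC", gcPercent)
    if (type == "bisulfite") {
        deficit <- probs[, "C"] - cResidual
        probs[, "C"] <- cResidual
        probs[, "T"] <- probs[, "T"] + deficit
        desc <- sprintf(
            "bisulfite conversion: C depleted to %.3f throughout, deficit read as T",
            cResidual)
    } else if (type %in% c("atac", "rnaseq")) {
        amp <- if (type == "atac") atacAmp else rnaAmp
        decay <- if (type == "atac") atacDecay else rnaDecay
        span <- min(if (type == "atac") atacSpan else rnaSpan, L)
        pattern <- if (type == "atac")
            rep(c("T", "G", "A", "C"), length.out = span)
        else
            rep(c("C", "G", "A", "T"), length.out = span)
        for (p in seq_len(span)) {
            delta <- amp * decay^(p - 1)
            e <- as.numeric(BASES == pattern[p])
            probs[p, ] <- (1 - delta) * probs[p, ] + delta * e
        }
        desc <- if (type == "atac")
            sprintf("Tn5 start bias: amplitude %.2f decaying by %.2f over %d positions",
                    amp, decay, span)
        else
            sprintf("random-priming bias: amplitude %.2f decaying by %.2f over %d positions",
                    amp, decay, span)
    } else if (type == "chiapet") {
        bases <- strsplit(toupper(linkerSeq), "")[[1]]
        stopifnot(all(bases %in% BASES))
        pos <- linkerStart + seq_along(bases) - 1L
        pos <- pos[pos <= L]
        for (i in seq_along(pos)) {
            e <- as.numeric(BASES == bases[i])
            probs[pos[i], ] <- linkerStrength * e +
                (1 - linkerStrength) * probs[pos[i], ]
        }
        desc <- sprintf(
            "ChIA-PET linker '%s' at positions %d-%d (strength %.2f)",
            linkerSeq, linkerStart, max(pos), linkerStrength)
    }
    stopifnot(max(abs(rowSums(probs) - 1)) < 1e-12)
    structure(list(name = type, baseProbs = probs, description = desc),
              class = "SignatureModel")
}

#' @export
print.SignatureModel <- function(x, ...) {
    cat("SignatureModel:", x$name, "(", nrow(x$baseProbs), "positions )\n ",
        x$description, "\n")
    invisible(x)
}

# one Dirichlet draw per row of alpha (rows of a signature matrix)
rdirichletRows <- function(alpha) {
    g <- matrix(stats::rgamma(length(alpha), shape = alpha),
                nrow = nrow(alpha))
    g / rowSums(g)
}

#' Draw a composition profile from a signature
#'
#' Simulates the profile of one library: at each position the base counts
#' are a multinomial draw of \code{nReads} trials from the signature's
#' probability row (no N calls). Deterministic for a fixed seed.
#'
#' @param sig a \code{SignatureModel} from [makeSignature()].
#' @param nReads reads per position (default 100,000, the standard
#'   sampling cap).
#' @param seed RNG seed.
#' @param sampleId identifier for the profile.
#' @param jitter optional Dirichlet concentration; when finite, the
#'   signature rows are first perturbed by a per-sample Dirichlet draw
#'   with concentration \code{jitter * p}, emulating sample-to-sample
#'   variability within a library type.
#' @return a [CompositionProfile-class].
#' @export
sampleProfile <- function(sig, nReads = 100000L, seed = 0L,
                          sampleId = sig$name, jitter = Inf) {
    stopifnot(nReads >= 1L)
    set.seed(as.integer(seed))
    probs <- sig$baseProbs
    if (is.finite(jitter))
        probs <- rdirichletRows(jitter * probs)
    L <- nrow(probs)
    cnt <- matrix(0L, L, 5L, dimnames = list(NULL, BASESN))
    for (p in seq_len(L))
        cnt[p, BASES] <- as.integer(stats::rmultinom(1, nReads, probs[p, ]))
    CompositionProfile(sampleId, cnt, readsSampled = nReads,
                       readsTotal = nReads, seed = seed)
}

#' Generate a synthetic FASTQ file from a signature
#'
#' Writes \code{nReads} reads of length \code{readLen}: the first L bases
#' of each read are drawn independently per position from the signature's
#' probability rows, positions beyond L from the last row. Quality is a
#' constant dummy ('I'). Gzip output when \code{path} ends in
#' \code{.gz}. Extracting the composition from the written file recovers
#' the signature probabilities to within multinomial error.
#'
#' @param sig a \code{SignatureModel}.
#' @param nReads number of reads (must be >= 1).
#' @param readLen read length, at least the signature's position count.
#' @param path output path (.fastq or .fastq.gz).
#' @param seed RNG seed.
#' @return \code{path}, invisibly.
#' @export
generateFastq <- function(sig, nReads, readLen = nrow(sig$baseProbs),
                          path = tempfile(fileext = ".fastq"), seed = 0L) {
    if (nReads < 1L) stop("nReads must be >= 1")
    L <- nrow(sig$baseProbs)
    stopifnot(readLen >= L)
    set.seed(as.integer(seed))
    nReads <- as.integer(nReads)
    cols <- vector("list", readLen)
    for (p in seq_len(readLen)) {
        pr <- sig$baseProbs[min(p, L), ]
        cols[[p]] <- BASES[sample.int(4L, nReads, replace = TRUE, prob = pr)]
    }
    seqs <- do.call(paste0, cols)
    qual <- strrep("I", readLen)
    lines <- character(4L * nReads)
    lines[seq(1L, by = 4L, length.out = nReads)] <-
        paste0("@", sig$name, "_read", seq_len(nReads))
    lines[seq(2L, by = 4L, length.out = nReads)] <- seqs
    lines[seq(3L, by = 4L, length.out = nReads)] <- "+"
    lines[seq(4L, by = 4L, length.out = nReads)] <- qual
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
    ok <- tryCatch({ writeLines(lines, con); TRUE },
                   error = function(e) {
                       stop("cannot write FASTQ to ", path, ": ",
                            conditionMessage(e))
                   })
    close(con)
    invisible(path)
}

#' Default signature set for a synthetic reference database
#'
#' Named mapping from repository-style library-type labels to signature
#' types, mirroring the protocols with the most distinctive composition
#' signatures.
#' @return named character vector (names = labels, values = signature
#'   types).
#' @export
defaultSignatureTypes <- function() {
    c("ChIP-Seq" = "genomic",
      "Bisulfite-Seq" = "bisulfite",
      "ATAC-seq" = "atac",
      "ChIA-PET" = "chiapet",
      "RNA-Seq" = "rnaseq")
}

#' Generate a synthetic labelled reference database
#'
#' Simulates \code{nPerType} libraries per library type. Each library's
#' expected composition is its type signature perturbed by a per-sample
#' Dirichlet draw (concentration \code{jitterConcentration}; larger =
#' tighter clusters), then observed through a multinomial with
#' \code{nReads} reads per position — so samples within a type scatter
#' realistically instead of coinciding.
#'
#' @param nPerType samples per type (default 50).
#' @param types named character vector mapping labels to signature types
#'   (default [defaultSignatureTypes()]).
#' @param nReads reads per simulated library (default 100,000).
#' @param L positions per profile (default 50).
#' @param gcPercent baseline GC content (default 41).
#' @param jitterConcentration Dirichlet concentration for per-sample
#'   jitter (default 2000); \code{Inf} disables jitter.
#' @param species species label stored with every record.
#' @param seed RNG seed; the whole database is reproducible from it.
#' @return a [ReferenceDatabase-class].
#' @export
generateReferenceDB <- function(nPerType = 50L,
                                types = defaultSignatureTypes(),
                                nReads = 100000L, L = 50L, gcPercent = 41,
                                jitterConcentration = 2000,
                                species = "synthetic", seed = 0L) {
    stopifnot(nPerType >= 1L, length(types) >= 1L,
              !is.null(names(types)))
    profiles <- list()
    labels <- character()
    i <- 0L
    for (lab in names(types)) {
        sig <- makeSignature(types[[lab]], L = L, gcPercent = gcPercent)
        for (s in seq_len(nPerType)) {
            i <- i + 1L
            profiles[[i]] <- sampleProfile(
                sig, nReads = nReads,
                seed = as.integer(seed) + i,
                sampleId = sprintf("%s_%03d", types[[lab]], s),
                jitter = jitterConcentration)
            labels[i] <- lab
        }
    }
    ReferenceDatabase(profiles, libraryType = labels, species = species)
}
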