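# shared fixtures: tiny FASTQ writers and a cached synthetic map

writeFastq <- function(seqs, path = tempfile(fileext = ".fastq"),
                       quals = strrep("I", nchar(seqs)),
                       ids = paste0("read", seq_along(seqs))) {
    con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
    writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), con)
    close(con)
    path
}

# one fitted 5-type map shared across tests (fit once; ~200 samples is
# plenty to exercise the embedding, tiling and prediction layers)
sharedMapFixture <- local({
    cache <- NULL
    function() {
        if (is.null(cache)) {
            db <- generateReferenceDB(nPerType = 40, nReads = 20000,
                                      seed = 7)
            model <- fitReferenceMap(db, seed = 42)
            grid <- buildGrid(mapCoords(model), mapLabels(model))
            cache <<- list(db = db, model = model, grid = grid)
        }
        cache
    }
})
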