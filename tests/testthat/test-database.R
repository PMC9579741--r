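makeToyDb <- function(typeCounts, seed = 1) {
    set.seed(seed)
    profiles <- list(); labels <- character(); i <- 0
    for (ty in names(typeCounts)) {
        sig <- makeSignature("genomic", L = 10)
        for (s in seq_len(typeCounts[[ty]])) {
            i <- i + 1
            profiles[[i]] <- sampleProfile(sig, nReads = 200,
                                           seed = 1000 + i,
                                           sampleId = sprintf("s%04d", i))
            labels[i] <- ty
        }
    }
    ReferenceDatabase(profiles, labels)
}

test_that("filtering drops OTHER and small types and caps large ones", {
    db <- makeToyDb(c(X = 24, Y = 25, Z = 80, OTHER = 10))
    out <- filterDatabase(db, minPerType = 25, capPerType = 50, seed = 4)
    tab <- table(libraryType(out))
    expect_equal(sort(names(tab)), c("Y", "Z"))
    expect_equal(as.integer(tab[["Y"]]), 25)
    expect_equal(as.integer(tab[["Z"]]), 50)
    log <- S4Vectors::metadata(out)$filter_log
    expect_setequal(log$action[log$library_type == "X"],
                    "dropped_below_minimum")
    expect_setequal(log$action[log$library_type == "OTHER"],
                    "excluded_OTHER")
    expect_equal(log$n_after[log$library_type == "Z"], 50)
})

test_that("'other' is excluded case-insensitively and emptiness errors", {
    db <- makeToyDb(c(other = 30))
    expect_error(filterDatabase(db), "all 30 records removed")
})

test_that("filtering is idempotent and capping is seeded", {
    db <- makeToyDb(c(Y = 30, Z = 80))
    f1 <- filterDatabase(db, minPerType = 25, capPerType = 50, seed = 9)
    f2 <- filterDatabase(f1, minPerType = 25, capPerType = 50, seed = 9)
    expect_identical(colnames(f1), colnames(f2))
    expect_identical(featureMatrix(f1), featureMatrix(f2))

    g1 <- filterDatabase(db, minPerType = 25, capPerType = 50, seed = 1)
    g2 <- filterDatabase(db, minPerType = 25, capPerType = 50, seed = 1)
    g3 <- filterDatabase(db, minPerType = 25, capPerType = 50, seed = 2)
    expect_identical(colnames(g1), colnames(g2))
    expect_false(identical(colnames(g1), colnames(g3)))
    expect_equal(sum(libraryType(g3) == "Z"), 50)
})

test_that("feature matrix has 4 columns per position, blocks summing to 100", {
    db <- generateReferenceDB(nPerType = 6, nReads = 500, seed = 2)
    fm <- featureMatrix(db)
    expect_equal(dim(fm), c(30, 200))
    blockSums <- fm %*% kronecker(diag(50), rep(1, 4))
    expect_true(all(abs(blockSums - 100) < 1e-6))
    expect_true(all(abs(rowSums(fm) - 5000) < 1e-6))
})

test_that("a pure-A profile maps to a (100,0,0,0) feature row", {
    cnt <- matrix(0L, 10, 5, dimnames = list(NULL, c("A","C","G","T","N")))
    cnt[, "A"] <- 5L
    p <- CompositionProfile("pureA", cnt, readsSampled = 5L)
    db <- ReferenceDatabase(list(p), "X")
    expect_equal(unname(featureMatrix(db)[1, ]),
                 rep(c(100, 0, 0, 0), 10))
})

test_that("profiles of differing length are rejected", {
    a <- sampleProfile(makeSignature("genomic", L = 10), 100, seed = 1)
    b <- sampleProfile(makeSignature("genomic", L = 12), 100, seed = 2)
    expect_error(ReferenceDatabase(list(a, b), c("X", "X")),
                 "inconsistent position counts")
})

test_that("database files round-trip losslessly", {
    db <- generateReferenceDB(nPerType = 4, nReads = 300, seed = 5)
    f <- tempfile(fileext = ".tsv")
    saveDatabase(db, f)
    back <- loadDatabase(f)
    expect_equal(featureMatrix(back), featureMatrix(db))
    expect_equal(libraryType(back), libraryType(db))
    expect_equal(SummarizedExperiment::colData(back)$reads_sampled,
                 SummarizedExperiment::colData(db)$reads_sampled)
    expect_equal(nrow(utils::read.table(f, header = TRUE, sep = "\t")), 20)

    # filter log survives via the sidecar
    filt <- filterDatabase(db, minPerType = 2, capPerType = 3, seed = 0)
    saveDatabase(filt, f)
    back2 <- loadDatabase(f)
    expect_equal(S4Vectors::metadata(back2)$filter_log$n_after,
                 S4Vectors::metadata(filt)$filter_log$n_after)

    # header mismatch errors
    lines <- readLines(f)
    lines[1] <- sub("library_type", "libtype", lines[1])
    f3 <- tempfile(); writeLines(lines, f3)
    expect_error(loadDatabase(f3), "expected header")
})

test_that("duplicate sample ids warn but are kept", {
    a <- sampleProfile(makeSignature("genomic", L = 10), 100, seed = 1,
                       sampleId = "dup")
    b <- sampleProfile(makeSignature("genomic", L = 10), 100, seed = 2,
                       sampleId = "dup")
    expect_warning(db <- ReferenceDatabase(list(a, b), c("X", "X")),
                   "duplicate sample_id")
    expect_equal(ncol(db), 2)
})
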