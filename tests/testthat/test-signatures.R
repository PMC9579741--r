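test_that("the genomic signature encodes the genome GC content exactly", {
    sig <- makeSignature("genomic", gcPercent = 42)
    expect_equal(dim(sig$baseProbs), c(50, 4))
    # every row is (0.29, 0.21, 0.21, 0.29) for (A, C, G, T) at 42% GC
    expect_true(all(apply(sig$baseProbs, 1, function(r)
        isTRUE(all.equal(unname(r), c(0.29, 0.21, 0.21, 0.29))))))
    expect_equal(unname(rowSums(sig$baseProbs)), rep(1, 50))
})

test_that("signature shapes match their protocol descriptions", {
    bis <- makeSignature("bisulfite", cResidual = 0.02)
    expect_equal(unname(bis$baseProbs[, "C"]), rep(0.02, 50))
    gen <- makeSignature("genomic")
    # the C deficit is read as T
    expect_equal(bis$baseProbs[, "T"],
                 gen$baseProbs[, "T"] + gen$baseProbs[, "C"] - 0.02)

    atac <- makeSignature("atac")
    expect_equal(atac$baseProbs[13:50, ], gen$baseProbs[13:50, ])
    expect_false(isTRUE(all.equal(atac$baseProbs[1, ], gen$baseProbs[1, ])))
    # the start bias decays monotonically
    dev <- apply(abs(atac$baseProbs - gen$baseProbs), 1, max)
    expect_true(all(diff(dev[1:12]) < 1e-12))

    chia <- makeSignature("chiapet")
    expect_equal(chia$baseProbs[c(1:16, 26:50), ],
                 gen$baseProbs[c(1:16, 26:50), ])
    linker <- strsplit("ACGCGATAT", "")[[1]]
    for (i in seq_along(linker))
        expect_gte(chia$baseProbs[16 + i, linker[i]], 0.9)

    rna <- makeSignature("rnaseq")
    expect_equal(rna$baseProbs[11:50, ], gen$baseProbs[11:50, ])
    expect_false(isTRUE(all.equal(rna$baseProbs[1, ], gen$baseProbs[1, ])))

    expect_error(makeSignature("hic"), "valid types.*genomic")
})

test_that("sampled profiles are multinomial around the signature", {
    sig <- makeSignature("genomic", gcPercent = 42)
    p <- sampleProfile(sig, nReads = 100000, seed = 1)
    pct <- toPercentages(p)
    gcPct <- pct[, "C"] + pct[, "G"]
    # binomial SE ~ 0.16% at n = 100,000; 0.5 is > 3 sigma
    expect_true(all(abs(gcPct - 42) < 0.5))

    p1 <- sampleProfile(sig, nReads = 1, seed = 2)
    expect_true(all(rowSums(counts(p1)) == 1))

    expect_identical(counts(sampleProfile(sig, 500, seed = 9)),
                     counts(sampleProfile(sig, 500, seed = 9)))
    expect_error(sampleProfile(sig, 0), "nReads")
})

test_that("generated FASTQ recovers the signature through the extractor", {
    sig <- makeSignature("bisulfite")
    f <- generateFastq(sig, nReads = 1000, readLen = 60,
                       path = tempfile(fileext = ".fastq.gz"), seed = 4)
    prof <- extractProfile(f, seed = 1)
    expect_equal(readsTotal(prof), 1000)
    expect_equal(readsSampled(prof), 1000)
    pct <- toPercentages(prof)
    expect_lt(mean(pct[, "C"]), 5)

    # closure at larger n: observed frequencies within 3-sigma multinomial
    # bounds of the generating probabilities
    gen <- makeSignature("atac")
    f2 <- generateFastq(gen, nReads = 100000, readLen = 50,
                        path = tempfile(fileext = ".fastq"), seed = 6)
    p2 <- extractProfile(f2, reads = 100000, seed = 2)
    obs <- toPercentages(p2) / 100
    expTol <- 3 * sqrt(gen$baseProbs * (1 - gen$baseProbs) / 100000)
    expect_true(all(abs(obs - gen$baseProbs) <= expTol + 1e-3))

    expect_error(generateFastq(sig, 0), "nReads")
})

test_that("types separate far beyond within-type scatter", {
    db <- generateReferenceDB(nPerType = 10, nReads = 50000, seed = 11)
    fm <- featureMatrix(db)
    labs <- libraryType(db)
    d <- as.matrix(dist(fm))
    same <- outer(labs, labs, `==`) & upper.tri(d)
    diff <- outer(labs, labs, `!=`) & upper.tri(d)
    expect_gte(mean(d[diff]) / mean(d[same]), 5)
})

test_that("database generation is reproducible and jitter-controlled", {
    d1 <- generateReferenceDB(nPerType = 3, nReads = 500, seed = 21)
    d2 <- generateReferenceDB(nPerType = 3, nReads = 500, seed = 21)
    expect_identical(featureMatrix(d1), featureMatrix(d2))
    expect_equal(ncol(d1), 15)
    expect_equal(sort(unique(libraryType(d1))),
                 sort(names(defaultSignatureTypes())))

    # jitter off: within-type spread shrinks to pure multinomial noise,
    # several-fold tighter than the jittered default
    dOff <- generateReferenceDB(nPerType = 4, nReads = 50000, seed = 22,
                                jitterConcentration = Inf,
                                types = c(G = "genomic"))
    dOn <- generateReferenceDB(nPerType = 4, nReads = 50000, seed = 22,
                               jitterConcentration = 2000,
                               types = c(G = "genomic"))
    expect_lt(mean(dist(featureMatrix(dOff))) * 3,
              mean(dist(featureMatrix(dOn))))
})
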