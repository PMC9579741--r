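test_that("queries of each signature type recover their own label", {
    fx <- sharedMapFixture()
    types <- defaultSignatureTypes()
    reports <- lapply(names(types), function(lab) {
        prof <- sampleProfile(makeSignature(types[[lab]]), nReads = 20000,
                              seed = 500 + match(lab, names(types)),
                              jitter = 2000)
        predictLibraryType(prof, fx$model, fx$grid)
    })
    top <- vapply(reports, topType, character(1), grid = fx$grid)
    expect_equal(top, names(types))
    for (r in reports)
        expect_equal(sum(as.numeric(as.matrix(r[, fx$grid@typeNames]))), 100)
})

test_that("a single-type map reports 100% for its only type", {
    db <- generateReferenceDB(nPerType = 30, nReads = 5000, seed = 31,
                              types = c(OnlyType = "bisulfite"))
    model <- fitReferenceMap(db, seed = 1)
    grid <- buildGrid(mapCoords(model), mapLabels(model), nx = 6, ny = 6)
    prof <- sampleProfile(makeSignature("bisulfite"), 5000, seed = 99,
                          jitter = 2000)
    rep <- predictLibraryType(prof, model, grid)
    expect_equal(rep$OnlyType, 100)
})

test_that("batches preserve order and factorise over concatenation", {
    fx <- sharedMapFixture()
    profs <- lapply(1:3, function(i)
        sampleProfile(makeSignature("chiapet"), 5000, seed = 700 + i,
                      sampleId = paste0("q", i), jitter = 2000))
    all3 <- predictLibraryType(profs, fx$model, fx$grid)
    expect_equal(all3$sample_id, c("q1", "q2", "q3"))
    oneByOne <- do.call(rbind, lapply(profs, predictLibraryType,
                                      model = fx$model, grid = fx$grid))
    expect_equal(as.data.frame(all3), as.data.frame(oneByOne))
})

test_that("mismatched profiles are skipped with a warning, batch continues", {
    fx <- sharedMapFixture()
    good <- sampleProfile(makeSignature("bisulfite"), 5000, seed = 41,
                          sampleId = "good", jitter = 2000)
    bad <- sampleProfile(makeSignature("genomic", L = 30), 5000, seed = 42,
                         sampleId = "bad30")
    expect_warning(rep <- predictLibraryType(list(bad, good),
                                             fx$model, fx$grid),
                   "bad30 covers 30 positions")
    expect_equal(rep$sample_id, "good")
    expect_error(suppressWarnings(
        predictLibraryType(bad, fx$model, fx$grid)),
        "no profile matches")
})

test_that("fallback to the nearest occupied tile is flagged", {
    fx <- sharedMapFixture()
    # any query must end in an occupied tile, flagged when redirected
    prof <- sampleProfile(makeSignature("rnaseq"), 5000, seed = 55,
                          jitter = 2000)
    rep <- predictLibraryType(prof, fx$model, fx$grid)
    occ <- sum(fx$grid@counts[rep$tile_x, rep$tile_y, ])
    expect_gt(occ, 0)
    expect_type(rep$fallback_used, "logical")
})

test_that("rendering writes figures and a faithful TSV", {
    fx <- sharedMapFixture()
    profs <- lapply(1:2, function(i)
        sampleProfile(makeSignature("atac"), 5000, seed = 60 + i,
                      sampleId = paste0("s", i), jitter = 2000))
    rep <- predictLibraryType(profs, fx$model, fx$grid)
    out <- tempfile("render")
    paths <- renderReport(rep, fx$model, fx$grid, out)
    for (stem in c("reference_map", "tile_probability_maps",
                   "query_heatmap"))
        for (ext in c("svg", "png"))
            expect_true(file.exists(file.path(out, paste0(stem, ".", ext))))
    tsv <- utils::read.table(file.path(out, "report.tsv"), header = TRUE,
                             sep = "\t", check.names = FALSE)
    expect_equal(tsv$sample_id, c("s1", "s2"))
    expect_equal(colnames(tsv),
                 c("sample_id", "x", "y", "tile_x", "tile_y",
                   "fallback_used", fx$grid@typeNames))

    expect_error(renderReport(rep[0, ], fx$model, fx$grid, out),
                 "nothing to render")
})
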