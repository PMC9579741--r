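# a spread of points with a known bounding box; y jittered to avoid a
# degenerate box
spreadCoords <- function(xs, ys = seq(0, 1, length.out = length(xs))) {
    cbind(x = xs, y = ys)
}

test_that("binning is half-open with a closed top edge", {
    co <- spreadCoords(c(0, 10), c(0, 10))
    grid <- buildGrid(co, c("a", "b"), nx = 4, ny = 4, pad = 0)
    # interior edge belongs to the tile on the right
    edge <- grid@xEdges[3]
    expect_equal(tileOf(grid, c(edge, 1))$tile_x, 3)
    # the very top/right edge closes into the last tile
    expect_equal(unlist(tileOf(grid, c(10, 10))), c(tile_x = 4, tile_y = 4))
    # outside the box
    expect_true(is.na(tileOf(grid, c(11, 5))$tile_x))
    expect_true(is.na(tileOf(grid, c(5, -2))$tile_y))
})

test_that("every point is binned exactly once (conservation)", {
    set.seed(8)
    co <- cbind(rnorm(300), rnorm(300))
    labs <- sample(c("u", "v", "w"), 300, replace = TRUE)
    grid <- buildGrid(co, labs, nx = 7, ny = 5)
    expect_equal(sum(grid@counts), 300)
    expect_equal(unname(grid@typeTotals), as.vector(table(labs)))
    # occupied-tile percentages are row-stochastic (x100)
    psum <- apply(grid@percent, c(1, 2), sum)
    occ <- apply(grid@counts, c(1, 2), sum) > 0
    expect_true(all(abs(psum[occ] - 100) < 1e-9))
    expect_true(all(psum[!occ] == 0))
})

test_that("a single-type database fills its occupied tiles at 100%", {
    set.seed(2)
    co <- cbind(runif(40), runif(40))
    grid <- buildGrid(co, rep("only", 40), nx = 6, ny = 6)
    occ <- apply(grid@counts[, , 1, drop = FALSE], c(1, 2), sum) > 0
    expect_true(all(grid@percent[, , 1][occ] == 100))
})

test_that("tile percentages follow the imbalance-normalised formula", {
    # left tile: 10 of X (N_X = 100) and 10 of Y (N_Y = 400)
    # => 100*(10/100) / (10/100 + 10/400) = 80% X, 20% Y
    xs <- c(rep(0, 10), rep(10, 90), rep(0, 10), rep(10, 390))
    ys <- runif(500)
    labs <- c(rep("X", 100), rep("Y", 400))
    grid <- buildGrid(cbind(xs, ys), labs, nx = 2, ny = 1)
    expect_equal(unname(grid@percent[1, 1, "X"]), 80)
    expect_equal(unname(grid@percent[1, 1, "Y"]), 20)
    # raw counts in that tile are 50/50 - the normalisation is the point
    expect_equal(unname(grid@counts[1, 1, "X"]),
                 unname(grid@counts[1, 1, "Y"]))
})

test_that("a single full-map tile with balanced types is uniform", {
    set.seed(3)
    co <- cbind(runif(60), runif(60))
    labs <- rep(c("a", "b", "c"), each = 20)
    grid <- buildGrid(co, labs, nx = 1, ny = 1)
    expect_equal(unname(grid@percent[1, 1, ]), rep(100 / 3, 3))
})

test_that("duplicating every sample of one type leaves percentages unchanged", {
    set.seed(4)
    co <- cbind(runif(90), runif(90))
    labs <- rep(c("p", "q", "r"), each = 30)
    g1 <- buildGrid(co, labs, nx = 5, ny = 5)
    dup <- labs == "q"
    co2 <- rbind(co, co[dup, ])
    labs2 <- c(labs, labs[dup])
    g2 <- buildGrid(co2, labs2, nx = 5, ny = 5)
    expect_equal(g2@percent, g1@percent, tolerance = 1e-12)
})

test_that("degenerate bounding boxes are rejected", {
    co <- cbind(rep(1, 5), 1:5)
    expect_error(buildGrid(co, rep("a", 5), 2, 2), "degenerate")
})

test_that("nearest occupied tile falls back correctly and breaks ties", {
    co <- spreadCoords(c(0, 0.4, 10), c(0, 0.4, 10))
    grid <- buildGrid(co, c("a", "a", "b"), nx = 5, ny = 5, pad = 0)
    # a query inside an occupied tile resolves to itself
    self <- nearestOccupiedTile(grid, c(0.2, 0.2))
    expect_equal(unname(self), c(1, 1))
    # an empty-tile query snaps to the closest occupied tile
    near <- nearestOccupiedTile(grid, c(9.9, 7.5))
    expect_equal(unname(near), c(5, 5))

    # exact equidistance resolves to the lower row-major index
    co2 <- cbind(c(0, 3), c(0, 2))
    g2 <- buildGrid(co2, c("a", "b"), nx = 3, ny = 1, pad = 0)
    # middle tile centre (1.5) is exactly equidistant from the occupied
    # tile centres at 0.5 and 2.5
    expect_equal(unname(nearestOccupiedTile(g2, c(1.5, 1))), c(1, 1))
})

test_that("the self-consistency matrix is row-stochastic and diagonal for
           separated types, uniform for co-located ones", {
    # perfectly separated clusters
    co <- rbind(cbind(runif(20), runif(20)),
                cbind(runif(20) + 5, runif(20) + 5))
    labs <- rep(c("left", "right"), each = 20)
    grid <- buildGrid(co, labs, nx = 4, ny = 4)
    cm <- tileConfusionMatrix(grid, co, labs)
    expect_equal(unname(diag(cm)), c(100, 100))
    expect_true(all(abs(rowSums(cm) - 100) < 1e-9))

    # two types fully co-located, equal N -> all entries 50
    co2 <- rbind(cbind(runif(20), runif(20)),
                 cbind(runif(20), runif(20)))
    labs2 <- rep(c("m", "n"), each = 20)
    g2 <- buildGrid(co2, labs2, nx = 1, ny = 1)
    cm2 <- tileConfusionMatrix(g2, co2, labs2)
    expect_equal(unname(cm2), matrix(50, 2, 2))
})

test_that("grids round-trip through their tabular export", {
    fx <- sharedMapFixture()
    f <- tempfile(fileext = ".tsv")
    saveGrid(fx$grid, f)
    back <- loadGrid(f)
    expect_equal(back@counts, fx$grid@counts)
    expect_equal(back@percent, fx$grid@percent)
    expect_equal(back@xEdges, fx$grid@xEdges)
    expect_equal(back@typeTotals, fx$grid@typeTotals)
})
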