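test_that("a single planted pair at score 100 tops out both sides", {
    ds <- generateDataset(SyntheticSpec(plantedScores = 100, seed = 8L))
    res <- runPipeline(ds$db, ds$deg, ds$sender, ds$receiver)
    act <- activePairs(res)
    expect_identical(nrow(act), 1L)
    expect_equal(act$ligandLevel, 10, tolerance = 1e-9)
    expect_equal(act$receptorLevel, 10, tolerance = 1e-9)
    expect_equal(act$score, 100, tolerance = 1e-8)
})

test_that("planted pairs are recovered in order with matching scores", {
    spec <- SyntheticSpec(plantedScores = c(80, 60, 40, 20, 5), seed = 19L)
    ds <- generateDataset(spec)
    res <- runPipeline(ds$db, ds$deg, ds$sender, ds$receiver)
    act <- activePairs(res)
    expect_identical(act$pair_id, ds$truth$pair_id)
    expect_identical(act$rank, ds$truth$rank)
    expect_lt(max(abs(act$score - ds$truth$score)), 1e-6)
    # multichain planted pairs have equal-chain complexes by construction
    expect_identical(sum(ds$truth$multichain), 2L)
})

test_that("without planted pairs the background never leaks active pairs", {
    for (s in 1:100) {
        ds <- generateDataset(SyntheticSpec(nBackgroundGenes = 40L,
                                            plantedScores = numeric(),
                                            seed = s))
        res <- runPipeline(ds$db, ds$deg, ds$sender, ds$receiver)
        expect_identical(nrow(activePairs(res)), 0L)
    }
})

test_that("the same spec and seed write byte-identical files", {
    spec <- SyntheticSpec(seed = 23L)
    d1 <- file.path(tempdir(), "synth-a")
    d2 <- file.path(tempdir(), "synth-b")
    p1 <- writeDataset(generateDataset(spec), d1)
    p2 <- writeDataset(generateDataset(spec), d2)
    for (f in names(p1))
        expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
})

test_that("generated files survive the real I/O path unchanged", {
    ds <- generateDataset(SyntheticSpec(seed = 29L))
    dir <- file.path(tempdir(), "synth-io")
    paths <- writeDataset(ds, dir)
    res <- runPipeline(readLRDatabase(paths[["db"]]),
                       readDEGTable(paths[["deg"]]),
                       readExpression(paths[["sender"]]),
                       readExpression(paths[["receiver"]]))
    act <- activePairs(res)
    expect_identical(act$pair_id, ds$truth$pair_id)
    expect_lt(max(abs(act$score - ds$truth$score)), 1e-6)
})

test_that("spec validation rejects impossible planted scores", {
    expect_error(SyntheticSpec(plantedScores = c(60, 80)), "decreasing")
    expect_error(SyntheticSpec(plantedScores = c(80, -2)), "positive")
    expect_error(generateDataset(SyntheticSpec(plantedScores = 150)),
                 "ceiling")
})

test_that("the boundary fixture exercises every strict inequality", {
    fx <- generateBoundaryFixture()
    res <- runPipeline(fx$db, fx$deg, fx$sender, fx$receiver)
    got <- as.data.frame(scoredPairs(res))[c("pair_id", "active")]
    cmp <- merge(got, fx$expected, by = "pair_id")
    expect_identical(cmp$active.x, cmp$active.y)
})
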