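cfg <- ScoringConfig()

test_that("ligand selection applies both DEG cuts strictly", {
    deg <- DEGTable(c("A", "B", "C"),
                    log2fc = c(1.5, 0.9, 2.0),
                    fdr = c(0.005, 0.001, 0.02))
    expect_identical(selectSenderLigandGenes(deg, cfg), "A")
    # exact boundaries are excluded; downregulation never qualifies
    edge <- DEGTable(c("FC", "FDR", "DOWN"),
                     log2fc = c(1.0, 3, -3),
                     fdr = c(1e-9, 0.01, 1e-9))
    expect_identical(selectSenderLigandGenes(edge, cfg), character(0))
    expect_identical(selectSenderLigandGenes(DEGTable(), cfg), character(0))
})

test_that("expression thresholding is strict and restriction-aware", {
    p <- ExpressionProfile(c(A = 5.0, B = 1.0, C = 0.2))
    expect_identical(exprValues(thresholdExpression(p, c("A", "B", "C"), cfg)),
                     c(A = 5.0))
    p2 <- ExpressionProfile(c(A = 5, Z = 100))
    expect_identical(exprValues(thresholdExpression(p2, "A", cfg)),
                     c(A = 5))
    low <- ExpressionProfile(c(A = 0.5, B = 1.0))
    expect_length(thresholdExpression(low, c("A", "B"), cfg), 0L)
})

test_that("scale maximum is the mean of the top decile", {
    expect_identical(computeScaleMax(c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1)), 10)
    expect_identical(computeScaleMax(rep(5, 20)), 5)
    # brute-force oracle on the explicit 1..100 list
    vals <- as.numeric(1:100)
    brute <- mean(rev(sort(vals))[1:ceiling(0.1 * 100)])
    expect_identical(brute, 95.5)
    expect_identical(computeScaleMax(vals), 95.5)
    expect_error(computeScaleMax(numeric()), "empty")
    expect_error(computeScaleMax(c(1, 0)), "positive")
})

test_that("scaling divides by the scale max, multiplies by 10 and clips", {
    p <- ExpressionProfile(c(ATMAX = 95.5, OUTLIER = 191, LOW = 4.775))
    sc <- exprValues(scaleExpression(p, 95.5, cfg))
    expect_identical(sc[["ATMAX"]], 10)
    expect_identical(sc[["OUTLIER"]], 10)  # 20 coerced to the ceiling
    expect_identical(sc[["LOW"]], 0.5)
})

test_that("complex level is the geometric mean of chain values", {
    expect_identical(complexLevel(4.0), 4.0)
    expect_identical(complexLevel(c(4.0, 9.0)), 6.0)
    expect_equal(complexLevel(c(2.0, 4.0, 8.0)), 4.0)
    expect_error(complexLevel(numeric()), "chain")
})

test_that("pair scores are products; any missing subunit zeroes a side", {
    db <- LRDatabase(c("P1", "P2", "P3"),
                     ligand = list("L1", "L2", c("L3A", "L3B")),
                     receptor = list("R1", "R2", "R3"))
    sender <- ExpressionProfile(c(L1 = 5, L2 = 3, L3A = 4, L3B = 9))
    receiver <- ExpressionProfile(c(R1 = 4, R3 = 2))  # R2 removed upstream
    sc <- scorePairs(db, sender, receiver, cfg)
    expect_identical(sc$score[sc$pair_id == "P1"], 20)
    expect_identical(sc$score[sc$pair_id == "P2"], 0)
    expect_false(sc$active[sc$pair_id == "P2"])
    # 2-chain ligand: geometric mean then product, checked by brute force
    expect_identical(sc$ligandLevel[sc$pair_id == "P3"], (4 * 9)^(1 / 2))
    expect_identical(sc$score[sc$pair_id == "P3"], (4 * 9)^(1 / 2) * 2)
})

test_that("ranking is score-descending with deterministic id tie-break", {
    scored <- S4Vectors::DataFrame(
        pair_id = c("P1", "P2", "P3"),
        ligand = "L", receptor = "R",
        ligandLevel = 1, receptorLevel = 1,
        score = c(12, 20, 0), active = c(TRUE, TRUE, FALSE))
    rk <- rankPairs(scored, topK = 30L)
    expect_identical(rk$pair_id, c("P2", "P1", "P3"))
    expect_identical(rk$rank, c(1L, 2L, NA_integer_))
    tie <- scored
    tie$score <- c(5, 5, 0)
    expect_identical(rankPairs(tie, 30L)$pair_id[1:2], c("P1", "P2"))
})

test_that("levels and scores respect their bounds on random instances", {
    for (s in 301:320) {
        inst <- randomInstance(s)
        sc <- scoredPairs(runPipeline(inst$db, inst$deg, inst$sender,
                                      inst$receiver))
        expect_true(all(sc$ligandLevel >= 0 & sc$ligandLevel <= 10))
        expect_true(all(sc$receptorLevel >= 0 & sc$receptorLevel <= 10))
        expect_true(all(sc$score >= 0 & sc$score <= 100))
        expect_identical(sc$active, sc$score > 0)
        expect_identical(sc$score,
                         sc$ligandLevel * sc$receptorLevel)
    }
})

test_that("geometric mean commutes with scaling when no chain clips", {
    set.seed(55)
    for (rep in 1:20) {
        n <- sample(2:4, 1L)
        raw <- stats::rlnorm(n, 1, 0.5)
        m <- max(raw) * (1 + stats::runif(1, 0.1, 2))  # no clipping
        scaled <- pmin(10 * raw / m, 10)
        expect_equal(complexLevel(scaled),
                     min(10 * complexLevel(raw) / m, 10),
                     tolerance = 1e-12)
    }
})

test_that("raising a non-top ligand value only helps its own pair", {
    genes <- sprintf("L%02d", 1:15)
    vals <- setNames(seq(20, 160, by = 10), genes)
    vals[["L01"]] <- 5
    db <- LRDatabase(paste0("P", 1:15), as.list(genes),
                     as.list(sprintf("R%02d", 1:15)))
    deg <- DEGTable(genes, log2fc = rep(3, 15), fdr = rep(1e-6, 15))
    recv <- ExpressionProfile(setNames(rep(50, 15), sprintf("R%02d", 1:15)))
    base <- scoredPairs(runPipeline(db, deg, ExpressionProfile(vals), recv))
    bumped <- vals
    bumped[["L01"]] <- 8  # still far below the top-decile set
    after <- scoredPairs(runPipeline(db, deg, ExpressionProfile(bumped), recv))
    base <- base[order(base$pair_id), ]
    after <- after[order(after$pair_id), ]
    expect_gt(after$score[after$pair_id == "P1"],
              base$score[base$pair_id == "P1"])
    others <- base$pair_id != "P1"
    expect_identical(after$score[others], base$score[others])
})

test_that("scale invariance holds exactly for dyadic factors and to 1e-12
           otherwise, once threshold survivors are fixed", {
    # sender values chosen outside (1/137.5, 137.5*1] so the FPKM > 1
    # survivor set is identical for every factor tested
    set.seed(77)
    genes <- sprintf("L%02d", 1:20)
    v <- setNames(stats::runif(20, 150, 5000), genes)
    v[c(3, 11)] <- 0
    db <- LRDatabase(paste0("P", 1:20), as.list(genes),
                     as.list(sprintf("R%02d", 1:20)))
    deg <- DEGTable(genes, log2fc = rep(3, 20), fdr = rep(1e-5, 20))
    recv <- ExpressionProfile(setNames(stats::runif(20, 2, 800),
                                       sprintf("R%02d", 1:20)))
    s0 <- scoredPairs(runPipeline(db, deg, ExpressionProfile(v), recv))$score
    for (c0 in c(2^9, 2^-7)) {  # exact binary multiplication
        s2 <- scoredPairs(runPipeline(db, deg, ExpressionProfile(c0 * v),
                                      recv))$score
        expect_identical(s2, s0)
    }
    for (c0 in c(0.01, 137.5, 3.7)) {
        s2 <- scoredPairs(runPipeline(db, deg, ExpressionProfile(c0 * v),
                                      recv))$score
        expect_equal(s2, s0, tolerance = 1e-12)
    }
})

test_that("identical inputs give byte-identical results across runs", {
    inst <- randomInstance(404)
    r1 <- runPipeline(inst$db, inst$deg, inst$sender, inst$receiver)
    r2 <- runPipeline(inst$db, inst$deg, inst$sender, inst$receiver)
    expect_identical(as.data.frame(scoredPairs(r1)),
                     as.data.frame(scoredPairs(r2)))
    expect_identical(provenance(r1), provenance(r2))
})
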