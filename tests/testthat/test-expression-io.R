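writeExprFile <- function(lines) {
    tf <- tempfile(fileext = ".tsv")
    writeLines(lines, tf)
    tf
}

test_that("replicate columns are averaged per gene", {
    tf <- writeExprFile(c("gene\trep1\trep2", "G\t4.0\t6.0"))
    expect_identical(exprValues(readExpression(tf)), c(G = 5))
    # against a brute-force mean over random replicate matrices
    set.seed(21)
    for (rep in 1:5) {
        n <- sample(3:20, 1L)
        k <- sample(2:4, 1L)
        m <- matrix(stats::rlnorm(n * k), n, k)
        genes <- sprintf("G%02d", seq_len(n))
        lines <- c(paste(c("gene", paste0("r", seq_len(k))), collapse = "\t"),
                   vapply(seq_len(n), function(i)
                       paste(c(genes[i], sprintf("%.17g", m[i, ])),
                             collapse = "\t"), ""))
        got <- exprValues(readExpression(writeExprFile(lines)))
        want <- vapply(seq_len(n), function(i) mean(m[i, ]), 0)
        expect_equal(unname(got), want, tolerance = 1e-15)
    }
})

test_that("zeros are kept at ingest; filtering is a later stage", {
    tf <- writeExprFile(c("gene\tfpkm", "G\t0"))
    expect_identical(exprValues(readExpression(tf)), c(G = 0))
})

test_that("duplicated gene rows collapse to their mean with a warning", {
    tf <- writeExprFile(c("gene\tfpkm", "G\t2", "G\t4", "H\t7"))
    expect_warning(p <- readExpression(tf), "G")
    expect_identical(exprValues(p), c(G = 3, H = 7))
})

test_that("negative or non-numeric expression is rejected with row context", {
    tf <- writeExprFile(c("gene\tfpkm", "A\t1", "B\t-2"))
    expect_error(readExpression(tf), "row.* 2")
})

test_that("expression round trip is exact to full double precision", {
    set.seed(31)
    v <- setNames(stats::rlnorm(40, 2, 2), sprintf("G%02d", 1:40))
    p <- ExpressionProfile(v, "cond")
    tf <- tempfile(fileext = ".tsv")
    writeExpression(p, tf)
    back <- readExpression(tf, valueColumns = "fpkm", conditionLabel = "cond")
    expect_identical(exprValues(back), exprValues(p))
})

test_that("DEG rows are stored unfiltered and validated", {
    tf <- writeExprFile(c("gene\tlog2fc\tfdr",
                          "TNFSF4\t3.2\t1e-06",
                          "GENE1\t-2.0\t0.5"))
    deg <- readDEGTable(tf)
    s <- degStats(deg)
    expect_identical(s$gene, c("TNFSF4", "GENE1"))
    expect_identical(s$log2fc, c(3.2, -2.0))
    expect_identical(s$fdr, c(1e-06, 0.5))
    bad <- writeExprFile(c("gene\tlog2fc\tfdr", "A\t1\t1.5"))
    expect_error(readDEGTable(bad), "fdr")
})

test_that("DEG round trip is exact to full double precision", {
    set.seed(41)
    deg <- DEGTable(sprintf("G%02d", 1:25),
                    log2fc = stats::rnorm(25, 0, 3),
                    fdr = stats::runif(25))
    tf <- tempfile(fileext = ".tsv")
    writeDEGTable(deg, tf)
    back <- readDEGTable(tf)
    expect_identical(as.data.frame(degStats(back)),
                     as.data.frame(degStats(deg)))
})
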