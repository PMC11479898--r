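# Fixture builders shared across test files. Everything is generated in
# code; no data files are shipped.

# A random small scoring instance in both plain (oracle) and package form.
# Gene symbols may appear on both sides; zeros, sub-threshold values and
# DEG failures are all represented.
randomInstance <- function(seed) {
    set.seed(seed)
    nG <- sample(4:30, 1L)
    genes <- sprintf("G%02d", seq_len(nG))
    nP <- sample(1:15, 1L)
    pairs <- lapply(seq_len(nP), function(j) {
        list(id = sprintf("P%02d", j),
             lig = sample(genes, sample(1:3, 1L, prob = c(.6, .3, .1))),
             rec = sample(genes, sample(1:3, 1L, prob = c(.6, .3, .1))))
    })
    rndExpr <- function() {
        v <- stats::rlnorm(nG, 1.5, 1.5)
        v[stats::runif(nG) < 0.15] <- 0
        setNames(v, genes)
    }
    sender <- rndExpr()
    receiver <- rndExpr()
    deg <- data.frame(gene = genes,
                      log2fc = stats::rnorm(nG, 1, 1.5),
                      fdr = stats::runif(nG)^3,
                      stringsAsFactors = FALSE)
    list(
        plain = list(pairs = pairs, deg = deg, sender = sender,
                     receiver = receiver),
        db = LRDatabase(pairId = vapply(pairs, `[[`, "", "id"),
                        ligand = lapply(pairs, `[[`, "lig"),
                        receptor = lapply(pairs, `[[`, "rec")),
        deg = DEGTable(deg$gene, deg$log2fc, deg$fdr),
        sender = ExpressionProfile(sender, "random sender"),
        receiver = ExpressionProfile(receiver, "random receiver"))
}

# Pipeline scores aligned to the oracle's pair order.
pipelineScoresById <- function(res, ids) {
    sc <- scoredPairs(res)
    unname(sc$score[match(ids, sc$pair_id)])
}

# Hand-computed worked example (see test-pipeline.R for the arithmetic).
workedToyFixture <- function() {
    list(
        db = LRDatabase(
            pairId = c("P1", "P2", "P3", "P4"),
            ligand = list("L1", c("L2A", "L2B"), "L3", "L4"),
            receptor = list("R1", "R2", c("R3A", "R3B"), "R4")),
        deg = DEGTable(
            gene = c("L1", "L2A", "L2B", "L3", "L4"),
            log2fc = c(3, 2, 4, 1.5, 0.5),
            fdr = c(1e-4, 1e-3, 1e-5, 0.005, 1e-6)),
        sender = ExpressionProfile(
            c(L1 = 40, L2A = 10, L2B = 16, L3 = 2, L4 = 100),
            "toy sender"),
        receiver = ExpressionProfile(
            c(R1 = 5, R2 = 20, R3A = 8, R3B = 0.9, R4 = 50),
            "toy receiver"))
}
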