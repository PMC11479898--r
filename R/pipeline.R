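#' Run the full communication-scoring pipeline
#'
#' Executes the complete sender-to-receiver ligand-receptor scoring
#' procedure:
#' 1. select candidate ligand genes from the sender DEG table (FDR <
#'    `fdrMax`, log2FC > `log2fcMin`, both strict);
#' 2. restrict the sender profile to selected genes that appear among the
#'    database's ligand subunits, and threshold at FPKM > `fpkmMin`;
#' 3. restrict the receiver profile to the database's receptor subunits
#'    and threshold likewise;
#' 4. compute a separate scale maximum for each side as the mean of the
#'    top `topFraction` of the surviving values;
#' 5. scale each side by its own maximum, multiply by `scaleFactor`, and
#'    clip values above `ceiling` down to the ceiling;
#' 6. aggregate multichain complexes by geometric mean of their (clipped)
#'    chain values;
#' 7. score each pair as S = L * R;
#' 8. call pairs with S > 0 active;
#' 9. rank active pairs by descending score (ties by pair id).
#'
#' The scale maximum of a side is computed over exactly the values that
#' are subsequently scaled (the database-restricted, DEG-selected where
#' applicable, thresholded genes), so unclipped scaled values genuinely
#' span (0, ceiling].
#'
#' @param db an [LRDatabase].
#' @param deg the sender [DEGTable] (stimulated vs resting contrast).
#' @param senderExpr sender [ExpressionProfile] (stimulated condition,
#'   FPKM).
#' @param receiverExpr receiver [ExpressionProfile] (FPKM).
#' @param config a [ScoringConfig].
#'
#' @return A [CommunicationResult]. When no ligand or no receptor survives
#'   selection and thresholding the result carries zero active pairs (all
#'   scores 0) rather than raising an error; `provenance(x)$note` records
#'   which side was empty.
#'
#' @examples
#' db <- LRDatabase(c("P1", "P2"),
#'                  ligand = list("L1", c("L2A", "L2B")),
#'                  receptor = list("R1", "R2"))
#' deg <- DEGTable(c("L1", "L2A", "L2B"), log2fc = c(3, 2, 4),
#'                 fdr = c(1e-4, 1e-3, 1e-5))
#' sender <- ExpressionProfile(c(L1 = 40, L2A = 10, L2B = 16))
#' receiver <- ExpressionProfile(c(R1 = 5, R2 = 20))
#' res <- runPipeline(db, deg, sender, receiver)
#' activePairs(res)
#' @export
runPipeline <- function(db, deg, senderExpr, receiverExpr,
                        config = ScoringConfig()) {
    ligUniverse <- unique(unlist(db@pairs$ligand, use.names = FALSE))
    recUniverse <- unique(unlist(db@pairs$receptor, use.names = FALSE))

    selected <- selectSenderLigandGenes(deg, config)
    senderThr <- thresholdExpression(senderExpr,
                                     intersect(selected, ligUniverse), config)
    receiverThr <- thresholdExpression(receiverExpr, recUniverse, config)

    note <- character()
    if (length(senderThr) == 0L) note <- c(note, "no expressed ligands")
    if (length(receiverThr) == 0L) note <- c(note, "no expressed receptors")

    if (length(note)) {
        senderScaled <- ExpressionProfile(numeric(),
                                          conditionLabel(senderExpr))
        receiverScaled <- ExpressionProfile(numeric(),
                                            conditionLabel(receiverExpr))
        scaleMaxLig <- NA_real_
        scaleMaxRec <- NA_real_
    } else {
        scaleMaxLig <- computeScaleMax(exprValues(senderThr),
                                       config@topFraction)
        scaleMaxRec <- computeScaleMax(exprValues(receiverThr),
                                       config@topFraction)
        senderScaled <- scaleExpression(senderThr, scaleMaxLig, config)
        receiverScaled <- scaleExpression(receiverThr, scaleMaxRec, config)
    }

    scored <- rankPairs(scorePairs(db, senderScaled, receiverScaled, config),
                        config@topK)

    prov <- list(
        config = list(fpkmMin = config@fpkmMin, fdrMax = config@fdrMax,
                      log2fcMin = config@log2fcMin, ceiling = config@ceiling,
                      scaleFactor = config@scaleFactor,
                      topFraction = config@topFraction,
                      topK = config@topK),
        senderCondition = conditionLabel(senderExpr),
        receiverCondition = conditionLabel(receiverExpr),
        counts = list(
            nPairs = length(db),
            nDEGSelected = length(selected),
            nLigandUniverse = length(ligUniverse),
            nReceptorUniverse = length(recUniverse),
            nLigandGenesKept = length(senderThr),
            nReceptorGenesKept = length(receiverThr),
            nActive = sum(scored$active)),
        scaleMax = list(ligand = scaleMaxLig, receptor = scaleMaxRec),
        inputDigests = list(
            db = .contentDigest(as.list(db@pairs)),
            deg = .contentDigest(as.list(degStats(deg))),
            sender = .contentDigest(exprValues(senderExpr)),
            receiver = .contentDigest(exprValues(receiverExpr))),
        note = if (length(note)) paste(note, collapse = "; ") else NULL)

    new("CommunicationResult", scores = scored, senderScaled = senderScaled,
        receiverScaled = receiverScaled, config = config,
        provenance = prov)
}

#' Write pipeline outputs to a directory
#'
#' Writes `scored_pairs.tsv` (all pairs, levels and scores rounded to 4
#' decimals for readability), `active_pairs.tsv` (the active subset),
#' `scored_pairs.json` (full double precision, machine-readable) and
#' `provenance.json` (configuration echo, per-stage counts, scale maxima,
#' input digests).
#'
#' @param result a [CommunicationResult].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeResult <- function(result, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    sc <- as.data.frame(scoredPairs(result))
    rounded <- sc
    for (col in c("ligandLevel", "receptorLevel", "score"))
        rounded[[col]] <- round(rounded[[col]], 4)
    paths <- c(
        scored = file.path(dir, "scored_pairs.tsv"),
        active = file.path(dir, "active_pairs.tsv"),
        full = file.path(dir, "scored_pairs.json"),
        prov = file.path(dir, "provenance.json"))
    utils::write.table(rounded, paths["scored"], sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    utils::write.table(rounded[rounded$active, , drop = FALSE],
                       paths["active"], sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    jsonlite::write_json(sc, paths["full"], digits = I(17), auto_unbox = TRUE,
                         na = "null")
    jsonlite::write_json(provenance(result), paths["prov"], digits = I(17),
                         auto_unbox = TRUE, na = "null")
    invisible(paths)
}
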