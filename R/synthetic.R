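# Synthetic benchmark data with planted active pairs.
#
# The generator inverts the scaling transform: given the background values
# that will share a side's scale maximum, it solves for the raw FPKM of
# each planted subunit so that its post-pipeline scaled value hits the
# intended target. Because planted values themselves can enter the
# top-decile set, the solve iterates to a fixed point.

# Solve raw FPKMs so that scaleFactor * raw / scaleMax(background + raw)
# equals targetScaled for every planted subunit.
.solvePlantedRaw <- function(background, targetScaled, config,
                             tol = 1e-9, maxIter = 500L) {
    if (!length(targetScaled))
        return(numeric(0))
    m0 <- if (length(background)) {
        computeScaleMax(background, config@topFraction)
    } else 1
    raw <- targetScaled * m0 / config@scaleFactor
    for (i in seq_len(maxIter)) {
        m <- computeScaleMax(c(background, raw), config@topFraction)
        rawNew <- targetScaled * m / config@scaleFactor
        if (max(abs(rawNew - raw) / pmax(raw, .Machine$double.eps)) < 1e-14) {
            raw <- rawNew
            break
        }
        raw <- rawNew
    }
    m <- computeScaleMax(c(background, raw), config@topFraction)
    achieved <- pmin(config@scaleFactor * raw / m, config@ceiling)
    if (max(abs(achieved - targetScaled)) > tol)
        return(NULL)  # caller retries with a rescaled background
    if (any(raw <= config@fpkmMin))
        return(NULL)  # planted gene would be removed by thresholding
    raw
}

#' Generate a synthetic dataset with planted active pairs
#'
#' Builds a ligand-receptor database, a sender DEG table, and sender and
#' receiver expression profiles such that running [runPipeline()] on them
#' recovers exactly the planted pairs as active, in the planted score
#' order, with scores matching `plantedScores` to high precision
#' (typically ~1e-12; guaranteed within 1e-9).
#'
#' The generated universe contains, per side, `nBackgroundGenes` decoy
#' genes with log-normal FPKM that shape the side's top-decile scale
#' maximum but can never form an active pair: decoy ligands pass the DEG
#' cuts yet pair with receptors expressed below the FPKM threshold, decoy
#' receptors pair with ligands that fail the DEG cuts. Additional noise
#' genes outside the database exercise the symbol-matching path. Planted
#' pairs get ligand and receptor levels equal to `sqrt(plantedScores)`;
#' multichain planted pairs use two chains with equal subunit expression,
#' so the geometric mean leaves the level unchanged.
#'
#' @param spec a [SyntheticSpec].
#' @param config the [ScoringConfig] the dataset is calibrated against.
#'
#' @return A list with elements `db` ([LRDatabase]), `deg` ([DEGTable]),
#'   `sender` and `receiver` ([ExpressionProfile]), and `truth`
#'   (a [S4Vectors::DataFrame] of pair_id, intended score, intended rank,
#'   multichain flag).
#'
#' @details The solve-for-raw-FPKM step can fail when a planted value
#'   would perturb the top-decile set so strongly that no fixed point
#'   within tolerance exists, or when a planted raw value would fall below
#'   the expression threshold; the generator then rescales the background
#'   upward and retries a bounded number of times before failing loudly.
#'   Planted scores must not exceed `ceiling^2` (score 100 with defaults:
#'   the planted genes become their side's top genes with L = R = 10).
#'
#' @examples
#' ds <- generateDataset(SyntheticSpec(plantedScores = c(80, 20), seed = 3L))
#' res <- runPipeline(ds$db, ds$deg, ds$sender, ds$receiver)
#' activePairs(res)$pair_id  # the two planted pairs, best first
#' @seealso [generateBoundaryFixture()], [runPipeline()]
#' @export
generateDataset <- function(spec = SyntheticSpec(),
                            config = ScoringConfig()) {
    stopifnot(is(spec, "SyntheticSpec"), is(config, "ScoringConfig"))
    if (any(spec@plantedScores > config@ceiling^2))
        stop("plantedScores must lie in (0, ceiling^2]", call. = FALSE)
    set.seed(spec@seed)
    nB <- spec@nBackgroundGenes
    scores <- spec@plantedScores
    nP <- length(scores)
    nMulti <- round(spec@multichainFraction * nP)
    multichain <- seq_len(nP) <= nMulti

    idx2 <- function(n) sprintf("%03d", seq_len(n))
    bgl <- paste0("BGL", idx2(nB))   # decoy ligands (DEG-pass, dead partner)
    drx <- paste0("DRX", idx2(nB))   # dead receptors (FPKM <= threshold)
    bgr <- paste0("BGR", idx2(nB))   # decoy receptors
    dlx <- paste0("DLX", idx2(nB))   # dead ligands (fail DEG cuts)
    nN <- ceiling(nB / 2)
    nse <- paste0("NSE", idx2(nN))   # noise genes outside the database

    bglExpr <- stats::rlnorm(nB, spec@exprMeanlog, spec@exprSdlog)
    bgrExpr <- stats::rlnorm(nB, spec@exprMeanlog, spec@exprSdlog)
    dlxExpr <- stats::rlnorm(nB, spec@exprMeanlog, spec@exprSdlog)
    drxExpr <- stats::runif(nB, 0, config@fpkmMin)
    nseSend <- stats::rlnorm(nN, spec@exprMeanlog, spec@exprSdlog)
    nseRecv <- stats::rlnorm(nN, spec@exprMeanlog, spec@exprSdlog)

    # planted gene symbols; chain counts per pair
    ligSub <- lapply(seq_len(nP), function(j)
        if (multichain[j]) sprintf("PLG%02d%s", j, c("A", "B"))
        else sprintf("PLG%02d", j))
    recSub <- lapply(seq_len(nP), function(j)
        if (multichain[j]) sprintf("PRC%02d%s", j, c("A", "B"))
        else sprintf("PRC%02d", j))
    target <- sqrt(scores)           # per-subunit scaled target, both sides
    ligTargets <- rep(target, times = lengths(ligSub))
    recTargets <- rep(target, times = lengths(recSub))

    solveSide <- function(bgValues, targets) {
        bg <- bgValues
        for (attempt in seq_len(8L)) {
            keep <- bg[bg > config@fpkmMin]
            raw <- .solvePlantedRaw(keep, targets, config)
            if (!is.null(raw)) return(list(bg = bg, raw = raw))
            bg <- bg * 2
        }
        stop("could not invert the scaling transform for the requested ",
             "planted scores; background repeatedly perturbed the ",
             "top-decile maximum", call. = FALSE)
    }
    lig <- solveSide(bglExpr, ligTargets)
    rec <- solveSide(bgrExpr, recTargets)
    bglExpr <- lig$bg
    bgrExpr <- rec$bg

    sender <- ExpressionProfile(
        setNames(c(lig$raw, bglExpr, dlxExpr, nseSend),
                 c(unlist(ligSub), bgl, dlx, nse)),
        conditionLabel = "synthetic sender (stimulated)")
    receiver <- ExpressionProfile(
        setNames(c(rec$raw, bgrExpr, drxExpr, nseRecv),
                 c(unlist(recSub), bgr, drx, nse)),
        conditionLabel = "synthetic receiver (activated)")

    degGenes <- c(unlist(ligSub), bgl, dlx, nse)
    nLigSub <- length(unlist(ligSub))
    deg <- DEGTable(
        gene = degGenes,
        log2fc = c(rep(spec@degLog2fc, nLigSub + nB),   # planted + decoys pass
                   rep(0, nB),                          # dead ligands fail FC
                   stats::rnorm(nN, 0, 0.3)),           # noise fails FC
        fdr = c(rep(spec@degFdr, nLigSub + nB),
                stats::runif(nB, 0.5, 1),
                stats::runif(nN, 0.5, 1)))

    db <- LRDatabase(
        pairId = c(sprintf("PLT%02d", seq_len(nP)),
                   paste0("DCL", idx2(nB)), paste0("DCR", idx2(nB))),
        ligand = c(ligSub, as.list(bgl), as.list(dlx)),
        receptor = c(recSub, as.list(drx), as.list(bgr)),
        family = c(rep("planted", nP), rep("decoy-ligand", nB),
                   rep("decoy-receptor", nB)),
        sourceTag = sprintf("synthetic (seed %d)", spec@seed))

    truth <- DataFrame(
        pair_id = sprintf("PLT%02d", seq_len(nP)),
        score = scores,
        rank = seq_len(nP),
        multichain = multichain)

    list(db = db, deg = deg, sender = sender, receiver = receiver,
         truth = truth)
}

#' Write a generated dataset through the package's standard writers
#'
#' Emits `lr_database.tsv`, `deg.tsv`, `sender_expr.tsv`,
#' `receiver_expr.tsv` and `truth.tsv` into a directory, using the same
#' writers and full-precision formats as real data, so generated fixtures
#' exercise the genuine I/O path.
#'
#' @param dataset the list returned by [generateDataset()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeDataset <- function(dataset, dir) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(db = file.path(dir, "lr_database.tsv"),
               deg = file.path(dir, "deg.tsv"),
               sender = file.path(dir, "sender_expr.tsv"),
               receiver = file.path(dir, "receiver_expr.tsv"),
               truth = file.path(dir, "truth.tsv"))
    writeLRDatabase(dataset$db, paths["db"])
    writeDEGTable(dataset$deg, paths["deg"])
    writeExpression(dataset$sender, paths["sender"])
    writeExpression(dataset$receiver, paths["receiver"])
    tr <- as.data.frame(dataset$truth)
    tr$score <- .fmtFull(tr$score)
    utils::write.table(tr, paths["truth"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(paths)
}

#' Deterministic fixture probing every strict threshold boundary
#'
#' Builds a small dataset containing genes at exactly FPKM = `fpkmMin`,
#' FDR = `fdrMax` and log2FC = `log2fcMin` (all of which the strict cuts
#' must exclude) and genes just above each boundary (all of which must be
#' included). Each boundary gene is paired with a well-expressed anchor
#' partner so that inclusion of the boundary gene is equivalent to its
#' pair being active.
#'
#' @param config a [ScoringConfig].
#' @return A list with `db`, `deg`, `sender`, `receiver` as in
#'   [generateDataset()], plus `expected`: a data.frame of pair_id and the
#'   activity the thresholds dictate.
#' @examples
#' fx <- generateBoundaryFixture()
#' res <- runPipeline(fx$db, fx$deg, fx$sender, fx$receiver)
#' merge(as.data.frame(scoredPairs(res))[c("pair_id", "active")],
#'       fx$expected, by = "pair_id")
#' @export
generateBoundaryFixture <- function(config = ScoringConfig()) {
    eps <- 1e-9
    fp <- config@fpkmMin
    fc <- config@log2fcMin
    fd <- config@fdrMax
    # ligand-side boundary genes, each paired with the anchor receptor
    ligGenes <- c(LFPKMAT = fp, LFPKMUP = fp + eps,
                  LFCAT = 50, LFCUP = 50, LFDRAT = 50, LFDRUP = 50,
                  ANCHL = 100)
    recGenes <- c(RFPKMAT = fp, RFPKMUP = fp + eps, ANCHR = 100)
    deg <- DEGTable(
        gene = c(names(ligGenes)),
        log2fc = c(fc + 2, fc + 2, fc, fc + eps, fc + 2, fc + 2, fc + 2),
        fdr = c(fd / 10, fd / 10, fd / 10, fd / 10, fd, fd - eps, fd / 10))
    pairIds <- c("B_L_FPKM_AT", "B_L_FPKM_UP", "B_L_FC_AT", "B_L_FC_UP",
                 "B_L_FDR_AT", "B_L_FDR_UP", "B_ANCHOR",
                 "B_R_FPKM_AT", "B_R_FPKM_UP")
    db <- LRDatabase(
        pairId = pairIds,
        ligand = c(as.list(names(ligGenes)),
                   list("ANCHL", "ANCHL")),
        receptor = c(as.list(rep("ANCHR", 7L)),
                     list("RFPKMAT", "RFPKMUP")),
        sourceTag = "boundary fixture")
    expected <- data.frame(
        pair_id = pairIds,
        active = c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE, TRUE,
                   FALSE, TRUE),
        stringsAsFactors = FALSE)
    list(db = db, deg = deg,
         sender = ExpressionProfile(ligGenes, "boundary sender"),
         receiver = ExpressionProfile(recGenes, "boundary receiver"),
         expected = expected)
}
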