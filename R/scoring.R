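#' Select candidate sender ligand genes from the DEG table
#'
#' A gene qualifies as a sender-side ligand candidate when it is
#' significantly upregulated in the stimulated condition: FDR strictly
#' below `fdrMax` AND log2 fold change strictly above `log2fcMin`
#' (defaults 0.01 and 1). Both cuts are strict, so a gene at exactly
#' FDR = 0.01 or log2FC = 1 is excluded; downregulated genes never
#' qualify.
#'
#' @param deg a [DEGTable].
#' @param config a [ScoringConfig].
#' @return Character vector of qualifying gene symbols (DEG-table order).
#' @examples
#' deg <- DEGTable(c("A", "B", "C"),
#'                 log2fc = c(1.5, 0.9, 2.0),
#'                 fdr    = c(0.005, 0.001, 0.02))
#' selectSenderLigandGenes(deg, ScoringConfig())  # "A"
#' @export
selectSenderLigandGenes <- function(deg, config = ScoringConfig()) {
    s <- degStats(deg)
    s$gene[s$fdr < config@fdrMax & s$log2fc > config@log2fcMin]
}

#' Threshold an expression profile
#'
#' Keeps the genes of `restrictTo` (when given) whose expression is
#' strictly greater than `fpkmMin`; everything else is dropped. Applied to
#' both sides before scaling, so only expressed ligands and receptors
#' enter the analysis.
#'
#' @param profile an [ExpressionProfile].
#' @param restrictTo optional character vector of gene symbols to restrict
#'   to (e.g. the database's receptor subunit universe); `NULL` keeps all.
#' @param config a [ScoringConfig].
#' @return A thresholded [ExpressionProfile] (same condition label).
#' @examples
#' p <- ExpressionProfile(c(A = 5, B = 1, C = 0.2))
#' exprValues(thresholdExpression(p, c("A", "B", "C")))  # A only
#' @export
thresholdExpression <- function(profile, restrictTo = NULL,
                                config = ScoringConfig()) {
    v <- exprValues(profile)
    keep <- v > config@fpkmMin
    if (!is.null(restrictTo))
        keep <- keep & names(v) %in% toupper(trimws(restrictTo))
    ExpressionProfile(v[keep], conditionLabel(profile))
}

#' Scale maximum: mean of the top fraction of expression values
#'
#' The reference maximum used to scale one side's expression is not the
#' single largest value but the arithmetic mean of the top
#' `ceiling(topFraction * n)` values (at least one), which makes the
#' scaling robust to a single extreme gene.
#'
#' @param values numeric vector of positive expression values.
#' @param topFraction fraction of the highest values averaged (default
#'   0.10).
#' @return The scale maximum (single numeric).
#' @examples
#' computeScaleMax(1:100)  # mean(91:100) = 95.5
#' computeScaleMax(c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1))  # 10
#' @export
computeScaleMax <- function(values, topFraction = 0.10) {
    if (length(values) == 0L)
        stop("cannot compute a scale maximum from an empty value set",
             call. = FALSE)
    if (any(!is.finite(values) | values <= 0))
        stop("scale-maximum input must be positive and finite", call. = FALSE)
    k <- max(1L, as.integer(ceiling(topFraction * length(values))))
    mean(sort(values, decreasing = TRUE)[seq_len(k)])
}

#' Scale an expression profile to the [0, ceiling] range
#'
#' Each value v becomes `min(scaleFactor * v / scaleMax, ceiling)`:
#' division by the side's own scale maximum, multiplication by 10, and
#' coercion of outliers above the ceiling down to it. Ligand and receptor
#' sides are always scaled with their own scale maxima.
#'
#' @param profile an [ExpressionProfile] (already thresholded).
#' @param scaleMax the side's scale maximum from [computeScaleMax()].
#' @param config a [ScoringConfig].
#' @return An [ExpressionProfile] of scaled values in \[0, ceiling\].
#' @examples
#' p <- ExpressionProfile(c(A = 95.5, B = 191, C = 4.775))
#' exprValues(scaleExpression(p, 95.5))  # 10, 10 (clipped), 0.5
#' @export
scaleExpression <- function(profile, scaleMax, config = ScoringConfig()) {
    stopifnot(is.finite(scaleMax), scaleMax > 0)
    v <- exprValues(profile)
    ExpressionProfile(pmin(config@scaleFactor * v / scaleMax,
                           config@ceiling),
                      conditionLabel(profile))
}

#' Expression level of a (possibly multichain) complex
#'
#' A heteromeric ligand or receptor is summarized by the geometric mean of
#' its chains' scaled expression values; a single-chain molecule is its
#' sole value unchanged. Chains are clipped to the ceiling before this
#' aggregation, so the complex level always stays within \[0, ceiling\].
#'
#' @param values numeric vector of scaled chain expression levels (>= 0).
#' @return The complex-level expression (single numeric).
#' @examples
#' complexLevel(4)          # 4
#' complexLevel(c(4, 9))    # 6
#' complexLevel(c(2, 4, 8)) # 4
#' @export
complexLevel <- function(values) {
    if (length(values) == 0L)
        stop("complexLevel() needs at least one chain value", call. = FALSE)
    if (length(values) == 1L) return(unname(values))
    unname(prod(values)^(1 / length(values)))
}

#' Score every ligand-receptor pair
#'
#' For each database pair, the ligand level L is the [complexLevel()] of
#' its subunits' scaled sender expression and the receptor level R the
#' [complexLevel()] of its subunits' scaled receiver expression; the
#' communication score is the product S = L * R and a pair is active iff
#' S > 0. A complex with any subunit absent from its scaled profile
#' (unmeasured, not a selected ligand, or removed by thresholding) gets
#' level 0 — a heteromer cannot signal without all of its chains — which
#' makes the pair inactive.
#'
#' @param db an [LRDatabase].
#' @param senderScaled scaled sender [ExpressionProfile] (ligand side).
#' @param receiverScaled scaled receiver [ExpressionProfile] (receptor
#'   side).
#' @param config a [ScoringConfig].
#' @return A [S4Vectors::DataFrame] with one row per pair in database
#'   order: `pair_id`, `ligand`, `receptor` (display strings),
#'   `ligandLevel`, `receptorLevel`, `score`, `active`.
#' @seealso [rankPairs()], [runPipeline()]
#' @export
scorePairs <- function(db, senderScaled, receiverScaled,
                       config = ScoringConfig()) {
    sv <- exprValues(senderScaled)
    rv <- exprValues(receiverScaled)
    sideLevel <- function(subunits, values) {
        vapply(subunits, function(genes) {
            idx <- match(genes, names(values))
            if (anyNA(idx)) return(0)
            complexLevel(values[idx])
        }, 0)
    }
    p <- db@pairs
    L <- sideLevel(p$ligand, sv)
    R <- sideLevel(p$receptor, rv)
    S <- L * R
    DataFrame(pair_id = p$pair_id,
              ligand = .joinSubunits(p$ligand),
              receptor = .joinSubunits(p$receptor),
              ligandLevel = unname(L), receptorLevel = unname(R),
              score = unname(S), active = unname(S > 0))
}

#' Rank scored pairs
#'
#' Sorts pairs by descending score, active pairs first, ties broken by
#' `pair_id` ascending for determinism. Active pairs receive 1-based
#' ranks; inactive pairs keep `NA` ranks and sort after all active ones.
#'
#' @param scored the [S4Vectors::DataFrame] returned by [scorePairs()].
#' @param topK number of leading active pairs in the `topK` attribute
#'   slice.
#' @return The scored table sorted as above, with a `rank` column added;
#'   the first `min(topK, n_active)` rows are the visualization slice.
#' @export
rankPairs <- function(scored, topK = 30L) {
    ord <- order(-scored$score, scored$pair_id)
    out <- scored[ord, , drop = FALSE]
    nAct <- sum(out$active)
    out$rank <- c(seq_len(nAct), rep(NA_integer_, nrow(out) - nAct))
    out
}
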