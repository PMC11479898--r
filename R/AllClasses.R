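#' @import methods
#' @importFrom S4Vectors DataFrame elementNROWS isSingleString
#' @importFrom IRanges CharacterList
NULL

#' Scoring configuration
#'
#' Holds every threshold and knob of the communication-score computation:
#' the expression floor applied to ligands and receptors, the differential-
#' expression cuts that define candidate sender ligands, the scaling ceiling
#' and factor, the fraction of values averaged to define the scale maximum,
#' and the number of top-ranked pairs kept for visualization.
#'
#' All comparisons against `fpkmMin`, `fdrMax` and `log2fcMin` are strict:
#' a gene at exactly FPKM = 1, FDR = 0.01 or log2FC = 1 is excluded.
#'
#' @slot fpkmMin numeric(1). Expression threshold; only genes with
#'   FPKM strictly greater than this survive (default 1).
#' @slot fdrMax numeric(1). FDR cutoff for sender ligand selection,
#'   strict (default 0.01).
#' @slot log2fcMin numeric(1). log2 fold-change cutoff for sender ligand
#'   selection, strict and signed: only upregulated genes qualify
#'   (default 1).
#' @slot ceiling numeric(1). Cap applied to scaled expression values
#'   (default 10).
#' @slot scaleFactor numeric(1). Multiplier applied after division by the
#'   scale maximum (default 10).
#' @slot topFraction numeric(1). Fraction of the highest expressed values
#'   averaged to define the scale maximum (default 0.10).
#' @slot topK integer(1). Number of top-ranked pairs retained for the chord
#'   diagram (default 30).
#'
#' @seealso [runPipeline()], [computeScaleMax()]
#' @exportClass ScoringConfig
setClass("ScoringConfig",
    representation(
        fpkmMin     = "numeric",
        fdrMax      = "numeric",
        log2fcMin   = "numeric",
        ceiling     = "numeric",
        scaleFactor = "numeric",
        topFraction = "numeric",
        topK        = "integer"
    )
)

setValidity("ScoringConfig", function(object) {
    msg <- character()
    for (s in c("fpkmMin", "fdrMax", "log2fcMin", "ceiling",
                "scaleFactor", "topFraction")) {
        v <- slot(object, s)
        if (length(v) != 1L || !is.finite(v) || v <= 0)
            msg <- c(msg, sprintf("'%s' must be a single finite positive number", s))
    }
    if (length(object@topFraction) == 1L && is.finite(object@topFraction) &&
        object@topFraction > 1)
        msg <- c(msg, "'topFraction' must lie in (0, 1]")
    if (length(object@topK) != 1L || is.na(object@topK) || object@topK < 1L)
        msg <- c(msg, "'topK' must be a single integer >= 1")
    if (length(msg)) msg else TRUE
})

#' @rdname ScoringConfig-class
#' @param fpkmMin,fdrMax,log2fcMin,ceiling,scaleFactor,topFraction,topK see
#'   the corresponding slots.
#' @return `ScoringConfig()` returns a validated ScoringConfig object.
#' @examples
#' cfg <- ScoringConfig()
#' cfg
#' @export
ScoringConfig <- function(fpkmMin = 1, fdrMax = 0.01, log2fcMin = 1,
                          ceiling = 10, scaleFactor = 10,
                          topFraction = 0.10, topK = 30L) {
    new("ScoringConfig",
        fpkmMin = as.numeric(fpkmMin), fdrMax = as.numeric(fdrMax),
        log2fcMin = as.numeric(log2fcMin), ceiling = as.numeric(ceiling),
        scaleFactor = as.numeric(scaleFactor),
        topFraction = as.numeric(topFraction),
        topK = as.integer(topK))
}

#' Ligand-receptor pair database
#'
#' A curated set of directed ligand-receptor interactions. Either side of a
#' pair may be a multichain complex (several gene symbols), stored as a
#' [IRanges::CharacterList] so subunit order is preserved exactly. Gene
#' symbols are upper-cased at construction so matching against expression
#' data is case-insensitive.
#'
#' @slot pairs A [S4Vectors::DataFrame] with columns `pair_id` (character,
#'   unique), `ligand` and `receptor` (CharacterList of gene symbols,
#'   each element non-empty and duplicate-free), `family` and
#'   `display_name` (character, may be NA).
#' @slot sourceTag character(1) provenance string.
#'
#' @seealso [readLRDatabase()], [validateSymbols()]
#' @exportClass LRDatabase
setClass("LRDatabase",
    representation(pairs = "DataFrame", sourceTag = "character")
)

setValidity("LRDatabase", function(object) {
    p <- object@pairs
    need <- c("pair_id", "ligand", "receptor", "family", "display_name")
    if (!all(need %in% colnames(p)))
        return(sprintf("pairs must have columns: %s", paste(need, collapse = ", ")))
    msg <- character()
    ids <- p$pair_id
    if (anyDuplicated(ids))
        msg <- c(msg, sprintf("duplicated pair_id: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    if (any(is.na(ids)) || any(!nzchar(ids)))
        msg <- c(msg, "pair_id must be non-empty and non-NA")
    for (side in c("ligand", "receptor")) {
        su <- p[[side]]
        if (!is(su, "CharacterList"))
            return(sprintf("'%s' column must be a CharacterList", side))
        if (any(elementNROWS(su) == 0L))
            msg <- c(msg, sprintf("every %s must have >= 1 subunit", side))
        flat <- unlist(su, use.names = FALSE)
        if (length(flat) && any(is.na(flat) | !nzchar(trimws(flat))))
            msg <- c(msg, sprintf("empty %s gene symbol", side))
        if (any(vapply(su, anyDuplicated, 0L) > 0L))
            msg <- c(msg, sprintf("duplicated subunit within a %s complex", side))
    }
    if (length(object@sourceTag) != 1L)
        msg <- c(msg, "sourceTag must be a single string")
    if (length(msg)) msg else TRUE
})

#' @rdname LRDatabase-class
#' @param pairId character vector of unique pair identifiers.
#' @param ligand,receptor list (or CharacterList) of gene-symbol vectors,
#'   one element per pair; symbols are trimmed and upper-cased.
#' @param family,displayName optional character vectors (recycled NA).
#' @param sourceTag provenance string.
#' @return `LRDatabase()` returns a validated LRDatabase.
#' @examples
#' db <- LRDatabase(
#'     pairId   = c("P1", "P2"),
#'     ligand   = list("TNFSF4", c("IL12A", "IL12B")),
#'     receptor = list("TNFRSF4", c("IL12RB1", "IL12RB2")))
#' db
#' ligandSubunits(db)
#' @export
LRDatabase <- function(pairId, ligand, receptor, family = NA_character_,
                       displayName = NA_character_, sourceTag = "") {
    n <- length(pairId)
    norm <- function(x) CharacterList(lapply(x, function(g) toupper(trimws(g))))
    pairs <- DataFrame(
        pair_id      = as.character(pairId),
        ligand       = norm(as.list(ligand)),
        receptor     = norm(as.list(receptor)),
        family       = rep_len(as.character(family), n),
        display_name = rep_len(as.character(displayName), n))
    new("LRDatabase", pairs = pairs, sourceTag = as.character(sourceTag))
}

#' Expression profile of one cell state
#'
#' Gene-level mean expression (FPKM) for a single condition, e.g. the
#' IL-33-primed mast-cell (sender) or activated memory CD4+ T-cell
#' (receiver) state. Values are non-negative; zeros are kept at ingest and
#' removed only by the thresholding stage. Gene symbols are upper-cased.
#'
#' @slot values named numeric vector, gene symbol -> mean FPKM (>= 0).
#' @slot conditionLabel character(1) free-text condition description.
#'
#' @seealso [readExpression()], [thresholdExpression()]
#' @exportClass ExpressionProfile
setClass("ExpressionProfile",
    representation(values = "numeric", conditionLabel = "character")
)

setValidity("ExpressionProfile", function(object) {
    v <- object@values
    msg <- character()
    if (length(v)) {
        if (is.null(names(v)) || any(!nzchar(names(v))))
            msg <- c(msg, "all values must be named by gene symbol")
        else if (anyDuplicated(names(v)))
            msg <- c(msg, "gene symbols must be unique")
        if (any(!is.finite(v)))
            msg <- c(msg, "expression values must be finite")
        else if (any(v < 0))
            msg <- c(msg, "expression values must be >= 0")
    }
    if (length(object@conditionLabel) != 1L)
        msg <- c(msg, "conditionLabel must be a single string")
    if (length(msg)) msg else TRUE
})

#' @rdname ExpressionProfile-class
#' @param values named numeric vector of mean FPKM values.
#' @param conditionLabel condition description string.
#' @return `ExpressionProfile()` returns a validated ExpressionProfile.
#' @examples
#' ExpressionProfile(c(TNFSF4 = 42.1, CD80 = 3.3), "IL-33-primed MC")
#' @export
ExpressionProfile <- function(values = numeric(), conditionLabel = "") {
    if (length(values)) names(values) <- toupper(trimws(names(values)))
    new("ExpressionProfile", values = values,
        conditionLabel = as.character(conditionLabel))
}

#' Differential-expression table for the sender contrast
#'
#' Per-gene log2 fold change and FDR for the stimulated-versus-resting
#' sender contrast (here IL-33-primed versus resting mast cells). No
#' filtering is applied at construction; ligand selection happens in
#' [selectSenderLigandGenes()].
#'
#' @slot stats A [S4Vectors::DataFrame] with columns `gene` (unique,
#'   upper-cased), `log2fc` (finite) and `fdr` (in \[0, 1\]).
#'
#' @seealso [readDEGTable()], [selectSenderLigandGenes()]
#' @exportClass DEGTable
setClass("DEGTable", representation(stats = "DataFrame"))

setValidity("DEGTable", function(object) {
    s <- object@stats
    if (!all(c("gene", "log2fc", "fdr") %in% colnames(s)))
        return("stats must have columns gene, log2fc, fdr")
    msg <- character()
    if (anyDuplicated(s$gene))
        msg <- c(msg, "gene symbols must be unique")
    if (any(!is.finite(s$log2fc)))
        msg <- c(msg, "log2fc must be finite")
    if (any(!is.finite(s$fdr) | s$fdr < 0 | s$fdr > 1))
        msg <- c(msg, "fdr must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' @rdname DEGTable-class
#' @param gene character vector of gene symbols.
#' @param log2fc numeric vector of signed log2 fold changes.
#' @param fdr numeric vector of adjusted p-values in \[0, 1\].
#' @return `DEGTable()` returns a validated DEGTable.
#' @examples
#' DEGTable(c("TNFSF4", "CD80"), log2fc = c(3.2, 1.4), fdr = c(1e-6, 2e-3))
#' @export
DEGTable <- function(gene = character(), log2fc = numeric(), fdr = numeric()) {
    new("DEGTable", stats = DataFrame(
        gene = toupper(trimws(as.character(gene))),
        log2fc = as.numeric(log2fc), fdr = as.numeric(fdr)))
}

#' Result of the communication-scoring pipeline
#'
#' Bundles the scored pair table (sorted by descending score, active pairs
#' ranked 1..n), the scaled sender and receiver profiles actually used for
#' scoring, the configuration, and a provenance record with per-stage
#' counts and input digests.
#'
#' @slot scores A [S4Vectors::DataFrame] with columns `pair_id`, `ligand`,
#'   `receptor` (display strings, subunits joined by "+"), `ligandLevel`,
#'   `receptorLevel`, `score`, `active`, `rank` (NA for inactive pairs).
#' @slot senderScaled,receiverScaled [ExpressionProfile] of scaled values
#'   in \[0, ceiling\] restricted to the genes that survived selection and
#'   thresholding.
#' @slot config the [ScoringConfig] used.
#' @slot provenance list: configuration echo, per-stage counts, scale
#'   maxima, input digests.
#'
#' @seealso [runPipeline()], [scoredPairs()], [activePairs()], [topPairs()]
#' @exportClass CommunicationResult
setClass("CommunicationResult",
    representation(
        scores         = "DataFrame",
        senderScaled   = "ExpressionProfile",
        receiverScaled = "ExpressionProfile",
        config         = "ScoringConfig",
        provenance     = "list"
    )
)

#' Specification of a synthetic benchmark dataset
#'
#' Describes a generated dataset with planted active ligand-receptor pairs
#' whose post-pipeline scores and ranking are known by construction, plus a
#' log-normal background that shapes the top-decile scale maxima without
#' producing unplanned active pairs.
#'
#' @slot nBackgroundGenes integer(1). Decoy genes per side shaping each
#'   scale maximum (default 100).
#' @slot plantedScores numeric, strictly decreasing intended scores in
#'   (0, ceiling^2]; length defines the number of planted pairs.
#' @slot multichainFraction numeric(1) in \[0, 1\]; this fraction of planted
#'   pairs (rounded, taken from the top of the ranking) gets two-chain
#'   ligand and receptor complexes with equal subunit expression.
#' @slot exprMeanlog,exprSdlog numeric(1). Log-normal parameters of the
#'   background FPKM distribution (defaults 2 and 1.5: median ~7 FPKM with
#'   a heavy right tail, typical of bulk RNA-seq FPKM marginals).
#' @slot degLog2fc,degFdr numeric(1). Differential-expression effect
#'   assigned to planted and decoy ligand genes so they pass the DEG cuts
#'   (defaults 3 and 1e-4).
#' @slot seed integer(1) RNG seed.
#'
#' @seealso [generateDataset()]
#' @exportClass SyntheticSpec
setClass("SyntheticSpec",
    representation(
        nBackgroundGenes   = "integer",
        plantedScores      = "numeric",
        multichainFraction = "numeric",
        exprMeanlog        = "numeric",
        exprSdlog          = "numeric",
        degLog2fc          = "numeric",
        degFdr             = "numeric",
        seed               = "integer"
    )
)

setValidity("SyntheticSpec", function(object) {
    msg <- character()
    if (object@nBackgroundGenes < 0L)
        msg <- c(msg, "nBackgroundGenes must be >= 0")
    s <- object@plantedScores
    if (length(s)) {
        if (any(!is.finite(s) | s <= 0))
            msg <- c(msg, "plantedScores must be positive and finite")
        if (length(s) > 1L && any(diff(s) >= 0))
            msg <- c(msg, "plantedScores must be strictly decreasing")
    }
    if (object@multichainFraction < 0 || object@multichainFraction > 1)
        msg <- c(msg, "multichainFraction must lie in [0, 1]")
    if (!is.finite(object@exprSdlog) || object@exprSdlog <= 0)
        msg <- c(msg, "exprSdlog must be positive")
    if (length(msg)) msg else TRUE
})

#' @rdname SyntheticSpec-class
#' @param nBackgroundGenes,plantedScores,multichainFraction see slots.
#' @param exprMeanlog,exprSdlog,degLog2fc,degFdr,seed see slots.
#' @return `SyntheticSpec()` returns a validated SyntheticSpec.
#' @examples
#' SyntheticSpec(plantedScores = c(80, 60, 40, 20, 5), seed = 7L)
#' @export
SyntheticSpec <- function(nBackgroundGenes = 100L,
                          plantedScores = c(80, 60, 40, 20, 5),
                          multichainFraction = 0.4,
                          exprMeanlog = 2, exprSdlog = 1.5,
                          degLog2fc = 3, degFdr = 1e-4, seed = 1L) {
    new("SyntheticSpec",
        nBackgroundGenes = as.integer(nBackgroundGenes),
        plantedScores = as.numeric(plantedScores),
        multichainFraction = as.numeric(multichainFraction),
        exprMeanlog = as.numeric(exprMeanlog),
        exprSdlog = as.numeric(exprSdlog),
        degLog2fc = as.numeric(degLog2fc),
        degFdr = as.numeric(degFdr),
        seed = as.integer(seed))
}

#' Chord-diagram specification
#'
#' The input of [renderChord()]: the top-ranked active pairs to draw, with
#' optional editorial exclusions and gene-symbol display overrides (e.g.
#' TNFSF4 shown as OX40L).
#'
#' @slot entries A [S4Vectors::DataFrame] with columns `pair_id`, `ligand`,
#'   `receptor` (display labels) and `score` (> 0), ordered by descending
#'   score.
#' @slot senderLabel,receiverLabel character(1) annotations for the two
#'   semicircles.
#' @slot excludedPairIds character, pair ids removed before layout.
#' @slot labelOverrides named character, gene symbol -> display name.
#'
#' @seealso [ChordSpec()], [chordGeometry()], [renderChord()]
#' @exportClass ChordSpec
setClass("ChordSpec",
    representation(
        entries         = "DataFrame",
        senderLabel     = "character",
        receiverLabel   = "character",
        excludedPairIds = "character",
        labelOverrides  = "character"
    )
)

setValidity("ChordSpec", function(object) {
    e <- object@entries
    if (!all(c("pair_id", "ligand", "receptor", "score") %in% colnames(e)))
        return("entries must have columns pair_id, ligand, receptor, score")
    if (nrow(e) == 0L)
        return("no pairs to draw; check the active-pair count (and exclusions)")
    if (any(e$score <= 0))
        return("all chord entries must be active (score > 0)")
    TRUE
})
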