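#' @rdname LRDatabase-class
#' @export
setMethod("pairIds", "LRDatabase", function(x) x@pairs$pair_id)

#' @rdname LRDatabase-class
#' @export
setMethod("ligandSubunits", "LRDatabase", function(x) {
    setNames(x@pairs$ligand, x@pairs$pair_id)
})

#' @rdname LRDatabase-class
#' @export
setMethod("receptorSubunits", "LRDatabase", function(x) {
    setNames(x@pairs$receptor, x@pairs$pair_id)
})

#' @rdname LRDatabase-class
#' @export
setMethod("length", "LRDatabase", function(x) nrow(x@pairs))

#' @rdname LRDatabase-class
#' @param i index (numeric, logical or pair_id character) to subset pairs.
#' @param j,drop,... ignored; present for generic compatibility.
#' @export
setMethod("[", "LRDatabase", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) i <- match(i, x@pairs$pair_id)
    initialize(x, pairs = x@pairs[i, , drop = FALSE])
})

#' @rdname LRDatabase-class
#' @export
setMethod("show", "LRDatabase", function(object) {
    n <- length(object)
    multi <- sum(elementNROWS(object@pairs$ligand) > 1L |
                 elementNROWS(object@pairs$receptor) > 1L)
    cat(sprintf("LRDatabase with %d pair%s (%d multichain)\n",
                n, if (n == 1L) "" else "s", multi))
    if (nzchar(object@sourceTag))
        cat("  source:", object@sourceTag, "\n")
    if (n) {
        shown <- head(seq_len(n), 5L)
        lab <- sprintf("  %s: %s -> %s", object@pairs$pair_id[shown],
                       .joinSubunits(object@pairs$ligand[shown]),
                       .joinSubunits(object@pairs$receptor[shown]))
        cat(lab, sep = "\n")
        if (n > 5L) cat("  ...\n")
    }
    invisible(NULL)
})

#' @rdname ExpressionProfile-class
#' @export
setMethod("exprValues", "ExpressionProfile", function(x) x@values)

#' @rdname ExpressionProfile-class
#' @export
setMethod("conditionLabel", "ExpressionProfile", function(x) x@conditionLabel)

#' @rdname ExpressionProfile-class
#' @export
setMethod("geneSymbols", "ExpressionProfile", function(x) names(x@values))

#' @rdname ExpressionProfile-class
#' @export
setMethod("length", "ExpressionProfile", function(x) length(x@values))

#' @rdname ExpressionProfile-class
#' @export
setMethod("show", "ExpressionProfile", function(object) {
    cat(sprintf("ExpressionProfile: %d gene%s", length(object),
                if (length(object) == 1L) "" else "s"))
    if (nzchar(object@conditionLabel))
        cat(sprintf(" [%s]", object@conditionLabel))
    cat("\n")
    if (length(object)) {
        v <- head(object@values, 5L)
        cat(sprintf("  %s: %.4g\n", names(v), v), sep = "")
        if (length(object) > 5L) cat("  ...\n")
    }
    invisible(NULL)
})

#' @rdname DEGTable-class
#' @export
setMethod("degStats", "DEGTable", function(x) x@stats)

#' @rdname DEGTable-class
#' @export
setMethod("length", "DEGTable", function(x) nrow(x@stats))

#' @rdname DEGTable-class
#' @export
setMethod("show", "DEGTable", function(object) {
    cat(sprintf("DEGTable with %d gene%s\n", length(object),
                if (length(object) == 1L) "" else "s"))
    invisible(NULL)
})

#' @rdname CommunicationResult-class
#' @export
setMethod("scoredPairs", "CommunicationResult", function(x) x@scores)

#' @rdname CommunicationResult-class
#' @export
setMethod("activePairs", "CommunicationResult", function(x) {
    x@scores[x@scores$active, , drop = FALSE]
})

#' @rdname CommunicationResult-class
#' @export
setMethod("topPairs", "CommunicationResult", function(x, k = NULL) {
    if (is.null(k)) k <- x@config@topK
    act <- activePairs(x)
    act[seq_len(min(as.integer(k), nrow(act))), , drop = FALSE]
})

#' @rdname CommunicationResult-class
#' @export
setMethod("provenance", "CommunicationResult", function(x) x@provenance)

#' @rdname CommunicationResult-class
#' @export
setMethod("show", "CommunicationResult", function(object) {
    sc <- object@scores
    nAct <- sum(sc$active)
    cat(sprintf("CommunicationResult: %d pairs scored, %d active (S > 0)\n",
                nrow(sc), nAct))
    cts <- object@provenance$counts
    if (!is.null(cts))
        cat(sprintf("  ligands kept: %d | receptors kept: %d\n",
                    cts$nLigandGenesKept, cts$nReceptorGenesKept))
    if (nAct) {
        top <- sc[sc$active, , drop = FALSE]
        top <- top[seq_len(min(5L, nrow(top))), , drop = FALSE]
        cat(sprintf("  #%d %s: %s -> %s  S = %.3f\n", top$rank, top$pair_id,
                    top$ligand, top$receptor, top$score), sep = "")
        if (nAct > 5L) cat("  ...\n")
    }
    invisible(NULL)
})
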