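# Independent straight-line re-implementation of the communication-score
# procedure, written against plain R structures with explicit loops and no
# package code. Used as a cross-check oracle for the pipeline.
#
# pairs:    list of list(id =, lig = character, rec = character)
# deg:      data.frame(gene, log2fc, fdr)
# sender:   named numeric (FPKM), receiver: named numeric (FPKM)
# cfg:      list(fpkmMin, fdrMax, log2fcMin, ceiling, scaleFactor,
#                topFraction)
oracleScorePairs <- function(pairs, deg, sender, receiver, cfg) {
    selected <- character(0)
    for (i in seq_len(nrow(deg)))
        if (deg$fdr[i] < cfg$fdrMax && deg$log2fc[i] > cfg$log2fcMin)
            selected <- c(selected, deg$gene[i])

    ligUniv <- unique(unlist(lapply(pairs, `[[`, "lig")))
    recUniv <- unique(unlist(lapply(pairs, `[[`, "rec")))

    keepSide <- function(values, restrict) {
        out <- numeric(0)
        for (g in names(values))
            if (g %in% restrict && values[[g]] > cfg$fpkmMin)
                out[g] <- values[[g]]
        out
    }
    sKeep <- keepSide(sender, intersect(selected, ligUniv))
    rKeep <- keepSide(receiver, recUniv)

    scaleSide <- function(v) {
        if (length(v) == 0L) return(v)
        k <- max(1, ceiling(cfg$topFraction * length(v)))
        m <- mean(sort(v, decreasing = TRUE)[1:k])
        out <- v
        for (g in names(v))
            out[g] <- min(cfg$scaleFactor * v[[g]] / m, cfg$ceiling)
        out
    }
    sSc <- scaleSide(sKeep)
    rSc <- scaleSide(rKeep)

    gm <- function(x) if (length(x) == 1L) x else prod(x)^(1 / length(x))

    ids <- character(length(pairs))
    L <- R <- S <- numeric(length(pairs))
    for (i in seq_along(pairs)) {
        p <- pairs[[i]]
        ids[i] <- p$id
        L[i] <- if (all(p$lig %in% names(sSc))) gm(unname(sSc[p$lig])) else 0
        R[i] <- if (all(p$rec %in% names(rSc))) gm(unname(rSc[p$rec])) else 0
        S[i] <- L[i] * R[i]
    }
    data.frame(pair_id = ids, L = L, R = R, S = S,
               stringsAsFactors = FALSE)
}

defaultOracleCfg <- function() {
    list(fpkmMin = 1, fdrMax = 0.01, log2fcMin = 1, ceiling = 10,
         scaleFactor = 10, topFraction = 0.10)
}
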