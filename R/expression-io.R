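#' Read a mean-expression profile from a delimited text file
#'
#' Reads a gene-by-expression table into an [ExpressionProfile]. When
#' several replicate columns are named, the stored value is their
#' arithmetic mean per gene. A gene symbol listed on several rows is
#' collapsed to the arithmetic mean of its rows with a warning. Zeros are
#' kept: expression filtering is the thresholding stage's job, not the
#' reader's.
#'
#' @param path path to the expression table.
#' @param sep field separator (default tab).
#' @param geneColumn physical name of the gene-symbol column.
#' @param valueColumns physical names of the expression column(s); `NULL`
#'   (default) uses every numeric column except `geneColumn`.
#' @param conditionLabel condition description stored with the profile.
#'
#' @return An [ExpressionProfile].
#'
#' @details Negative or non-numeric expression values are a validation
#'   error reported with the offending row number.
#'
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\trep1\trep2", "TNFSF4\t4.0\t6.0"), tf)
#' exprValues(readExpression(tf))  # TNFSF4 = 5
#' @seealso [writeExpression()], [thresholdExpression()]
#' @export
readExpression <- function(path, sep = "\t", geneColumn = "gene",
                           valueColumns = NULL, conditionLabel = "") {
    df <- .readTable(path, sep)
    if (!geneColumn %in% colnames(df))
        stop(sprintf("required column '%s' not found; file has: %s",
                     geneColumn, paste(colnames(df), collapse = ", ")),
             call. = FALSE)
    if (is.null(valueColumns)) {
        valueColumns <- setdiff(colnames(df)[vapply(df, is.numeric, TRUE)],
                                geneColumn)
        if (!length(valueColumns))
            stop("no numeric expression column found", call. = FALSE)
    } else {
        missing <- setdiff(valueColumns, colnames(df))
        if (length(missing))
            stop("expression column(s) not found: ",
                 paste(missing, collapse = ", "), call. = FALSE)
    }
    vals <- df[valueColumns]
    bad <- which(Reduce(`|`, lapply(vals, function(v)
        !is.numeric(v) | is.na(suppressWarnings(as.numeric(v))) |
            as.numeric(v) < 0)))
    if (length(bad))
        stop(sprintf("negative or non-numeric expression at row%s %s",
                     if (length(bad) > 1L) "s" else "",
                     paste(bad, collapse = ", ")), call. = FALSE)
    # replicate mean per row, then collapse duplicated gene symbols
    rowMean <- rowMeans(as.matrix(vals))
    genes <- toupper(trimws(as.character(df[[geneColumn]])))
    if (anyDuplicated(genes)) {
        dups <- unique(genes[duplicated(genes)])
        warning("duplicated gene symbol(s) collapsed by arithmetic mean: ",
                paste(dups, collapse = ", "), call. = FALSE)
        agg <- vapply(split(rowMean, genes), mean, 0)
        agg <- agg[unique(genes)]  # preserve first-appearance order
        return(ExpressionProfile(agg, conditionLabel))
    }
    ExpressionProfile(setNames(rowMean, genes), conditionLabel)
}

#' Write an expression profile to TSV at full precision
#'
#' Values are written with 17 significant digits so that reading the file
#' back reproduces every double exactly.
#'
#' @param profile an [ExpressionProfile].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @seealso [readExpression()]
#' @export
writeExpression <- function(profile, path) {
    v <- exprValues(profile)
    out <- data.frame(gene = names(v), fpkm = .fmtFull(unname(v)),
                      stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a differential-expression table
#'
#' Reads the sender stimulated-versus-resting contrast (gene, log2 fold
#' change, FDR) into a [DEGTable]. No filtering is applied here; the
#' ligand-selection cuts live in [selectSenderLigandGenes()].
#'
#' @param path path to the DEG table.
#' @param sep field separator (default tab).
#' @param columns named character vector mapping the logical columns
#'   `gene`, `log2fc`, `fdr` to physical column names.
#'
#' @return A [DEGTable].
#' @details An FDR outside \[0, 1\] or a non-finite log2 fold change is a
#'   validation error.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\tlog2fc\tfdr", "TNFSF4\t3.2\t1e-06"), tf)
#' readDEGTable(tf)
#' @seealso [writeDEGTable()]
#' @export
readDEGTable <- function(path, sep = "\t",
                         columns = c(gene = "gene", log2fc = "log2fc",
                                     fdr = "fdr")) {
    df <- .readTable(path, sep)
    cols <- .resolveColumns(df, columns,
                            required = c("gene", "log2fc", "fdr"))
    DEGTable(gene = as.character(df[[cols[["gene"]]]]),
             log2fc = as.numeric(df[[cols[["log2fc"]]]]),
             fdr = as.numeric(df[[cols[["fdr"]]]]))
}

#' Write a differential-expression table to TSV at full precision
#'
#' @param deg a [DEGTable].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @seealso [readDEGTable()]
#' @export
writeDEGTable <- function(deg, path) {
    s <- degStats(deg)
    out <- data.frame(gene = s$gene, log2fc = .fmtFull(s$log2fc),
                      fdr = .fmtFull(s$fdr), stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}
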