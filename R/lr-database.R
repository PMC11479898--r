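#' Read a ligand-receptor pair database from a delimited text file
#'
#' Parses a TSV/CSV table of directed ligand-receptor interactions into an
#' [LRDatabase]. Multichain complexes are encoded within one cell, subunit
#' symbols joined by `subunitSep` (default `"+"`, e.g. `IL12A+IL12B`).
#' Symbols are trimmed and upper-cased; row order and within-complex
#' subunit order are preserved exactly.
#'
#' @param path path to the database file.
#' @param sep field separator (default tab).
#' @param subunitSep separator joining subunit symbols within a cell.
#' @param columns named character vector mapping the logical columns
#'   `pair_id`, `ligand`, `receptor` (required) and `family`,
#'   `display_name` (optional) to the physical column names in the file.
#' @param sourceTag provenance string stored with the database.
#'
#' @return An [LRDatabase].
#'
#' @details Validation failures are reported with row context: a missing
#'   required column names the column, duplicated pair ids list the
#'   offenders, and an empty ligand or receptor cell reports its row
#'   number. No alias or synonym resolution is attempted; unmatched gene
#'   symbols are surfaced later by [validateSymbols()] rather than guessed.
#'
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("pair_id\tligand\treceptor",
#'              "P1\tTNFSF4\tTNFRSF4",
#'              "P2\tIL12A+IL12B\tIL12RB1+IL12RB2"), tf)
#' db <- readLRDatabase(tf)
#' receptorSubunits(db)[["P2"]]
#' @seealso [writeLRDatabase()], [validateSymbols()]
#' @export
readLRDatabase <- function(path, sep = "\t", subunitSep = "+",
                           columns = c(pair_id = "pair_id",
                                       ligand = "ligand",
                                       receptor = "receptor",
                                       family = "family",
                                       display_name = "display_name"),
                           sourceTag = basename(path)) {
    df <- .readTable(path, sep)
    cols <- .resolveColumns(df, columns,
                            required = c("pair_id", "ligand", "receptor"))
    splitCell <- function(column) {
        raw <- as.character(df[[cols[[column]]]])
        empty <- which(is.na(raw) | !nzchar(trimws(raw)))
        if (length(empty))
            stop(sprintf("empty %s cell at row%s %s", column,
                         if (length(empty) > 1L) "s" else "",
                         paste(empty, collapse = ", ")), call. = FALSE)
        strsplit(raw, subunitSep, fixed = TRUE)
    }
    if (nrow(df) == 0L)
        return(LRDatabase(character(), list(), list(), sourceTag = sourceTag))
    ids <- as.character(df[[cols[["pair_id"]]]])
    if (anyDuplicated(ids))
        stop("duplicated pair_id: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "),
             call. = FALSE)
    LRDatabase(
        pairId      = ids,
        ligand      = splitCell("ligand"),
        receptor    = splitCell("receptor"),
        family      = if ("family" %in% names(cols))
                          as.character(df[[cols[["family"]]]]) else NA_character_,
        displayName = if ("display_name" %in% names(cols))
                          as.character(df[[cols[["display_name"]]]]) else NA_character_,
        sourceTag   = sourceTag)
}

#' Write a ligand-receptor database to TSV
#'
#' Emits one row per pair with subunits joined by `subunitSep`; a read with
#' [readLRDatabase()] reproduces pair ids, subunit lists and row order
#' exactly.
#'
#' @param db an [LRDatabase].
#' @param path output file path.
#' @param subunitSep separator used to join subunits within a cell.
#' @return Invisibly, `path`.
#' @seealso [readLRDatabase()]
#' @export
writeLRDatabase <- function(db, path, subunitSep = "+") {
    p <- db@pairs
    out <- data.frame(
        pair_id      = p$pair_id,
        ligand       = vapply(p$ligand, paste, "", collapse = subunitSep),
        receptor     = vapply(p$receptor, paste, "", collapse = subunitSep),
        family       = p$family,
        display_name = p$display_name,
        stringsAsFactors = FALSE)
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
    invisible(path)
}

#' Report database gene symbols absent from an expression universe
#'
#' For every pair, lists the ligand and receptor subunits that are not
#' measured in the given gene universe (e.g. the union of gene symbols in
#' the sender and receiver profiles). A pair with any unmeasured subunit
#' can never be called active, so this report is the first thing to check
#' when fewer active pairs than expected are returned. The database is not
#' modified.
#'
#' @param db an [LRDatabase].
#' @param universe character vector of measured gene symbols (matched
#'   case-insensitively).
#' @return A [S4Vectors::DataFrame] with columns `pair_id`,
#'   `missingLigand` and `missingReceptor` (CharacterList), one row per
#'   pair with at least one unmeasured subunit; zero rows when the
#'   universe covers the database.
#' @examples
#' db <- LRDatabase("P1", list("TNFSF4"), list("TNFRSF4"))
#' validateSymbols(db, c("TNFSF4"))
#' @export
validateSymbols <- function(db, universe) {
    universe <- toupper(trimws(universe))
    p <- db@pairs
    missLig <- CharacterList(lapply(p$ligand, setdiff, y = universe))
    missRec <- CharacterList(lapply(p$receptor, setdiff, y = universe))
    keep <- elementNROWS(missLig) > 0L | elementNROWS(missRec) > 0L
    DataFrame(pair_id = p$pair_id,
              missingLigand = missLig,
              missingReceptor = missRec)[keep, , drop = FALSE]
}
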