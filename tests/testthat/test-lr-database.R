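writeDbFile <- function(lines) {
    tf <- tempfile(fileext = ".tsv")
    writeLines(lines, tf)
    tf
}

test_that("database parsing handles single- and multichain pairs", {
    tf <- writeDbFile(c(
        "pair_id\tligand\treceptor",
        "P1\tTNFSF4\tTNFRSF4",
        "P2\tCD80\tCD28",
        "P3\tIL12A+IL12B\tIL12RB1+IL12RB2"))
    db <- readLRDatabase(tf)
    expect_s4_class(db, "LRDatabase")
    expect_length(db, 3L)
    expect_identical(pairIds(db), c("P1", "P2", "P3"))
    expect_identical(as.character(ligandSubunits(db)[["P3"]]),
                     c("IL12A", "IL12B"))
    expect_identical(as.character(receptorSubunits(db)[["P3"]]),
                     c("IL12RB1", "IL12RB2"))
})

test_that("gene symbols are trimmed and upper-cased at ingest", {
    tf <- writeDbFile(c("pair_id\tligand\treceptor",
                        "P1\t tnfsf4 \tTnfrsf4"))
    db <- readLRDatabase(tf)
    expect_identical(as.character(ligandSubunits(db)[[1]]), "TNFSF4")
    expect_identical(as.character(receptorSubunits(db)[[1]]), "TNFRSF4")
})

test_that("duplicate pair ids are a validation error naming offenders", {
    tf <- writeDbFile(c("pair_id\tligand\treceptor",
                        "P1\tA\tB", "P1\tC\tD"))
    expect_error(readLRDatabase(tf), "P1")
})

test_that("a header-only file yields an empty database", {
    tf <- writeDbFile("pair_id\tligand\treceptor")
    db <- readLRDatabase(tf)
    expect_length(db, 0L)
})

test_that("missing required columns and empty cells are reported precisely", {
    tf <- writeDbFile(c("pair_id\tligand", "P1\tA"))
    expect_error(readLRDatabase(tf), "receptor")
    tf2 <- writeDbFile(c("pair_id\tligand\treceptor",
                         "P1\tA\tB", "P2\t\tC"))
    expect_error(readLRDatabase(tf2), "row.* 2")
})

test_that("column remapping resolves non-default headers", {
    tf <- writeDbFile(c("id\tL\tR", "P1\tA\tB"))
    db <- readLRDatabase(tf, columns = c(pair_id = "id", ligand = "L",
                                         receptor = "R"))
    expect_identical(pairIds(db), "P1")
})

test_that("write/read round trip preserves ids, subunit lists and order", {
    set.seed(11)
    for (rep in 1:5) {
        n <- sample(1:12, 1L)
        lig <- lapply(seq_len(n), function(i)
            sprintf("LG%d_%d", i, seq_len(sample(1:3, 1L))))
        rec <- lapply(seq_len(n), function(i)
            sprintf("RC%d_%d", i, seq_len(sample(1:3, 1L))))
        db <- LRDatabase(sprintf("P%03d", sample(100, n)), lig, rec,
                         family = sample(c("tnf", "ig", NA), n, TRUE))
        tf <- tempfile(fileext = ".tsv")
        writeLRDatabase(db, tf)
        back <- readLRDatabase(tf)
        expect_identical(pairIds(back), pairIds(db))
        expect_identical(as.list(ligandSubunits(back)),
                         as.list(ligandSubunits(db)))
        expect_identical(as.list(receptorSubunits(back)),
                         as.list(receptorSubunits(db)))
    }
})

test_that("constructor validity rejects malformed databases", {
    expect_error(LRDatabase(c("P1", "P1"), list("A", "B"), list("C", "D")),
                 "duplicated pair_id")
    expect_error(LRDatabase("P1", list(character(0)), list("R")),
                 "subunit")
    expect_error(LRDatabase("P1", list(c("A", "A")), list("R")),
                 "duplicated subunit")
})

test_that("validateSymbols reports unmeasured subunits per pair", {
    db <- LRDatabase(c("P1", "P2"),
                     ligand = list("TNFSF4", c("IL12A", "IL12B")),
                     receptor = list("TNFRSF4", "IL12RB1"))
    rep1 <- validateSymbols(db, c("TNFSF4"))
    expect_identical(rep1$pair_id, c("P1", "P2"))
    expect_identical(as.character(rep1$missingReceptor[[1]]), "TNFRSF4")
    expect_identical(as.character(rep1$missingLigand[[2]]),
                     c("IL12A", "IL12B"))
    # full universe -> empty report; empty database -> empty report
    allSyms <- c("TNFSF4", "TNFRSF4", "IL12A", "IL12B", "IL12RB1")
    expect_identical(nrow(validateSymbols(db, allSyms)), 0L)
    empty <- LRDatabase(character(), list(), list())
    expect_identical(nrow(validateSymbols(empty, "X")), 0L)
    # matching is case-insensitive
    expect_identical(nrow(validateSymbols(db, tolower(allSyms))), 0L)
})
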