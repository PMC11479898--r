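# Internal helpers shared across modules.

# Join CharacterList elements with "+" for display / TSV storage.
.joinSubunits <- function(cl) {
    vapply(cl, paste, "", collapse = "+")
}

# Rolling polynomial digest (base 31 mod 2^31-1) of an R object, used only
# for provenance echoes; vectorized over 512-byte chunks. All intermediates
# are kept below 2^53 so double arithmetic is exact (.mulmod splits the
# multiplicand).
.mulmod <- function(a, b, p = 2147483647) {
    a1 <- a %/% 65536
    a0 <- a %% 65536
    (((a1 * b) %% p) * 65536 + a0 * b) %% p
}

.contentDigest <- function(object) {
    bytes <- as.numeric(serialize(object, NULL, version = 2L))
    p <- 2147483647
    chunk <- 512L
    pow <- numeric(chunk)          # pow[i] = 31^(chunk - i) mod p
    pow[chunk] <- 1
    for (i in rev(seq_len(chunk - 1L))) pow[i] <- (pow[i + 1L] * 31) %% p
    h <- 0
    n <- length(bytes)
    start <- 1L
    while (start <= n) {
        seg <- bytes[start:min(start + chunk - 1L, n)]
        m <- length(seg)
        segHash <- sum((seg * pow[(chunk - m + 1L):chunk]) %% p) %% p
        # 31^m mod p by square-and-multiply
        hPow <- 1
        b31 <- 31
        e <- m
        while (e > 0) {
            if (e %% 2 == 1) hPow <- .mulmod(hPow, b31, p)
            b31 <- .mulmod(b31, b31, p)
            e <- e %/% 2
        }
        h <- (.mulmod(h, hPow, p) + segHash) %% p
        start <- start + chunk
    }
    sprintf("%08x", h)
}

# read.delim wrapper with consistent defaults for all table readers.
.readTable <- function(path, sep = "\t") {
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    utils::read.delim(path, sep = sep, header = TRUE,
                      stringsAsFactors = FALSE, check.names = FALSE,
                      comment.char = "", quote = "\"")
}

# Resolve logical column names through a user mapping; error names the
# missing logical column and the candidates present in the file.
.resolveColumns <- function(df, columns, required) {
    out <- character(0)
    for (logical in names(columns)) {
        physical <- columns[[logical]]
        if (!physical %in% colnames(df)) {
            if (logical %in% required)
                stop(sprintf(
                    "required column '%s' (mapped from '%s') not found; file has: %s",
                    physical, logical, paste(colnames(df), collapse = ", ")),
                    call. = FALSE)
            next
        }
        out[logical] <- physical
    }
    out
}

# Full-precision numeric formatting for TSV round trips.
.fmtFull <- function(x) sprintf("%.17g", x)
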