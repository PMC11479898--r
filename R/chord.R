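# Chord-diagram layout and rendering for top-ranked ligand-receptor pairs.
# Layout: ligand complexes occupy one semicircle, receptor complexes the
# other; one ribbon per pair, angular width proportional to its score. All
# geometry is computed here and exported as a JSON sidecar so that tests
# (and downstream tools) assert on angles, never on pixels.

#' Build a chord specification from a pipeline result
#'
#' Takes the top-`k` active pairs of a [CommunicationResult], removes any
#' editorially excluded pairs (e.g. the ubiquitous ICAM/integrin adhesion
#' pairs that would dominate the plot), and applies display-name overrides
#' such as showing TNFSF4 as OX40L.
#'
#' @param result a [CommunicationResult].
#' @param topK number of top-ranked pairs to draw (default: the
#'   configuration's `topK`, 30 by default).
#' @param exclude character vector of pair ids to drop before layout.
#' @param labelOverrides named character vector, gene symbol -> display
#'   name; applied per subunit, so `c(TNFSF4 = "OX40L")` also relabels
#'   complexes containing TNFSF4.
#' @param senderLabel,receiverLabel semicircle annotations.
#' @return A [ChordSpec].
#' @examples
#' ds <- generateDataset(SyntheticSpec(seed = 5L))
#' res <- runPipeline(ds$db, ds$deg, ds$sender, ds$receiver)
#' ChordSpec(res, topK = 5)
#' @export
ChordSpec <- function(result, topK = NULL, exclude = character(),
                      labelOverrides = character(),
                      senderLabel = "sender", receiverLabel = "receiver") {
    stopifnot(is(result, "CommunicationResult"))
    entries <- topPairs(result, topK)
    entries <- entries[!entries$pair_id %in% exclude, , drop = FALSE]
    relabel <- function(display) {
        if (!length(labelOverrides)) return(display)
        vapply(strsplit(display, "+", fixed = TRUE), function(sub) {
            hit <- sub %in% names(labelOverrides)
            sub[hit] <- labelOverrides[sub[hit]]
            paste(sub, collapse = "+")
        }, "")
    }
    new("ChordSpec",
        entries = DataFrame(pair_id = entries$pair_id,
                            ligand = relabel(entries$ligand),
                            receptor = relabel(entries$receptor),
                            score = entries$score),
        senderLabel = senderLabel, receiverLabel = receiverLabel,
        excludedPairIds = as.character(exclude),
        labelOverrides = labelOverrides)
}

#' Compute the chord-diagram geometry
#'
#' Lays out one sector per distinct ligand complex on the upper
#' semicircle and one per distinct receptor complex on the lower
#' semicircle (sectors ordered by total score, descending), and one ribbon
#' per pair whose angular width on either side is proportional to its
#' score. The layout is fully deterministic for a given specification.
#'
#' @param spec a [ChordSpec].
#' @param gapDeg angular gap between adjacent sectors (degrees).
#' @param marginDeg angular margin at both ends of each semicircle
#'   (degrees).
#' @return A list with `sectors` (data.frame: name, side, start, end in
#'   degrees), `ribbons` (data.frame: pair_id, ligand, receptor, score,
#'   and the angular intervals `l_start`, `l_end`, `r_start`, `r_end`),
#'   and `params`.
#' @details Angles are measured counterclockwise in degrees; the ligand
#'   semicircle spans (0, 180), the receptor semicircle (180, 360).
#'   Within a side, ribbon width = score * (available span / total score),
#'   so width ratios equal score ratios exactly.
#' @seealso [renderChord()]
#' @export
chordGeometry <- function(spec, gapDeg = 2, marginDeg = 8) {
    e <- as.data.frame(spec@entries)
    layoutSide <- function(labels, scores, a0, a1) {
        total <- vapply(split(scores, labels), sum, 0)
        total <- sort(total, decreasing = TRUE)
        nms <- names(total)
        # deterministic tie-break: alphabetical within equal totals
        ord <- order(-total, nms)
        nms <- nms[ord]
        total <- total[ord]
        n <- length(nms)
        avail <- (a1 - a0) - 2 * marginDeg - gapDeg * (n - 1L)
        if (avail <= 0)
            stop("gapDeg/marginDeg leave no room for sectors", call. = FALSE)
        unit <- avail / sum(scores)
        width <- unname(total) * unit
        start <- a0 + marginDeg + c(0, cumsum(width[-n] + gapDeg))
        list(sectors = data.frame(name = nms, start = start,
                                  end = start + width,
                                  stringsAsFactors = FALSE),
             unit = unit)
    }
    lig <- layoutSide(e$ligand, e$score, 0, 180)
    rec <- layoutSide(e$receptor, e$score, 180, 360)

    # stack ribbons inside each sector in global entry order (descending
    # score, the order of the spec entries)
    ribbon <- e[c("pair_id", "ligand", "receptor", "score")]
    place <- function(labels, layout) {
        cursor <- setNames(layout$sectors$start, layout$sectors$name)
        starts <- numeric(length(labels))
        for (i in seq_along(labels)) {
            starts[i] <- cursor[[labels[i]]]
            cursor[[labels[i]]] <- starts[i] + e$score[i] * layout$unit
        }
        cbind(start = starts, end = starts + e$score * layout$unit)
    }
    lpos <- place(e$ligand, lig)
    rpos <- place(e$receptor, rec)
    ribbon$l_start <- lpos[, "start"]
    ribbon$l_end <- lpos[, "end"]
    ribbon$r_start <- rpos[, "start"]
    ribbon$r_end <- rpos[, "end"]

    list(sectors = rbind(
             cbind(lig$sectors, side = "ligand",
                   stringsAsFactors = FALSE),
             cbind(rec$sectors, side = "receptor",
                   stringsAsFactors = FALSE)),
         ribbons = ribbon,
         params = list(gapDeg = gapDeg, marginDeg = marginDeg,
                       unitLigand = lig$unit, unitReceptor = rec$unit,
                       senderLabel = spec@senderLabel,
                       receiverLabel = spec@receiverLabel))
}

# quadratic bezier through the circle centre region, for ribbon borders
.bezier <- function(p0, p1, ctrl = c(0, 0), n = 40L) {
    t <- seq(0, 1, length.out = n)
    cbind((1 - t)^2 * p0[1] + 2 * (1 - t) * t * ctrl[1] + t^2 * p1[1],
          (1 - t)^2 * p0[2] + 2 * (1 - t) * t * ctrl[2] + t^2 * p1[2])
}

.arcPoints <- function(a0, a1, r, n = 30L) {
    a <- seq(a0, a1, length.out = n) * pi / 180
    cbind(r * cos(a), r * sin(a))
}

#' Render a chord diagram
#'
#' Draws the circular ligand-receptor communication diagram described by a
#' [ChordSpec]: annular sectors for ligand and receptor complexes, radial
#' labels, and translucent ribbons whose width is proportional to the
#' communication score. Alongside the image, a machine-readable geometry
#' sidecar (JSON) is written; all quantitative statements about the figure
#' should be made against that sidecar.
#'
#' @param spec a [ChordSpec].
#' @param file output image path; the device is chosen by extension
#'   (`.svg`, `.pdf` or `.png`).
#' @param geometryFile path of the JSON geometry sidecar; default replaces
#'   the image extension with `.geometry.json`. `NA` skips the sidecar.
#' @param gapDeg,marginDeg layout parameters, see [chordGeometry()].
#' @param width,height device size in inches (pixels / 96 for PNG).
#' @return Invisibly, the geometry list.
#' @examples
#' ds <- generateDataset(SyntheticSpec(seed = 5L))
#' res <- runPipeline(ds$db, ds$deg, ds$sender, ds$receiver)
#' out <- file.path(tempdir(), "chord.svg")
#' geom <- renderChord(ChordSpec(res, topK = 5), out)
#' geom$ribbons
#' @export
renderChord <- function(spec, file, geometryFile = NULL,
                        gapDeg = 2, marginDeg = 8,
                        width = 8, height = 8) {
    geom <- chordGeometry(spec, gapDeg = gapDeg, marginDeg = marginDeg)
    if (is.null(geometryFile))
        geometryFile <- paste0(sub("\\.[A-Za-z]+$", "", file),
                               ".geometry.json")
    ext <- tolower(sub(".*\\.", "", file))
    switch(ext,
        svg = grDevices::svg(file, width = width, height = height),
        pdf = grDevices::pdf(file, width = width, height = height),
        png = grDevices::png(file, width = width * 96, height = height * 96),
        stop("unsupported image format: .", ext, call. = FALSE))
    on.exit(grDevices::dev.off(), add = TRUE)

    op <- graphics::par(mar = c(1, 1, 2, 1))
    on.exit(graphics::par(op), add = TRUE)
    graphics::plot.new()
    graphics::plot.window(c(-1.45, 1.45), c(-1.45, 1.45), asp = 1)

    ligSectors <- geom$sectors[geom$sectors$side == "ligand", ]
    cols <- grDevices::hcl.colors(max(nrow(ligSectors), 2L), "Zissou 1")
    ligCol <- setNames(cols[seq_len(nrow(ligSectors))], ligSectors$name)

    for (i in seq_len(nrow(geom$sectors))) {
        s <- geom$sectors[i, ]
        col <- if (s$side == "ligand") ligCol[[s$name]] else "grey65"
        ring <- rbind(.arcPoints(s$start, s$end, 1.0),
                      .arcPoints(s$end, s$start, 1.08))
        graphics::polygon(ring, col = col, border = "grey30", lwd = 0.5)
        mid <- (s$start + s$end) / 2
        a <- mid * pi / 180
        graphics::text(1.12 * cos(a), 1.12 * sin(a), s$name, cex = 0.6,
                       srt = if (cos(a) < 0) mid + 180 else mid,
                       adj = if (cos(a) < 0) 1 else 0, xpd = NA)
    }
    for (i in seq_len(nrow(geom$ribbons))) {
        rb <- geom$ribbons[i, ]
        col <- grDevices::adjustcolor(ligCol[[rb$ligand]], alpha.f = 0.55)
        pts <- rbind(
            .arcPoints(rb$l_start, rb$l_end, 0.985),
            .bezier(c(cos(rb$l_end * pi / 180), sin(rb$l_end * pi / 180)) * 0.985,
                    c(cos(rb$r_start * pi / 180), sin(rb$r_start * pi / 180)) * 0.985),
            .arcPoints(rb$r_start, rb$r_end, 0.985),
            .bezier(c(cos(rb$r_end * pi / 180), sin(rb$r_end * pi / 180)) * 0.985,
                    c(cos(rb$l_start * pi / 180), sin(rb$l_start * pi / 180)) * 0.985))
        graphics::polygon(pts, col = col, border = NA)
    }
    graphics::text(0, 1.38, geom$params$senderLabel, font = 2, cex = 0.9)
    graphics::text(0, -1.38, geom$params$receiverLabel, font = 2, cex = 0.9)

    if (!is.na(geometryFile))
        jsonlite::write_json(geom, geometryFile, digits = I(17),
                             auto_unbox = TRUE, dataframe = "rows")
    invisible(geom)
}
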