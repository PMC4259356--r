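## Plain-text interchange: chip definitions and reports as TSV, gene
## signatures as GMT, PWMs as MEME-minimal or TRANSFAC matrix text, ledgers
## as JSON. FASTA goes through Biostrings.

#' Read / write a chip definition as TSV
#'
#' Columns: \code{probeset_id}, \code{probe_id}, \code{probe_index},
#' \code{sequence}.
#'
#' @param path file path.
#' @return \code{readChipDefinition} returns a
#'   \linkS4class{ChipDefinition}.
#' @export
readChipDefinition <- function(path) {
    d <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
    chipDefinition(d$probeset_id, d$probe_id, d$probe_index, d$sequence)
}

#' @rdname readChipDefinition
#' @param chip a \linkS4class{ChipDefinition}.
#' @export
writeChipDefinition <- function(chip, path) {
    utils::write.table(as.data.frame(chipProbes(chip)), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Write a cross-hybridization report as TSV
#'
#' @param report a \linkS4class{CrossHybReport}.
#' @param path file path.
#' @param flaggedOnly write only flagged probes.
#' @export
writeCrossHybReport <- function(report, path, flaggedOnly = FALSE) {
    d <- as.data.frame(crossHybTable(report))
    if (flaggedOnly) d <- d[d$flagged, , drop = FALSE]
    d$identity <- sprintf("%.4f", d$identity)
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Read / write gene signatures in GMT format
#'
#' One signature per tab-delimited line: name, description, member symbols.
#' The description field carries \code{species=...;category=...} when
#' written by this package, and is parsed back if present.
#'
#' @param path file path.
#' @return \code{readGMT} returns a named list of
#'   \linkS4class{GeneSignature}s.
#' @export
readGMT <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    sigs <- lapply(lines, function(ln) {
        f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
        if (length(f) < 3L) stop("malformed GMT line: ", substr(ln, 1, 40))
        desc <- f[2]
        species <- sub(".*species=([^;]+).*", "\\1", desc)
        category <- sub(".*category=([^;]+).*", "\\1", desc)
        if (identical(species, desc)) species <- "mouse"
        if (identical(category, desc)) category <- "uncategorized"
        geneSignature(name = f[1], species = species, category = category,
                      symbols = f[-(1:2)], provenance = desc)
    })
    stats::setNames(sigs, vapply(sigs, function(s) s@name, character(1)))
}

#' @rdname readGMT
#' @param signatures list of \linkS4class{GeneSignature}s.
#' @export
writeGMT <- function(signatures, path) {
    lines <- vapply(signatures, function(s)
        paste(c(s@name,
                sprintf("species=%s;category=%s", s@species, s@category),
                s@symbols), collapse = "\t"), character(1))
    writeLines(lines, path)
    invisible(path)
}

#' Read position weight matrices from MEME minimal format
#'
#' Parses \code{MOTIF} blocks with their letter-probability matrices
#' (alphabet ACGT).
#'
#' @param path file path.
#' @param scoreThreshold hit threshold passed to every
#'   \linkS4class{MotifModel}.
#' @return named list of \linkS4class{MotifModel}s.
#' @export
readMemeMotifs <- function(path, scoreThreshold = 0.8) {
    lines <- readLines(path)
    starts <- grep("^MOTIF\\b", lines)
    if (!length(starts)) stop("no MOTIF blocks found")
    motifs <- lapply(starts, function(i) {
        name <- strsplit(trimws(lines[i]), "\\s+")[[1]][2]
        j <- i + 1L
        while (j <= length(lines) &&
               !grepl("^letter-probability matrix", lines[j])) j <- j + 1L
        if (j > length(lines))
            stop("MOTIF without letter-probability matrix: ", name)
        w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j]))
        rows <- lines[(j + 1L):(j + w)]
        m <- t(vapply(rows, function(r)
            as.numeric(strsplit(trimws(r), "\\s+")[[1]]), numeric(4)))
        motifModel(name, t(m), scoreThreshold = scoreThreshold)
    })
    stats::setNames(motifs, vapply(motifs, function(m) m@name, character(1)))
}

#' @rdname readMemeMotifs
#' @param motifs list of \linkS4class{MotifModel}s.
#' @export
writeMemeMotifs <- function(motifs, path) {
    out <- c("MEME version 4", "", "ALPHABET= ACGT", "")
    for (m in motifs) {
        out <- c(out, paste("MOTIF", m@name),
                 sprintf("letter-probability matrix: alength= 4 w= %d",
                         motifWidth(m)),
                 apply(m@matrix, 2, function(col)
                     paste(sprintf("%.6f", col), collapse = " ")),
                 "")
    }
    writeLines(out, path)
    invisible(path)
}

#' Read position weight matrices from TRANSFAC matrix text
#'
#' Parses \code{ID}/\code{P0}-style blocks (numbered rows of A C G T counts
#' or frequencies, terminated by \code{//}); counts are normalized to
#' per-column probabilities.
#'
#' @inheritParams readMemeMotifs
#' @return named list of \linkS4class{MotifModel}s.
#' @export
readTransfacMotifs <- function(path, scoreThreshold = 0.8) {
    lines <- readLines(path)
    ids <- grep("^ID\\s+", lines)
    if (!length(ids)) stop("no TRANSFAC ID blocks found")
    ends <- c(ids[-1] - 1L, length(lines))
    motifs <- lapply(seq_along(ids), function(b) {
        block <- lines[ids[b]:ends[b]]
        name <- sub("^ID\\s+", "", block[1])
        rows <- grep("^\\s*\\d+\\s", block, value = TRUE)
        if (!length(rows)) stop("TRANSFAC block without matrix rows: ", name)
        m <- t(vapply(rows, function(r) {
            f <- strsplit(trimws(r), "\\s+")[[1]]
            as.numeric(f[2:5])
        }, numeric(4)))
        probs <- t(m / rowSums(m))
        motifModel(name, probs, scoreThreshold = scoreThreshold)
    })
    stats::setNames(motifs, vapply(motifs, function(m) m@name, character(1)))
}

#' Write a curation ledger as JSON (and optionally a readable TSV)
#'
#' @param ledger a \linkS4class{CurationLedger}.
#' @param path JSON output path.
#' @param tsvPath optional path for a per-stage summary TSV.
#' @export
writeCurationLedger <- function(ledger, path, tsvPath = NULL) {
    obj <- list(
        start = ledger@start,
        stages = lapply(ledger@stages, function(st)
            list(category = st$category,
                 signatures = st$signatures,
                 removed = st$removed,
                 n_removed = length(st$removed),
                 n_remaining = length(st$remaining))),
        components = ledgerComponents(ledger),
        fractions = as.list(ledgerFractions(ledger)))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = 10)
    if (!is.null(tsvPath)) {
        d <- data.frame(
            stage = seq_along(ledger@stages),
            category = vapply(ledger@stages, `[[`, character(1), "category"),
            n_removed = vapply(ledger@stages,
                               function(s) length(s$removed), integer(1)),
            n_remaining = vapply(ledger@stages,
                                 function(s) length(s$remaining), integer(1)))
        utils::write.table(d, tsvPath, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    }
    invisible(path)
}
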