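## Cross-species probe masking: identify probes that cross-hybridize to the
## off-target species' transcriptome and redefine probe-sets to contain only
## species-specific probes. A probe is flagged when its longest contiguous
## exact off-target match reaches Lmin nt OR its best ungapped full-probe
## identity at any offset reaches Imin, on either strand. The computational
## core is a two-level k-mer seed-and-extend scanner (see src/crosshyb.cpp);
## correctness is pinned to a brute-force oracle in the test suite.

asTranscriptVector <- function(offtarget) {
    if (is(offtarget, "DNAStringSet")) {
        x <- as.character(offtarget)
        if (is.null(names(x))) names(x) <- sprintf("tx%04d", seq_along(x))
        x
    } else if (is.character(offtarget)) {
        if (is.null(names(offtarget)))
            names(offtarget) <- sprintf("tx%04d", seq_along(offtarget))
        offtarget
    } else {
        stop("off-target transcripts must be a DNAStringSet or character vector")
    }
}

#' Longest contiguous exact off-target match of a probe
#'
#' Length (nt) of the longest substring of \code{probe} (or, with
#' \code{bothStrands}, of its reverse complement) occurring exactly in any
#' off-target transcript. Returns 0 for an empty transcript set. Matches
#' shorter than 6 nt are below the scanner's resolution and reported as the
#' best value found (at most 5), which is far below any masking threshold.
#'
#' @param probe a single probe sequence (uppercase ACGT).
#' @param offtarget off-target transcripts (\code{DNAStringSet} or character
#'   vector).
#' @param bothStrands scan the reverse complement of the transcripts as well.
#' @return integer match length in nt.
#' @examples
#' longestOfftargetMatch("ACGTACGTACGTACGTACGTACGTA",
#'                       c(tx1 = "TTTTACGTACGTACGTACGTACGTACGTATTTT"))
#' @export
longestOfftargetMatch <- function(probe, offtarget, bothStrands = TRUE) {
    stopifnot(length(probe) == 1L, nchar(probe) >= 1L)
    if (!grepl("^[ACGT]+$", probe))
        stop("probe contains non-ACGT characters")
    tx <- asTranscriptVector(offtarget)
    if (!length(tx)) return(0L)
    hit <- .crossHybScanCpp(probe, unname(tx), bothStrands = bothStrands,
                            computeIdentity = FALSE)
    hit$match_len[1]
}

#' Scan a chip definition for cross-hybridizing probes
#'
#' Scores every probe against the off-target transcript set and flags those
#' with a contiguous exact match of at least \code{Lmin} nt or an ungapped
#' full-probe identity of at least \code{Imin} at any alignment offset
#' (either strand). Probes containing N are flagged conservatively.
#'
#' @param chip a \linkS4class{ChipDefinition}.
#' @param offtarget off-target transcripts (\code{DNAStringSet} or character
#'   vector).
#' @param Lmin contiguous-match flag threshold in nt (default 15).
#' @param Imin identity flag threshold over the full probe (default 0.80).
#' @param bothStrands scan the reverse complement as well (default TRUE).
#' @return a \linkS4class{CrossHybReport}.
#' @export
scanCrossHybridization <- function(chip, offtarget, Lmin = 15L, Imin = 0.80,
                                   bothStrands = TRUE) {
    stopifnot(is(chip, "ChipDefinition"))
    probes <- chipProbes(chip)
    if (nrow(probes) == 0L) stop("empty chip definition")
    plen <- nchar(probes$sequence)
    if (Lmin < 1L || Lmin > max(plen))
        stop("Lmin must satisfy 1 <= Lmin <= probe length")
    if (Imin <= 0 || Imin > 1) stop("Imin must be in (0, 1]")
    tx <- asTranscriptVector(offtarget)

    hasN <- grepl("N", probes$sequence, fixed = TRUE)
    if (length(tx)) {
        hit <- .crossHybScanCpp(probes$sequence, unname(tx),
                                bothStrands = bothStrands,
                                computeIdentity = TRUE)
        matchLen <- hit$match_len
        identity <- hit$identity
        partner <- names(tx)[hit$partner]
    } else {
        matchLen <- integer(nrow(probes))
        identity <- numeric(nrow(probes))
        partner <- rep(NA_character_, nrow(probes))
    }
    flagged <- (matchLen >= Lmin) | (identity >= Imin) | hasN
    new("CrossHybReport",
        report = DataFrame(probe_id = probes$probe_id,
                           match_len = matchLen,
                           identity = identity,
                           flagged = flagged,
                           partner = partner),
        params = list(Lmin = as.integer(Lmin), Imin = Imin,
                      bothStrands = bothStrands))
}

#' Redefine probe-sets from a cross-hybridization report
#'
#' Removes flagged probes from every probe-set, preserving probe order, and
#' drops probe-sets left with fewer than \code{minProbes} survivors.
#'
#' @param chip a \linkS4class{ChipDefinition}.
#' @param report the matching \linkS4class{CrossHybReport}.
#' @param minProbes minimum retained probes for a probe-set to survive
#'   (default 4).
#' @return a \linkS4class{MaskedChipDefinition}.
#' @export
redefineProbesets <- function(chip, report, minProbes = 4L) {
    stopifnot(is(chip, "ChipDefinition"), is(report, "CrossHybReport"),
              minProbes >= 1L)
    probes <- chipProbes(chip)
    rpt <- crossHybTable(report)
    flag <- rpt$flagged[match(probes$probe_id, rpt$probe_id)]
    if (anyNA(flag))
        stop("report does not cover every probe in the chip definition")

    keep <- split(probes$probe_id[!flag], probes$probeset_id[!flag])
    nOrig <- table(probes$probeset_id)
    allSets <- unique(probes$probeset_id)
    nKept <- stats::setNames(integer(length(allSets)), allSets)
    nKept[names(keep)] <- lengths(keep)

    drop <- nKept < minProbes
    reason <- ifelse(nKept[drop] == 0L,
                     "all probes cross-hybridizing",
                     sprintf("fewer than %d probes retained", minProbes))
    dropped <- DataFrame(probeset_id = allSets[drop[allSets]],
                         reason = unname(reason[allSets[drop[allSets]]]))
    survivors <- allSets[!drop[allSets]]
    new("MaskedChipDefinition",
        probesets = keep[survivors],
        dropped = dropped,
        params = list(Lmin = report@params$Lmin, Imin = report@params$Imin,
                      minProbes = as.integer(minProbes)))
}

#' One-call masking: scan and redefine
#'
#' @inheritParams scanCrossHybridization
#' @inheritParams redefineProbesets
#' @return list with \code{report} and \code{masked}.
#' @export
maskChip <- function(chip, offtarget, Lmin = 15L, Imin = 0.80,
                     minProbes = 4L, bothStrands = TRUE) {
    report <- scanCrossHybridization(chip, offtarget, Lmin = Lmin,
                                     Imin = Imin, bothStrands = bothStrands)
    list(report = report,
         masked = redefineProbesets(chip, report, minProbes = minProbes))
}
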