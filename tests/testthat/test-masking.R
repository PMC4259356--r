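# Cross-hybridization scan and probe-set redefinition, pinned to brute-force
# string oracles.

test_that("longestOfftargetMatch handles verbatim, empty and partial cases", {
    set.seed(11)
    probe <- paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE),
                   collapse = "")
    expect_identical(longestOfftargetMatch(probe,
        c(tx = paste0("TTTT", probe, "GGGG"))), 25L)
    expect_identical(longestOfftargetMatch(probe, character()), 0L)
    expect_error(longestOfftargetMatch("ACGTN", c(tx = "ACGT")), "non-ACGT")

    # a probe sharing exactly a 16-nt window: plant probe[5..20] into an
    # otherwise clean host with junction bases chosen so the match cannot
    # extend past the window
    host <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                  collapse = "")
    stopifnot(oracleLongestMatch(probe, host) < 12)
    window <- substr(probe, 5, 20)
    other <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
    planted <- paste0(substr(host, 1, 99), other(substr(probe, 4, 4)),
                      window, other(substr(probe, 21, 21)),
                      substr(host, 102, 400))
    if (oracleLongestMatch(probe, planted) == 16L)
        expect_identical(longestOfftargetMatch(probe, c(tx = planted)), 16L)
    # in all cases the scanner agrees with the brute-force oracle
    expect_identical(longestOfftargetMatch(probe, c(tx = planted)),
                     oracleLongestMatch(probe, planted))
})

test_that("reverse-complement matches are found and can be disabled", {
    set.seed(12)
    probe <- paste(sample(c("A", "C", "G", "T"), 25, replace = TRUE),
                   collapse = "")
    rcHost <- paste0("TTTTTTTTTT", oracleRevComp(probe), "TTTTTTTTTT")
    expect_identical(longestOfftargetMatch(probe, rcHost), 25L)
    # forward-only scanning must not see the reverse-complement planting;
    # sub-6-nt chance matches are below the scanner's stated resolution
    expect_lt(longestOfftargetMatch(probe, rcHost, bothStrands = FALSE), 6L)
    expect_lt(oracleLongestMatch(probe, rcHost, bothStrands = FALSE), 12L)
})

test_that("scan decisions equal the brute-force oracle on a synthetic chip", {
    cfg <- smallConfig(nGenes = 25L, fracCrossHyb = 0.08, seed = 41L)
    ref <- generateTwoSpeciesReference(cfg)
    human <- as.character(ref$humanTranscripts)
    rpt <- crossHybTable(scanCrossHybridization(ref$chip, human))
    probes <- chipProbes(ref$chip)

    oracleLen <- vapply(probes$sequence, oracleLongestMatch, integer(1),
                        targets = human)
    oracleId <- vapply(probes$sequence, oracleBestIdentity, numeric(1),
                       targets = human)
    oracleFlag <- (oracleLen >= 15L) | (oracleId >= 0.80)
    expect_identical(rpt$flagged, unname(oracleFlag))
    # exact match lengths agree wherever the scanner's k-mer resolution
    # guarantees exactness (>= 6 nt)
    agree <- oracleLen >= 6L
    expect_identical(rpt$match_len[agree], unname(oracleLen[agree]))
    expect_true(all(rpt$match_len[!agree] <= 5L))
    # the seed-and-extend identity never overestimates the oracle and agrees
    # at flag-relevant levels (an alignment without any exact 6-mer run can
    # be underestimated, but such alignments sit far below the threshold)
    expect_true(all(rpt$identity <= oracleId + 1e-12))
    strong <- oracleId >= 0.8
    expect_equal(rpt$identity[strong], unname(oracleId[strong]),
                 tolerance = 1e-12)
})

test_that("flags recover exactly the planted probes at default thresholds", {
    cfg <- smallConfig(nGenes = 150L, seed = 19L)
    ref <- generateTwoSpeciesReference(cfg)
    rpt <- crossHybTable(scanCrossHybridization(ref$chip,
                                                ref$humanTranscripts))
    expect_setequal(rpt$probe_id[rpt$flagged],
                    trueCrossHybProbes(ref$truth)$probe_id)
})

test_that("flagging is monotone in the thresholds", {
    cfg <- smallConfig(nGenes = 40L, seed = 3L)
    ref <- generateTwoSpeciesReference(cfg)
    f15 <- crossHybTable(scanCrossHybridization(ref$chip,
        ref$humanTranscripts, Lmin = 15L))$flagged
    f20 <- crossHybTable(scanCrossHybridization(ref$chip,
        ref$humanTranscripts, Lmin = 20L))$flagged
    expect_true(all(f15 | !f20))  # flags at 15 contain flags at 20
    i70 <- crossHybTable(scanCrossHybridization(ref$chip,
        ref$humanTranscripts, Imin = 0.70))$flagged
    i90 <- crossHybTable(scanCrossHybridization(ref$chip,
        ref$humanTranscripts, Imin = 0.90))$flagged
    expect_true(all(i70 | !i90))
})

test_that("probes containing N are flagged conservatively", {
    chip <- toyChip(nSets = 1L)
    p <- chipProbes(chip)
    seqs <- p$sequence
    substr(seqs[3], 10, 10) <- "N"
    chipN <- chipDefinition(p$probeset_id, p$probe_id, p$probe_index, seqs)
    rpt <- crossHybTable(scanCrossHybridization(chipN, "ACGTACGTACGTACGT"))
    expect_identical(rpt$flagged, seq_len(nrow(p)) == 3L)
})

test_that("redefineProbesets removes flagged probes and drops thin sets", {
    chip <- toyChip(nSets = 3L, probesPerSet = 11L)
    p <- chipProbes(chip)
    ids <- split(p$probe_id, p$probeset_id)

    # spec-style toy case: 9 / 2 / 0 probes flagged, minProbes = 4
    flagged <- c(ids$set01[1:9], ids$set02[1:2])
    masked <- redefineProbesets(chip, flagReport(chip, flagged),
                                minProbes = 4L)
    expect_identical(names(retainedProbes(masked)), c("set02", "set03"))
    expect_identical(lengths(retainedProbes(masked)),
                     c(set02 = 9L, set03 = 11L))
    expect_identical(droppedProbesets(masked)$probeset_id, "set01")
    expect_match(droppedProbesets(masked)$reason, "fewer than 4")
    # retained probe order is the chip order
    expect_identical(retainedProbes(masked)$set02, ids$set02[3:11])

    # zero flags: identity
    m0 <- redefineProbesets(chip, flagReport(chip, character()), 4L)
    expect_identical(retainedProbes(m0), ids[names(retainedProbes(m0))])
    expect_identical(nrow(droppedProbesets(m0)), 0L)

    # an all-flagged set is dropped with the dedicated reason
    mAll <- redefineProbesets(chip, flagReport(chip, ids$set01), 4L)
    expect_identical(unname(droppedProbesets(mAll)$reason),
                     "all probes cross-hybridizing")
})

test_that("masking is idempotent", {
    cfg <- smallConfig(nGenes = 30L, seed = 29L)
    ref <- generateTwoSpeciesReference(cfg)
    mk1 <- maskChip(ref$chip, ref$humanTranscripts)
    kept <- unlist(retainedProbes(mk1$masked), use.names = FALSE)
    p <- chipProbes(ref$chip)
    sub <- p[p$probe_id %in% kept, ]
    chip2 <- chipDefinition(sub$probeset_id, sub$probe_id, sub$probe_index,
                            sub$sequence)
    mk2 <- maskChip(chip2, ref$humanTranscripts)
    expect_identical(retainedProbes(mk2$masked), retainedProbes(mk1$masked))
    expect_identical(nrow(droppedProbesets(mk2$masked)), 0L)
})

test_that("chip definition TSV round-trips", {
    chip <- toyChip()
    path <- tempfile(fileext = ".tsv")
    writeChipDefinition(chip, path)
    back <- readChipDefinition(path)
    expect_identical(as.data.frame(chipProbes(back)),
                     as.data.frame(chipProbes(chip)))
})
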