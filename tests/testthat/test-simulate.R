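# Synthetic two-species generator: determinism, planted cross-hybridization
# structure, mixed-signal intensity model, signature registry.

test_that("identical config and seed give byte-identical outputs", {
    cfg <- smallConfig(seed = 17L)
    a <- generateTwoSpeciesReference(cfg)
    b <- generateTwoSpeciesReference(cfg)
    expect_identical(as.character(a$mouseTranscripts),
                     as.character(b$mouseTranscripts))
    expect_identical(as.character(a$humanTranscripts),
                     as.character(b$humanTranscripts))
    expect_identical(as.data.frame(chipProbes(a$chip)),
                     as.data.frame(chipProbes(b$chip)))
    expect_identical(as.data.frame(trueCrossHybProbes(a$truth)),
                     as.data.frame(trueCrossHybProbes(b$truth)))
    expect_identical(as.data.frame(trueDEGenes(a$truth)),
                     as.data.frame(trueDEGenes(b$truth)))
    simA <- simulateExperiment(cfg, a$chip, a$truth)
    simB <- simulateExperiment(cfg, b$chip, b$truth)
    expect_identical(simA$intensities, simB$intensities)
    expect_identical(simA$design, simB$design)
})

test_that("no cross-hybridization is planted when the fraction is zero", {
    ref <- generateTwoSpeciesReference(smallConfig(fracCrossHyb = 0))
    expect_identical(nrow(trueCrossHybProbes(ref$truth)), 0L)
})

test_that("planted probes carry their match and unplanted probes are clean (brute-force oracle)", {
    cfg <- smallConfig(nGenes = 40L, seed = 23L)
    ref <- generateTwoSpeciesReference(cfg)
    human <- as.character(ref$humanTranscripts)
    probes <- chipProbes(ref$chip)
    truth <- trueCrossHybProbes(ref$truth)

    for (i in seq_len(nrow(truth))) {
        got <- oracleLongestMatch(
            probes$sequence[match(truth$probe_id[i], probes$probe_id)],
            human)
        expect_gte(got, min(truth$match_len[i], cfg@plantMinLen))
    }
    unplanted <- setdiff(probes$probe_id, truth$probe_id)
    # oracle is O(probes x transcriptome); a seed-fixed subsample suffices
    set.seed(1)
    for (pid in sample(unplanted, 40)) {
        expect_lt(oracleLongestMatch(
            probes$sequence[match(pid, probes$probe_id)], human), 12L)
    }
})

test_that("probe geometry follows the configuration", {
    cfg <- smallConfig(nGenes = 15L, probesPerSet = 8L, probeLength = 20L)
    ref <- generateTwoSpeciesReference(cfg)
    p <- chipProbes(ref$chip)
    expect_identical(nrow(p), 15L * 8L)
    expect_true(all(nchar(p$sequence) == 20L))
    expect_identical(as.integer(table(p$probeset_id)[probesetIds(ref$chip)]),
                     rep(8L, 15L))
    # probes are exact substrings of their gene's transcript
    mouse <- as.character(ref$mouseTranscripts)
    expect_true(all(mapply(function(s, g) grepl(s, mouse[g], fixed = TRUE),
                           p$sequence, p$probeset_id)))
})

test_that("noise- and contamination-free intensities reproduce true log2FC exactly", {
    cfg <- smallConfig(nGenes = 50L, contaminationCoef = 0, noiseSD = 0,
                       seed = 9L)
    ref <- generateTwoSpeciesReference(cfg)
    sim <- simulateExperiment(cfg, ref$chip, ref$truth)
    de <- trueDEGenes(ref$truth)
    probes <- chipProbes(ref$chip)
    xeno <- sim$design$sample_id[sim$design$group == "C4-2B"][1]
    sham <- sim$design$sample_id[sim$design$group == "sham"][1]
    diffs <- log2(sim$intensities[, xeno]) - log2(sim$intensities[, sham])
    for (i in seq_len(nrow(de))) {
        pids <- probes$probe_id[probes$probeset_id == de$gene[i]]
        expect_equal(unname(diffs[pids]), rep(de$log2fc[i], length(pids)),
                     tolerance = 1e-12)
    }
    nullGenes <- setdiff(probes$probeset_id, de$gene)
    expect_equal(max(abs(diffs[probes$probeset_id %in% nullGenes])), 0)

    # and exactly through masking + summarization
    mk <- maskChip(ref$chip, ref$humanTranscripts)
    expr <- preprocessIntensities(sim$intensities, mk$masked,
                                  design = sim$design, normalize = "none")
    e <- SummarizedExperiment::assay(expr, "exprs")
    summaryDiff <- e[de$gene, xeno] - e[de$gene, sham]
    expect_equal(unname(summaryDiff), de$log2fc, tolerance = 1e-12)
})

test_that("cross-hybridizing probes gain more signal at higher human fractions", {
    cfg <- smallConfig(nGenes = 60L, noiseSD = 0, fracDE = 0, seed = 31L)
    ref <- generateTwoSpeciesReference(cfg)
    sim <- simulateExperiment(cfg, ref$chip, ref$truth)
    ch <- trueCrossHybProbes(ref$truth)$probe_id
    oneToOne <- sim$design$sample_id[sim$design$group == "C4-2B"][1]
    oneToNine <- sim$design$sample_id[sim$design$group == "PC-3"][1]
    # no DE and no noise: mouse abundance is equal across groups, so the
    # difference on planted probes is purely the ratio-scaled human bleed
    expect_true(all(sim$intensities[ch, oneToOne] >
                    sim$intensities[ch, oneToNine]))
    unpl <- setdiff(rownames(sim$intensities), ch)
    expect_equal(sim$intensities[unpl, oneToOne],
                 sim$intensities[unpl, oneToNine])
})

test_that("the default design has triplicate groups except duplicate sham and Ep156T", {
    cfg <- smallConfig()
    ref <- generateTwoSpeciesReference(cfg)
    sim <- simulateExperiment(cfg, ref$chip, ref$truth)
    tab <- table(sim$design$group)
    expect_identical(as.integer(tab[c("C4-2B", "VCaP", "PC-3", "intact")]),
                     rep(3L, 4))
    expect_identical(as.integer(tab[c("sham", "Ep156T")]), rep(2L, 2))
    expect_identical(
        unique(sim$design$mixing_ratio[sim$design$group == "VCaP"]), "1:5")
    expect_identical(
        unique(sim$design$mixing_ratio[sim$design$group == "sham"]), "0:1")
})

test_that("a group in the ratio map but not the design is rejected", {
    cfg <- smallConfig(mixingRatios = c("C4-2B" = "1:1", "ghost" = "1:2"))
    ref <- generateTwoSpeciesReference(cfg)
    expect_error(simulateExperiment(cfg, ref$chip, ref$truth), "ghost")
})

test_that("signature registry overlaps are planted as requested and the expected ledger is exact", {
    cfg <- smallConfig(nGenes = 200L, fracDE = 0.25, seed = 13L)
    ref <- generateTwoSpeciesReference(cfg)
    de <- trueDEGenes(ref$truth)$gene
    reg <- generateSignatureRegistry(ref$truth, cfg)
    led <- reg$expectedLedger
    expect_identical(sort(led@start), sort(de))
    nDE <- length(de)
    removedCounts <- vapply(ledgerStages(led),
                            function(s) length(s$removed), integer(1))
    expect_identical(unname(removedCounts),
                     as.integer(round(c(0.10, 0.08, 0.09) * nDE)))
    # running the curation op on the registry reproduces the expected ledger
    got <- curate(de, reg$signatures, order = reg$order)
    expect_identical(ledgerComponents(got), ledgerComponents(led))

    # degenerate cases: no overlap, and total overlap at stage one
    regNone <- generateSignatureRegistry(ref$truth, cfg,
        overlapFracs = c("inflammatory" = 0, "non-osteotropic" = 0,
                         "osteotropic" = 0))
    expect_identical(sort(ledgerComponents(regNone$expectedLedger)$core),
                     sort(de))
    regAll <- generateSignatureRegistry(ref$truth, cfg,
        overlapFracs = c("inflammatory" = 1, "non-osteotropic" = 0,
                         "osteotropic" = 0))
    ledAll <- regAll$expectedLedger
    expect_identical(ledgerComponents(ledAll)$core, character(0))
    expect_identical(length(ledgerStages(ledAll)$inflammatory$removed), nDE)
})

test_that("promoter generation respects window, planting rates and strand", {
    motif <- defaultQueryMotif()
    prom <- generatePromoters(sprintf("c%03d", 1:150),
                              sprintf("b%03d", 1:150),
                              motif, 1.0, 0.0, windowNt = 2000L, seed = 3L)
    expect_identical(length(prom), 300L)
    expect_true(all(Biostrings::width(prom) == 2000L))
    hits <- scanMotif(prom, motif)
    expect_true(all(hits[1:150] >= 1L))          # rate 1: always planted
    expect_lt(mean(hits[151:300] >= 1L), 0.05)   # rate 0: chance hits only
    expect_error(generatePromoters("g1", "g2", motif, 0.5, 0.5,
                                   windowNt = 10L),
                 "width")
})

test_that("invalid configurations are rejected", {
    expect_error(simulationConfig(fracDE = 1.5), "fracDE")
    expect_error(simulationConfig(nGenes = 0), "nGenes")
    expect_error(simulationConfig(noiseSD = -1), "noiseSD")
    expect_error(simulationConfig(mixingRatios = c(m = "x")), "mixingRatios")
})
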