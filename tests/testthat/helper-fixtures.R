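# Shared small fixtures, built in code.

smallConfig <- function(nGenes = 60L, seed = 7L, ...) {
    simulationConfig(nGenes = nGenes, seed = seed, ...)
}

# a 3-set toy chip with explicit sequences
toyChip <- function(nSets = 3L, probesPerSet = 11L, probeLength = 25L,
                    seed = 5L) {
    set.seed(seed)
    n <- nSets * probesPerSet
    seqs <- vapply(seq_len(n), function(i)
        paste(sample(c("A", "C", "G", "T"), probeLength, replace = TRUE),
              collapse = ""), character(1))
    chipDefinition(
        probesetId = rep(sprintf("set%02d", seq_len(nSets)),
                         each = probesPerSet),
        probeId = sprintf("set%02d_p%02d",
                          rep(seq_len(nSets), each = probesPerSet),
                          rep(seq_len(probesPerSet), nSets)),
        probeIndex = rep(seq_len(probesPerSet), nSets),
        sequence = seqs)
}

# a report flagging chosen probes of a chip
flagReport <- function(chip, flaggedIds, Lmin = 15L, Imin = 0.8) {
    p <- chipProbes(chip)
    new("CrossHybReport",
        report = S4Vectors::DataFrame(
            probe_id = p$probe_id,
            match_len = ifelse(p$probe_id %in% flaggedIds, Lmin, 0L),
            identity = 0,
            flagged = p$probe_id %in% flaggedIds,
            partner = NA_character_),
        params = list(Lmin = Lmin, Imin = Imin, bothStrands = TRUE))
}
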