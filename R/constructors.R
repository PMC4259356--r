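## Constructors, accessors and show methods.

#' Create a simulation configuration
#'
#' Defaults reproduce the study conditions the generator emulates: 11-probe
#' sets of 25-mers, a minority (10\%) of truly differentially expressed stroma
#' genes at |log2FC| 1.5 with 64\% up-regulated, 5\% cross-hybridizing probes,
#' human:mouse RNA ratios of 1:1 (C4-2B), 1:5 (VCaP), 1:9 (PC-3), 4:1
#' (subcutaneous) and 1:2 (orthotopic) xenografts, and three replicates per
#' group except sham and Ep156T controls (duplicates).
#'
#' @param nGenes genes per species.
#' @param probesPerSet probes per probe-set.
#' @param probeLength probe length (nt).
#' @param fracDE fraction of mouse genes differentially expressed.
#' @param effectMean,effectSD |log2FC| magnitude distribution.
#' @param fracUp fraction of effects that are up-regulated.
#' @param fracCrossHyb fraction of probes with a planted off-target match.
#' @param contaminationCoef off-target bleed-through coefficient in [0, 1].
#' @param mixingRatios named "human:mouse" ratio per xenograft model.
#' @param replicates named replicate count per group.
#' @param noiseSD log2-scale noise sd.
#' @param plantMinLen,plantMaxLen planted match length range (nt).
#' @param flankLength untiled random flank per transcript end (nt).
#' @param seed integer seed.
#' @return A \linkS4class{SimulationConfig}.
#' @examples
#' cfg <- simulationConfig(nGenes = 50, seed = 1)
#' cfg
#' @export
simulationConfig <- function(nGenes = 1000L,
                             probesPerSet = 11L,
                             probeLength = 25L,
                             fracDE = 0.1,
                             effectMean = 1.5,
                             effectSD = 0,
                             fracUp = 0.64,
                             fracCrossHyb = 0.05,
                             contaminationCoef = 0.5,
                             mixingRatios = c("C4-2B" = "1:1",
                                              "VCaP" = "1:5",
                                              "PC-3" = "1:9",
                                              "subcut" = "4:1",
                                              "ortho" = "1:2"),
                             replicates = c("C4-2B" = 3L, "VCaP" = 3L,
                                            "PC-3" = 3L, "subcut" = 3L,
                                            "ortho" = 3L, "intact" = 3L,
                                            "sham" = 2L, "Ep156T" = 2L),
                             noiseSD = 0.25,
                             plantMinLen = 15L,
                             plantMaxLen = probeLength,
                             flankLength = 20L,
                             seed = 1L) {
    new("SimulationConfig",
        nGenes = as.integer(nGenes),
        probesPerSet = as.integer(probesPerSet),
        probeLength = as.integer(probeLength),
        fracDE = fracDE, effectMean = effectMean, effectSD = effectSD,
        fracUp = fracUp, fracCrossHyb = fracCrossHyb,
        contaminationCoef = contaminationCoef,
        mixingRatios = mixingRatios,
        replicates = vapply(replicates, as.integer, integer(1)),
        noiseSD = noiseSD,
        plantMinLen = as.integer(plantMinLen),
        plantMaxLen = as.integer(plantMaxLen),
        flankLength = as.integer(flankLength),
        seed = as.integer(seed))
}

#' Create a chip definition
#'
#' @param probesetId,probeId,probeIndex,sequence parallel vectors describing
#'   every probe on the chip.
#' @return A \linkS4class{ChipDefinition}.
#' @export
chipDefinition <- function(probesetId, probeId, probeIndex, sequence) {
    new("ChipDefinition",
        probes = DataFrame(probeset_id = as.character(probesetId),
                           probe_id = as.character(probeId),
                           probe_index = as.integer(probeIndex),
                           sequence = as.character(sequence)))
}

#' @describeIn chipDefinition probe table accessor.
#' @param x a \code{ChipDefinition}.
#' @export
chipProbes <- function(x) x@probes

#' @describeIn chipDefinition probe-set ids on the chip.
#' @export
probesetIds <- function(x) unique(x@probes$probeset_id)

#' Accessors for masked chip definitions
#'
#' @param x a \linkS4class{MaskedChipDefinition}.
#' @return \code{retainedProbes} returns the named list probeset -> retained
#'   probe ids; \code{droppedProbesets} the drop table; \code{maskingParams}
#'   the parameter list.
#' @export
retainedProbes <- function(x) x@probesets

#' @rdname retainedProbes
#' @export
droppedProbesets <- function(x) x@dropped

#' @rdname retainedProbes
#' @export
maskingParams <- function(x) x@params

#' Accessor for cross-hybridization reports
#'
#' @param x a \linkS4class{CrossHybReport}.
#' @return the per-probe report \code{DataFrame}.
#' @export
crossHybTable <- function(x) x@report

#' Accessors for ground truth objects
#'
#' @param x a \linkS4class{GroundTruth}.
#' @return \code{trueDEGenes} returns the per-gene truth table;
#'   \code{trueCrossHybProbes} the planted cross-hybridizing probes.
#' @export
trueDEGenes <- function(x) x@deGenes

#' @rdname trueDEGenes
#' @export
trueCrossHybProbes <- function(x) x@crossHybProbes

#' Create a variance prior
#'
#' @param d0 prior degrees of freedom (may be \code{Inf}).
#' @param s0sq prior variance.
#' @param df residual degrees of freedom per gene.
#' @return A \linkS4class{VariancePrior}.
#' @export
variancePrior <- function(d0, s0sq, df = NA_real_) {
    new("VariancePrior", d0 = d0, s0sq = s0sq, df = df)
}

#' Create a motif model
#'
#' @param name motif name.
#' @param matrix 4 x width probability matrix (rows A, C, G, T).
#' @param scoreThreshold hit threshold as a fraction of the maximum log-odds
#'   score.
#' @return A \linkS4class{MotifModel}.
#' @export
motifModel <- function(name, matrix, scoreThreshold = 0.8) {
    dimnames(matrix) <- list(c("A", "C", "G", "T"), NULL)
    new("MotifModel", name = name, matrix = matrix,
        scoreThreshold = scoreThreshold)
}

#' @describeIn motifModel motif width (nt).
#' @param x a \code{MotifModel}.
#' @export
motifWidth <- function(x) ncol(x@matrix)

#' @describeIn motifModel consensus sequence (max-probability base per
#'   column).
#' @export
motifConsensus <- function(x) {
    paste(rownames(x@matrix)[apply(x@matrix, 2, which.max)], collapse = "")
}

#' Accessors for curation ledgers
#'
#' @param x a \linkS4class{CurationLedger}.
#' @return \code{ledgerComponents} returns the named component list (core
#'   plus one entry per subtraction category); \code{ledgerStages} the ordered
#'   stage records; \code{ledgerFractions} component fractions of the start
#'   set.
#' @export
ledgerComponents <- function(x) x@components

#' @rdname ledgerComponents
#' @export
ledgerStages <- function(x) x@stages

#' @rdname ledgerComponents
#' @export
ledgerFractions <- function(x) x@fractions

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig\n")
    cat(sprintf("  %d genes/species, %d x %d-mer probes per set\n",
                object@nGenes, object@probesPerSet, object@probeLength))
    cat(sprintf("  DE: %.0f%% of genes, |log2FC| ~ (%.2g, %.2g), %.0f%% up\n",
                100 * object@fracDE, object@effectMean, object@effectSD,
                100 * object@fracUp))
    cat(sprintf("  cross-hyb: %.1f%% of probes, contamination %.2g, noise sd %.2g\n",
                100 * object@fracCrossHyb, object@contaminationCoef,
                object@noiseSD))
    cat("  mixing ratios:",
        paste(names(object@mixingRatios), object@mixingRatios,
              sep = "=", collapse = ", "), "\n")
    cat("  replicates:",
        paste(names(object@replicates), object@replicates,
              sep = "=", collapse = ", "), "\n")
    cat(sprintf("  seed %d\n", object@seed))
})

setMethod("show", "ChipDefinition", function(object) {
    cat(sprintf("ChipDefinition: %d probes in %d probe-sets (%d-mers)\n",
                nrow(object@probes), length(probesetIds(object)),
                nchar(object@probes$sequence[1])))
})

setMethod("show", "CrossHybReport", function(object) {
    r <- object@report
    cat(sprintf("CrossHybReport: %d probes, %d flagged (Lmin=%d, Imin=%.2f)\n",
                nrow(r), sum(r$flagged), object@params$Lmin,
                object@params$Imin))
})

setMethod("show", "MaskedChipDefinition", function(object) {
    cat(sprintf("MaskedChipDefinition: %d probe-sets retained, %d dropped (minProbes=%d)\n",
                length(object@probesets), nrow(object@dropped),
                object@params$minProbes))
})

setMethod("show", "GroundTruth", function(object) {
    cat(sprintf("GroundTruth: %d DE genes, %d cross-hybridizing probes, %d signatures\n",
                nrow(object@deGenes), nrow(object@crossHybProbes),
                length(object@signatureMemberships)))
})

setMethod("show", "VariancePrior", function(object) {
    cat(sprintf("VariancePrior: d0 = %s, s0^2 = %.4g (residual df %s)\n",
                format(object@d0), object@s0sq, format(object@df)))
})

setMethod("show", "LocalFdrModel", function(object) {
    cat(sprintf("LocalFdrModel: pi0 = %.3f (plateau lambda = %.2f), Grenander f with %d steps\n",
                object@pi0, object@lambda, length(object@heights)))
})

setMethod("show", "OBBMST", function(object) {
    cat(sprintf("OBBMST (%s vs %s): %d + %d DE genes; %d common, %d/%d unique; R^2 = %.3f\n",
                object@modelA, object@modelB,
                nrow(object@listA), nrow(object@listB),
                nrow(object@common), length(object@uniqueA),
                length(object@uniqueB), object@r2))
})

setMethod("show", "CurationLedger", function(object) {
    cat(sprintf("CurationLedger: start %d genes\n", length(object@start)))
    for (st in object@stages)
        cat(sprintf("  - subtract %-22s removed %4d, remaining %4d\n",
                    st$category, length(st$removed), length(st$remaining)))
    cat(sprintf("  core: %d genes (%.1f%% of start)\n",
                length(object@components$core),
                100 * object@fractions[["core"]]))
})

setMethod("show", "OverlapResult", function(object) {
    cat(sprintf("OverlapResult: %d/%d signature genes in query (%.1f%%), fold %.2f, p = %.3g\n",
                object@k, object@K, object@coverage, object@fold, object@p))
})

setMethod("show", "MotifModel", function(object) {
    cat(sprintf("MotifModel '%s': width %d, consensus %s, threshold %.2f x max score\n",
                object@name, motifWidth(object), motifConsensus(object),
                object@scoreThreshold))
})

setMethod("show", "MotifEnrichmentResult", function(object) {
    cat(sprintf("MotifEnrichmentResult '%s': EF = %.3f (cluster %.3f vs background %.3f), p = %.3g (%d resamples)%s\n",
                object@motifName, object@EF, object@freqCluster,
                object@freqBackground, object@p, object@nResamples,
                if (object@reported) " [reported]" else ""))
})
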