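## End-to-end pipeline on synthetic data: simulate -> mask -> summarize ->
## differential expression (two xenograft models) -> combined transcriptome
## -> signature-subtraction curation -> niche overlap -> promoter motif
## enrichment. Writes a compact, deterministic set of plain-text outputs.

num <- function(x, digits = 6) formatC(x, digits = digits, format = "g")

writeTsv <- function(d, path) {
    utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' A sharp 12-nt query motif used by the packaged pipeline
#'
#' Columns put probability 0.91 on the consensus base and 0.03 elsewhere; at
#' the default 0.8 score threshold this tolerates roughly one mismatching
#' base, keeping chance promoter hits rare.
#'
#' @param name motif name.
#' @param consensus consensus sequence (default a 12-mer).
#' @param scoreThreshold hit threshold (fraction of max score).
#' @return a \linkS4class{MotifModel}.
#' @export
defaultQueryMotif <- function(name = "synthTF",
                              consensus = "TGACGTCATGCA",
                              scoreThreshold = 0.8) {
    ch <- strsplit(consensus, NULL)[[1]]
    stopifnot(all(ch %in% BASES))
    m <- matrix(0.03, nrow = 4, ncol = length(ch),
                dimnames = list(BASES, NULL))
    m[cbind(match(ch, BASES), seq_along(ch))] <- 0.91
    motifModel(name, m, scoreThreshold = scoreThreshold)
}

#' Run the full stroma-dissection pipeline on synthetic data
#'
#' Generates a two-species reference and experiment from \code{config}, masks
#' cross-hybridizing probes against the human transcripts, summarizes the
#' retained probes, tests two xenograft models
#' against a control group with the moderated t / local-fdr pipeline, builds
#' the combined stroma transcriptome, curates it against the synthetic
#' signature registry, and measures niche-signature overlap and promoter
#' motif enrichment for the core component.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param outDir optional directory; when given, compact TSV/JSON outputs
#'   are written there.
#' @param models two xenograft group names to contrast (default C4-2B and
#'   VCaP).
#' @param control control group for the contrasts (default "intact", the
#'   3-replicate control).
#' @param lfdrThreshold local-fdr selection threshold applied to both models
#'   (default 0.2; the stringent per-model presets of \code{fdrPresets} suit
#'   larger designs than the packaged fixtures).
#' @param Lmin,Imin,minProbes masking parameters.
#' @param promoterRates planted motif rates (cluster, background) for the
#'   promoter stage.
#' @param nResamples background draws for motif enrichment.
#' @param normalize normalization passed to
#'   \code{\link{preprocessIntensities}}; defaults to "none" because the
#'   simulator produces no array-level scale effects and quantile
#'   normalization would only distort fold changes on a small chip with a
#'   direction-skewed DE fraction (see \code{preprocessIntensities}).
#' @return (invisibly) a list with every intermediate object: \code{ref},
#'   \code{sim}, \code{report}, \code{masked}, \code{expr}, \code{de} (per
#'   model), \code{selected} (per model), \code{obbmst}, \code{registry},
#'   \code{ledger}, \code{overlap}, \code{motif}.
#' @examples
#' \donttest{
#' res <- runPipeline(simulationConfig(nGenes = 150, seed = 11))
#' res$ledger
#' }
#' @export
runPipeline <- function(config, outDir = NULL,
                        models = c("C4-2B", "VCaP"), control = "intact",
                        lfdrThreshold = 0.2,
                        Lmin = 15L, Imin = 0.80, minProbes = 4L,
                        promoterRates = c(cluster = 0.6, background = 0.3),
                        nResamples = 2000L,
                        normalize = c("none", "quantile")) {
    normalize <- match.arg(normalize)
    stopifnot(is(config, "SimulationConfig"), length(models) == 2L)

    ref <- generateTwoSpeciesReference(config)
    sim <- simulateExperiment(config, ref$chip, ref$truth)

    mk <- maskChip(ref$chip, ref$humanTranscripts, Lmin = Lmin, Imin = Imin,
                   minProbes = minProbes)
    expr <- preprocessIntensities(sim$intensities, mk$masked,
                                  design = sim$design, normalize = normalize)

    de <- lapply(models, function(m)
        differentialExpression(expr, contrast = c(m, control)))
    names(de) <- models
    selected <- lapply(de, selectDE, threshold = lfdrThreshold)
    obb <- buildObbmst(selected[[1]], selected[[2]],
                       modelA = models[1], modelB = models[2])

    registry <- generateSignatureRegistry(ref$truth, config,
                                          startSet = obbmstGenes(obb))
    ledger <- curate(obb, registry$signatures, order = registry$order)

    core <- ledgerComponents(ledger)$core
    universe <- unique(chipProbes(ref$chip)$probeset_id)
    overlap <- overlapTest(obbmstGenes(obb),
                           registry$signatures$hsc_niche_like,
                           universe, queryName = "combined stroma DE set")

    motif <- NULL
    if (length(core) >= 5L) {
        background <- setdiff(universe, core)
        qm <- defaultQueryMotif()
        promoters <- generatePromoters(core, background, qm,
                                       promoterRates[["cluster"]],
                                       promoterRates[["background"]],
                                       seed = config@seed + 3L)
        motif <- motifEnrichment(core, background, promoters, qm,
                                 nResamples = nResamples,
                                 seed = config@seed + 4L)
    }

    res <- list(ref = ref, sim = sim, report = mk$report,
                masked = mk$masked, expr = expr, de = de,
                selected = selected, obbmst = obb, registry = registry,
                ledger = ledger, overlap = overlap, motif = motif)
    if (!is.null(outDir)) writePipelineOutputs(res, outDir)
    invisible(res)
}

#' Write the pipeline's compact plain-text outputs
#'
#' @param res result list from \code{\link{runPipeline}}.
#' @param outDir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
writePipelineOutputs <- function(res, outDir) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    fp <- function(f) file.path(outDir, f)

    writeCrossHybReport(res$report, fp("crosshyb_flagged.tsv"),
                        flaggedOnly = TRUE)
    writeTsv(as.data.frame(droppedProbesets(res$masked)),
             fp("dropped_probesets.tsv"))

    for (m in names(res$de)) {
        sel <- res$selected[[m]]
        d <- as.data.frame(sel)
        d$log2fc <- num(d$log2fc)
        d$lfdr <- num(d$lfdr)
        writeTsv(d, fp(sprintf("de_%s.tsv", gsub("[^A-Za-z0-9]", "", m))))
    }

    obb <- res$obbmst
    writeTsv(data.frame(metric = c("common", "uniqueA", "uniqueB",
                                   "discordant", "r2"),
                        value = c(nrow(obb@common), length(obb@uniqueA),
                                  length(obb@uniqueB),
                                  sum(obb@common$discordant),
                                  num(obb@r2))),
             fp("obbmst_summary.tsv"))

    writeCurationLedger(res$ledger, fp("curation_ledger.json"),
                        tsvPath = fp("curation_stages.tsv"))

    venn <- vennPartition(list(
        A = res$obbmst@listA$gene, B = res$obbmst@listB$gene,
        core = ledgerComponents(res$ledger)$core))
    writeTsv(data.frame(region = names(venn), count = as.integer(venn)),
             fp("venn_regions.tsv"))

    ov <- res$overlap
    writeTsv(data.frame(signature = ov@signature, k = ov@k, K = ov@K,
                        n = ov@n, N = ov@N,
                        coverage_pct = num(ov@coverage),
                        fold = num(ov@fold), p = num(ov@p)),
             fp("niche_overlap.tsv"))

    if (!is.null(res$motif)) {
        mo <- res$motif
        jsonlite::write_json(
            list(motif = mo@motifName, EF = as.numeric(num(mo@EF)),
                 p = as.numeric(num(mo@p)),
                 freq_cluster = as.numeric(num(mo@freqCluster)),
                 freq_background = as.numeric(num(mo@freqBackground)),
                 n_resamples = mo@nResamples, reported = mo@reported),
            fp("motif_enrichment.json"), auto_unbox = TRUE, digits = 10)
    }
    invisible(outDir)
}
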