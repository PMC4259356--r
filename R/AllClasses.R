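#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom Rcpp evalCpp
#' @useDynLib xenostroma, .registration = TRUE
NULL

## ---------------------------------------------------------------------------
## Simulation configuration
## ---------------------------------------------------------------------------

#' Simulation configuration for two-species xenograft array data
#'
#' Holds all parameters of the synthetic-data generator: chip geometry,
#' differential-expression structure of the mouse (stroma) compartment,
#' cross-hybridization planting, human:mouse RNA mixing ratios per xenograft
#' model, group/replicate structure and the noise model.
#'
#' @slot nGenes number of genes per species.
#' @slot probesPerSet oligo probes per probe-set (one set per mouse gene).
#' @slot probeLength probe length in nt.
#' @slot fracDE fraction of mouse genes truly differentially expressed in
#'   xenograft groups.
#' @slot effectMean,effectSD mean and sd of the |log2 fold change| magnitude
#'   distribution of true effects.
#' @slot fracUp fraction of true effects that are up-regulated.
#' @slot fracCrossHyb fraction of probes with a planted off-target match.
#' @slot contaminationCoef fraction of off-target (human) transcript abundance
#'   bleeding into a cross-hybridizing probe's signal.
#' @slot mixingRatios named character vector, model -> "human:mouse" ratio.
#' @slot replicates named integer vector, group -> replicate count.
#' @slot noiseSD sd of additive Gaussian noise on the log2 scale.
#' @slot plantMinLen,plantMaxLen nt range of planted off-target match lengths.
#' @slot flankLength extra random nt on each side of the probe-tiled region.
#' @slot seed integer seed; identical config + seed gives identical output.
#' @export
setClass("SimulationConfig",
    representation(
        nGenes = "integer",
        probesPerSet = "integer",
        probeLength = "integer",
        fracDE = "numeric",
        effectMean = "numeric",
        effectSD = "numeric",
        fracUp = "numeric",
        fracCrossHyb = "numeric",
        contaminationCoef = "numeric",
        mixingRatios = "character",
        replicates = "integer",
        noiseSD = "numeric",
        plantMinLen = "integer",
        plantMaxLen = "integer",
        flankLength = "integer",
        seed = "integer"
    )
)

setValidity("SimulationConfig", function(object) {
    msg <- character()
    frac01 <- function(x, what) {
        if (length(x) != 1L || is.na(x) || x < 0 || x > 1)
            sprintf("%s must be a single value in [0, 1]", what)
        else character()
    }
    msg <- c(msg,
        frac01(object@fracDE, "fracDE"),
        frac01(object@fracUp, "fracUp"),
        frac01(object@fracCrossHyb, "fracCrossHyb"),
        frac01(object@contaminationCoef, "contaminationCoef"))
    if (object@nGenes < 1L) msg <- c(msg, "nGenes must be >= 1")
    if (object@probesPerSet < 1L) msg <- c(msg, "probesPerSet must be >= 1")
    if (object@probeLength < 1L) msg <- c(msg, "probeLength must be >= 1")
    if (object@noiseSD < 0) msg <- c(msg, "noiseSD must be >= 0")
    if (object@effectSD < 0) msg <- c(msg, "effectSD must be >= 0")
    if (any(object@replicates < 1L))
        msg <- c(msg, "all replicate counts must be >= 1")
    if (is.null(names(object@replicates)) || anyNA(names(object@replicates)))
        msg <- c(msg, "replicates must be a named vector (group -> count)")
    if (length(object@mixingRatios) &&
        (is.null(names(object@mixingRatios)) ||
         !all(grepl("^[0-9.]+:[0-9.]+$", object@mixingRatios))))
        msg <- c(msg, "mixingRatios must be named 'human:mouse' strings")
    if (object@plantMinLen > object@plantMaxLen ||
        object@plantMaxLen > object@probeLength)
        msg <- c(msg, "plant length range must satisfy min <= max <= probeLength")
    if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Chip definitions and masking
## ---------------------------------------------------------------------------

#' Chip definition: probe-set to probe sequence map
#'
#' Ordered table of probes per probe-set, mirroring an Affymetrix-style chip
#' definition restricted to perfect-match probe sequences.
#'
#' @slot probes a \linkS4class{DataFrame} with columns \code{probeset_id},
#'   \code{probe_id}, \code{probe_index} and \code{sequence}.
#' @export
setClass("ChipDefinition", representation(probes = "DataFrame"))

setValidity("ChipDefinition", function(object) {
    p <- object@probes
    need <- c("probeset_id", "probe_id", "probe_index", "sequence")
    if (!all(need %in% colnames(p)))
        return(paste("probes must have columns:", paste(need, collapse = ", ")))
    if (nrow(p) == 0L) return("chip definition has no probes")
    if (anyDuplicated(p$probe_id)) return("probe_ids must be unique chip-wide")
    if (any(!grepl("^[ACGTN]+$", p$sequence)))
        return("probe sequences must be uppercase ACGT (N tolerated, flagged)")
    TRUE
})

#' Per-probe cross-hybridization report
#'
#' @slot report a \linkS4class{DataFrame} with one row per probe:
#'   \code{probe_id}, \code{match_len} (longest contiguous exact off-target
#'   match, nt), \code{identity} (best ungapped full-probe alignment fraction),
#'   \code{flagged}, \code{partner} (off-target transcript id or NA).
#' @slot params list with \code{Lmin}, \code{Imin}, \code{bothStrands}.
#' @export
setClass("CrossHybReport",
    representation(report = "DataFrame", params = "list"))

setValidity("CrossHybReport", function(object) {
    r <- object@report
    need <- c("probe_id", "match_len", "identity", "flagged", "partner")
    if (!all(need %in% colnames(r)))
        return(paste("report must have columns:", paste(need, collapse = ", ")))
    if (any(r$match_len < 0)) return("match_len must be >= 0")
    if (any(r$identity < 0 | r$identity > 1))
        return("identity must be in [0, 1]")
    TRUE
})

#' Masked chip definition: species-specific probe-sets
#'
#' Result of removing cross-hybridizing probes and dropping probe-sets left
#' with too few probes to summarize robustly.
#'
#' @slot probesets named list, probeset_id -> retained probe ids (original
#'   order preserved).
#' @slot dropped \linkS4class{DataFrame} with columns \code{probeset_id},
#'   \code{reason}.
#' @slot params list with \code{Lmin}, \code{Imin}, \code{minProbes}.
#' @export
setClass("MaskedChipDefinition",
    representation(probesets = "list", dropped = "DataFrame",
                   params = "list"))

## ---------------------------------------------------------------------------
## Ground truth
## ---------------------------------------------------------------------------

#' Ground truth of a synthetic two-species experiment
#'
#' @slot deGenes \linkS4class{DataFrame}: \code{gene}, \code{direction}
#'   (+1/-1), \code{log2fc} (signed true effect).
#' @slot crossHybProbes \linkS4class{DataFrame}: \code{probe_id},
#'   \code{partner} (human transcript id), \code{match_len} (planted nt).
#' @slot signatureMemberships named list of gene-id vectors.
#' @export
setClass("GroundTruth",
    representation(deGenes = "DataFrame", crossHybProbes = "DataFrame",
                   signatureMemberships = "list"))

## ---------------------------------------------------------------------------
## Differential expression
## ---------------------------------------------------------------------------

#' Empirical-Bayes variance prior of the moderated t-statistic
#'
#' Scaled inverse chi-square prior on per-gene variances: d0 prior degrees of
#' freedom (possibly infinite) and s0^2 prior variance, fitted by moment
#' matching on log variances.
#'
#' @slot d0 prior degrees of freedom (may be \code{Inf}).
#' @slot s0sq prior variance (log2 units squared).
#' @slot df residual degrees of freedom per gene.
#' @export
setClass("VariancePrior",
    representation(d0 = "numeric", s0sq = "numeric", df = "numeric"))

setValidity("VariancePrior", function(object) {
    if (object@d0 < 0) return("d0 must be >= 0")
    if (object@s0sq <= 0) return("s0sq must be > 0")
    TRUE
})

#' Two-component local false discovery rate model
#'
#' Null proportion pi0 (upper-tail plateau estimate) and a Grenander-type
#' monotone nonincreasing density f on [0, 1]; lfdr(p) = min(1, pi0 / f(p)).
#'
#' @slot pi0 estimated null proportion in [0, 1].
#' @slot lambda plateau start used for the pi0 estimate.
#' @slot breaks,heights step-function representation of f (density constant at
#'   \code{heights[i]} on \code{[breaks[i], breaks[i+1])}).
#' @export
setClass("LocalFdrModel",
    representation(pi0 = "numeric", lambda = "numeric",
                   breaks = "numeric", heights = "numeric"))

setValidity("LocalFdrModel", function(object) {
    if (object@pi0 < 0 || object@pi0 > 1) return("pi0 must be in [0, 1]")
    if (any(diff(object@breaks) <= 0)) return("breaks must be increasing")
    if (length(object@heights) != length(object@breaks) - 1L)
        return("heights must have length(breaks) - 1")
    if (any(diff(object@heights) > 1e-9))
        return("density must be nonincreasing")
    TRUE
})

## ---------------------------------------------------------------------------
## Curation
## ---------------------------------------------------------------------------

#' A published-style gene signature
#'
#' @slot name signature name.
#' @slot species symbol species ("mouse" or "human").
#' @slot category curation/overlap category (e.g. "inflammatory",
#'   "non-osteotropic", "osteotropic", "niche-HSC", "niche-UGM",
#'   "stromal-cell-type", "wound", "desmoplastic").
#' @slot symbols unique gene symbols.
#' @slot direction optional per-symbol direction (+1/-1, or empty).
#' @slot provenance free-text citation string.
#' @export
setClass("GeneSignature",
    representation(name = "character", species = "character",
                   category = "character", symbols = "character",
                   direction = "integer", provenance = "character"))

setValidity("GeneSignature", function(object) {
    if (!length(object@symbols)) return("symbols must be non-empty")
    if (anyDuplicated(object@symbols))
        return("symbols must be unique within a signature")
    if (length(object@direction) &&
        length(object@direction) != length(object@symbols))
        return("direction must be empty or parallel to symbols")
    TRUE
})

#' Combined two-model stroma transcriptome
#'
#' Union of the differentially expressed stroma genes of two xenograft models,
#' with the common/unique partition and cross-model fold-change concordance.
#'
#' @slot modelA,modelB model names.
#' @slot listA,listB per-model \linkS4class{DataFrame}s (\code{gene},
#'   \code{log2fc}, \code{direction}).
#' @slot common \linkS4class{DataFrame}: \code{gene}, \code{log2fc_A},
#'   \code{log2fc_B}, \code{discordant} (opposite directions).
#' @slot uniqueA,uniqueB genes unique to each model.
#' @slot r2 squared Pearson correlation of log2 fold changes on the common set.
#' @slot slopeSign sign of the correlation (+1/-1).
#' @export
setClass("OBBMST",
    representation(modelA = "character", modelB = "character",
                   listA = "DataFrame", listB = "DataFrame",
                   common = "DataFrame",
                   uniqueA = "character", uniqueB = "character",
                   r2 = "numeric", slopeSign = "numeric"))

setValidity("OBBMST", function(object) {
    if (length(intersect(object@common$gene, object@uniqueA)))
        return("common and uniqueA must be disjoint")
    if (length(intersect(object@common$gene, object@uniqueB)))
        return("common and uniqueB must be disjoint")
    if (!setequal(c(object@common$gene, object@uniqueA), object@listA$gene))
        return("common + uniqueA must equal model A's list")
    if (!setequal(c(object@common$gene, object@uniqueB), object@listB$gene))
        return("common + uniqueB must equal model B's list")
    if (length(object@r2) && !is.na(object@r2) &&
        (object@r2 < 0 || object@r2 > 1))
        return("r2 must be in [0, 1]")
    TRUE
})

#' Ordered record of signature subtractions
#'
#' Each stage removes from the running remainder the genes present in that
#' stage's signature category; the final remainder is the core signature. The
#' stage-removed sets are pairwise disjoint and, together with the core,
#' partition the starting set exactly.
#'
#' @slot start starting gene set.
#' @slot stages list of per-stage lists: \code{category}, \code{signatures},
#'   \code{removed}, \code{remaining}.
#' @slot components named list: \code{core} plus one component per stage
#'   category.
#' @slot fractions named numeric, component sizes as fractions of the start
#'   set (sum to 1).
#' @export
setClass("CurationLedger",
    representation(start = "character", stages = "list",
                   components = "list", fractions = "numeric"))

setValidity("CurationLedger", function(object) {
    removed <- unlist(lapply(object@stages, `[[`, "removed"),
                      use.names = FALSE)
    if (anyDuplicated(removed))
        return("stage-removed sets must be pairwise disjoint")
    rebuilt <- c(removed, object@components$core)
    if (!setequal(rebuilt, object@start) ||
        length(rebuilt) != length(object@start))
        return("core plus stage removals must partition the start set exactly")
    if (length(object@fractions) &&
        abs(sum(object@fractions) - 1) > 1e-9)
        return("component fractions must sum to 1")
    TRUE
})

## ---------------------------------------------------------------------------
## Enrichment
## ---------------------------------------------------------------------------

#' Gene-set overlap against a signature (hypergeometric test)
#'
#' @slot k overlap count; @slot K signature size within the universe;
#' @slot n query size; @slot N universe size.
#' @slot coverage k/K as a percentage.
#' @slot p one-sided hypergeometric upper-tail probability (includes k).
#' @slot fold (k/n) / (K/N) fold enrichment.
#' @slot signature,query labels.
#' @export
setClass("OverlapResult",
    representation(k = "integer", K = "integer", n = "integer", N = "integer",
                   coverage = "numeric", p = "numeric", fold = "numeric",
                   signature = "character", query = "character"))

setValidity("OverlapResult", function(object) {
    if (object@k > min(object@n, object@K)) return("k must be <= min(n, K)")
    if (object@p <= 0 || object@p > 1) return("p must be in (0, 1]")
    if (object@coverage < 0 || object@coverage > 100)
        return("coverage must be in [0, 100]")
    TRUE
})

#' Position weight matrix motif model
#'
#' @slot name motif name.
#' @slot matrix 4 x width probability matrix (rows A, C, G, T; columns sum
#'   to 1).
#' @slot scoreThreshold fraction of the maximum log-odds score a window must
#'   reach to count as a hit.
#' @export
setClass("MotifModel",
    representation(name = "character", matrix = "matrix",
                   scoreThreshold = "numeric"))

setValidity("MotifModel", function(object) {
    m <- object@matrix
    if (nrow(m) != 4L) return("matrix must have 4 rows (A, C, G, T)")
    if (ncol(m) < 4L) return("motif width must be >= 4")
    if (any(abs(colSums(m) - 1) > 1e-9)) return("columns must sum to 1")
    if (any(m < 0)) return("probabilities must be >= 0")
    if (object@scoreThreshold <= 0 || object@scoreThreshold > 1)
        return("scoreThreshold must be in (0, 1]")
    TRUE
})

#' Promoter motif enrichment against resampled gene backgrounds
#'
#' @slot motifName motif.
#' @slot EF enrichment factor: promoter hit frequency in the cluster divided
#'   by the mean hit frequency over background draws of matched size.
#' @slot p resampling p-value with +1 Monte-Carlo correction.
#' @slot nResamples,seed resampling settings.
#' @slot freqCluster,freqBackground hit frequencies (background = resample
#'   mean).
#' @slot reported whether the (EF, p) pair passes the reporting rule.
#' @export
setClass("MotifEnrichmentResult",
    representation(motifName = "character", EF = "numeric", p = "numeric",
                   nResamples = "integer", seed = "integer",
                   freqCluster = "numeric", freqBackground = "numeric",
                   reported = "logical"))

setValidity("MotifEnrichmentResult", function(object) {
    if (object@EF < 0) return("EF must be >= 0")
    if (object@p <= 0 || object@p > 1) return("p must be in (0, 1]")
    TRUE
})
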