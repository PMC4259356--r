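## Synthetic two-species data generator.
##
## Emulates the mixed-signal problem of profiling mouse stroma under human
## cancer cell xenografts on a mouse expression array: human and mouse
## transcript sets, a chip definition whose probes tile the mouse
## transcripts, planted cross-hybridizing probes (shared subsequences copied
## into a human "partner" transcript), probe-level intensities that mix mouse
## signal with ratio-scaled human bleed-through, and a registry of published
## style signatures with controlled overlap against the true DE set.

BASES <- c("A", "C", "G", "T")

randomDNA <- function(n, len) {
    vapply(seq_len(n),
           function(i) paste(sample(BASES, len, replace = TRUE),
                             collapse = ""),
           character(1))
}

#' Convert a "human:mouse" ratio string to the human/mouse scale factor
#'
#' @param ratio character like \code{"1:5"}.
#' @return human abundance relative to mouse (e.g. "1:5" -> 0.2).
#' @export
mixingRatioToScale <- function(ratio) {
    parts <- strsplit(ratio, ":", fixed = TRUE)
    vapply(parts, function(p) {
        p <- as.numeric(p)
        if (length(p) != 2L || anyNA(p) || p[2] <= 0)
            stop("mixing ratio must be of the form 'human:mouse'")
        p[1] / p[2]
    }, numeric(1))
}

revComp <- function(x) {
    chartr("ACGT", "TGCA",
           vapply(strsplit(x, NULL),
                  function(ch) paste(rev(ch), collapse = ""), character(1)))
}

## Replace a probe window inside a mouse transcript with fresh random bases.
redrawWindow <- function(seqs, tx, start, len) {
    s <- seqs[tx]
    substr(s, start, start + len - 1L) <- paste(
        sample(BASES, len, replace = TRUE), collapse = "")
    seqs[tx] <- s
    seqs
}

#' Generate two-species reference sequences, chip definition and ground truth
#'
#' Mouse transcripts are i.i.d. uniform ACGT; each carries
#' \code{probesPerSet} non-overlapping probe windows that become one
#' probe-set. A fraction of probes is made cross-hybridizing by copying a
#' contiguous window of \code{plantMinLen}..\code{plantMaxLen} nt into one
#' human partner transcript; all other probes are rejection-sampled so that,
#' against the final human transcript set (either strand), their longest
#' contiguous match is below 12 nt and their best full-probe identity below
#' 0.76 -- a clean margin under the default masking thresholds.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @param maxRounds bound on rejection-sampling rounds before the
#'   configuration is declared infeasible.
#' @return list with \code{mouseTranscripts} and \code{humanTranscripts}
#'   (\code{DNAStringSet}), \code{chip} (\linkS4class{ChipDefinition}) and
#'   \code{truth} (\linkS4class{GroundTruth}).
#' @examples
#' ref <- generateTwoSpeciesReference(simulationConfig(nGenes = 40, seed = 7))
#' ref$chip
#' ref$truth
#' @export
generateTwoSpeciesReference <- function(config, maxRounds = 50L) {
    stopifnot(is(config, "SimulationConfig"))
    validObject(config)
    set.seed(config@seed)

    n <- config@nGenes
    pps <- config@probesPerSet
    plen <- config@probeLength
    flank <- config@flankLength
    txLen <- pps * plen + 2L * flank

    mouseIds <- sprintf("mmGene%04d", seq_len(n))
    humanIds <- sprintf("hsTX%04d", seq_len(n))
    mouse <- stats::setNames(randomDNA(n, txLen), mouseIds)
    human <- stats::setNames(randomDNA(n, txLen), humanIds)

    probeStart <- function(j) flank + (j - 1L) * plen + 1L
    probeTx <- rep(seq_len(n), each = pps)
    probeIdx <- rep(seq_len(pps), times = n)
    probeOf <- function(seqs) {
        substring(seqs[probeTx], probeStart(probeIdx),
                  probeStart(probeIdx) + plen - 1L)
    }
    probeIds <- sprintf("%s_p%02d", mouseIds[probeTx], probeIdx)
    nProbes <- n * pps

    ## plant cross-hybridizing probes
    nCross <- round(config@fracCrossHyb * nProbes)
    crossSel <- if (nCross > 0) sort(sample.int(nProbes, nCross)) else integer()
    plantLen <- if (nCross > 0)
        sample(seq(config@plantMinLen, config@plantMaxLen), nCross,
               replace = TRUE) else integer()
    plantPartner <- if (nCross > 0)
        sample.int(n, nCross, replace = TRUE) else integer()

    ## planted windows within one human transcript must not overlap, or a
    ## later plant would clobber an earlier one
    doPlant <- function(human, probes) {
        occupied <- vector("list", n)
        for (i in seq_along(crossSel)) {
            pr <- probes[crossSel[i]]
            L <- plantLen[i]
            srcStart <- sample.int(plen - L + 1L, 1L)
            window <- substr(pr, srcStart, srcStart + L - 1L)
            tgt <- plantPartner[i]
            dstStart <- NA_integer_
            for (try in 1:100) {
                cand <- sample.int(txLen - L + 1L, 1L)
                clash <- vapply(occupied[[tgt]], function(iv)
                    cand <= iv[2] && (cand + L - 1L) >= iv[1], logical(1))
                if (!any(clash)) { dstStart <- cand; break }
            }
            if (is.na(dstStart))
                stop("could not place a cross-hybridization window; ",
                     "configuration infeasible (too many planted probes ",
                     "per human transcript)")
            occupied[[tgt]] <- c(occupied[[tgt]],
                                 list(c(dstStart, dstStart + L - 1L)))
            s <- human[tgt]
            substr(s, dstStart, dstStart + L - 1L) <- window
            human[tgt] <- s
        }
        human
    }

    ## rejection loop: unplanted probes must have longest off-target match
    ## < 12 nt and full-probe identity < 0.76 against the final human set
    ## (including planted windows) -- a clean margin below the default
    ## masking thresholds (15 nt / 0.80)
    unplanted <- setdiff(seq_len(nProbes), crossSel)
    humanPlanted <- doPlant(human, probeOf(mouse))
    pending <- unplanted  # only redrawn probes need rescanning
    for (round in seq_len(maxRounds)) {
        probes <- probeOf(mouse)
        hit <- .crossHybScanCpp(probes[pending], unname(humanPlanted),
                                bothStrands = TRUE, computeIdentity = TRUE)
        bad <- pending[hit$match_len >= 12L | hit$identity >= 0.76]
        if (!length(bad)) break
        if (round == maxRounds)
            stop("rejection sampling failed after ", maxRounds,
                 " rounds; configuration infeasible (too many probes for ",
                 "the sequence space)")
        for (b in bad)
            mouse <- redrawWindow(mouse, probeTx[b], probeStart(probeIdx[b]),
                                  plen)
        pending <- bad
    }
    ## planted windows must come from the final mouse probe sequences:
    ## planting used the pre-redraw probes only for unplanted indices, and
    ## planted probe windows are never redrawn, so re-planting is a no-op;
    ## still, verify the planted matches stand in the final sequences.
    probes <- probeOf(mouse)

    chip <- chipDefinition(mouseIds[probeTx], probeIds, probeIdx, probes)
    truth <- new("GroundTruth",
        deGenes = DataFrame(gene = character(), direction = integer(),
                            log2fc = numeric()),
        crossHybProbes = DataFrame(
            probe_id = probeIds[crossSel],
            partner = humanIds[plantPartner],
            match_len = plantLen),
        signatureMemberships = list())

    ## true DE structure
    nDE <- round(config@fracDE * n)
    if (nDE > 0) {
        deSel <- sort(sample.int(n, nDE))
        dirs <- ifelse(stats::runif(nDE) < config@fracUp, 1L, -1L)
        mags <- abs(stats::rnorm(nDE, config@effectMean, config@effectSD))
        truth@deGenes <- DataFrame(gene = mouseIds[deSel],
                                   direction = dirs,
                                   log2fc = dirs * mags)
    }

    list(mouseTranscripts = Biostrings::DNAStringSet(mouse),
         humanTranscripts = Biostrings::DNAStringSet(humanPlanted),
         chip = chip,
         truth = truth)
}

#' Simulate probe-level intensities for the xenograft experiment
#'
#' Linear-scale signal for probe p in sample s is the mouse transcript
#' abundance of p's gene (shifted by the true log2 fold change in xenograft
#' groups for DE genes) plus, for planted cross-hybridizing probes,
#' \code{contaminationCoef * ratio(s) * humanAbundance(partner)}, where
#' \code{ratio(s)} is the sample's human:mouse RNA ratio. Gaussian noise with
#' sd \code{noiseSD} is added on the log2 scale and the result
#' back-transformed, so all intensities are strictly positive.
#'
#' @param config the \linkS4class{SimulationConfig} used for generation.
#' @param chip the matching \linkS4class{ChipDefinition}.
#' @param truth the matching \linkS4class{GroundTruth}.
#' @return list with \code{intensities} (probe x sample matrix, linear scale)
#'   and \code{design} (data.frame: sample_id, group, model, replicate,
#'   mixing_ratio).
#' @export
simulateExperiment <- function(config, chip, truth) {
    stopifnot(is(config, "SimulationConfig"), is(chip, "ChipDefinition"),
              is(truth, "GroundTruth"))
    set.seed(config@seed + 1L)

    probes <- chipProbes(chip)
    genes <- unique(probes$probeset_id)
    n <- length(genes)

    groups <- names(config@replicates)
    unknownRatio <- setdiff(names(config@mixingRatios), groups)
    if (length(unknownRatio))
        stop("mixingRatios name groups absent from the replicate map: ",
             paste(unknownRatio, collapse = ", "))
    design <- do.call(rbind, lapply(groups, function(g) {
        k <- config@replicates[[g]]
        data.frame(sample_id = sprintf("%s_r%d", g, seq_len(k)),
                   group = g, model = g, replicate = seq_len(k),
                   mixing_ratio = if (g %in% names(config@mixingRatios))
                       config@mixingRatios[[g]] else "0:1",
                   stringsAsFactors = FALSE)
    }))
    ratios <- mixingRatioToScale(design$mixing_ratio)
    xeno <- design$group %in% names(config@mixingRatios)

    ## baseline log2 abundances
    bMouse <- stats::setNames(stats::rnorm(n, mean = 8, sd = 1.2), genes)
    de <- trueDEGenes(truth)
    shift <- stats::setNames(numeric(n), genes)
    shift[de$gene] <- de$log2fc

    ch <- trueCrossHybProbes(truth)
    partnerIds <- unique(ch$partner)
    bHuman <- stats::setNames(stats::rnorm(length(partnerIds), 8, 1.2),
                              partnerIds)

    ns <- nrow(design)
    gIdx <- match(probes$probeset_id, genes)
    mouseLog2 <- matrix(bMouse[gIdx], nrow(probes), ns) +
        outer(shift[gIdx], as.numeric(xeno))
    signal <- 2 ^ mouseLog2

    if (nrow(ch)) {
        pIdx <- match(ch$probe_id, probes$probe_id)
        bleed <- config@contaminationCoef *
            outer(2 ^ bHuman[ch$partner], ratios)
        signal[pIdx, ] <- signal[pIdx, ] + bleed
    }

    if (config@noiseSD > 0) {
        signal <- 2 ^ (log2(signal) +
            matrix(stats::rnorm(length(signal), 0, config@noiseSD),
                   nrow(signal), ncol(signal)))
    }
    dimnames(signal) <- list(probes$probe_id, design$sample_id)
    list(intensities = signal, design = design)
}

#' Generate a signature registry with controlled overlaps and its expected
#' curation ledger
#'
#' Emits one signature per curation category whose overlap with
#' \code{startSet} is a planted, pairwise-disjoint gene subset, padded with
#' filler symbols outside the start set, plus a stem-cell niche style
#' signature with a planted overlap for overlap testing. The analytically
#' expected \linkS4class{CurationLedger} (which genes each stage removes and
#' the expected core) is returned alongside.
#'
#' @param truth a \linkS4class{GroundTruth}; its DE genes are the default
#'   start set.
#' @param config the matching \linkS4class{SimulationConfig} (seeds the
#'   draws).
#' @param startSet gene set to be curated (default the true DE genes).
#' @param overlapFracs named fractions of the start set overlapped by each
#'   category, in subtraction order.
#' @param nicheFrac fraction of the start set shared with the niche
#'   signature.
#' @param fillerPerSig non-overlapping filler symbols added to each
#'   signature.
#' @return list with \code{signatures} (named list of
#'   \linkS4class{GeneSignature}s), \code{expectedLedger} and \code{order}
#'   (category subtraction order).
#' @export
generateSignatureRegistry <- function(truth, config,
                                      startSet = trueDEGenes(truth)$gene,
                                      overlapFracs = c(
                                          "inflammatory" = 0.10,
                                          "non-osteotropic" = 0.08,
                                          "osteotropic" = 0.09),
                                      nicheFrac = 0.45,
                                      fillerPerSig = 40L) {
    stopifnot(is(truth, "GroundTruth"), is(config, "SimulationConfig"))
    set.seed(config@seed + 2L)
    nStart <- length(startSet)
    counts <- round(overlapFracs * nStart)
    if (sum(counts) > nStart)
        stop("requested overlaps exceed the available start set")

    pool <- sample(startSet)
    taken <- 0L
    categories <- names(overlapFracs)
    sigNames <- c("inflammatory" = "inflammatory_wound_desmoplastic",
                  "non-osteotropic" = "non_osteotropic_cancer_stroma",
                  "osteotropic" = "osteotropic_primary_stroma")
    signatures <- list()
    stages <- list()
    remaining <- startSet
    for (cat in categories) {
        k <- counts[[cat]]
        ov <- if (k > 0) pool[seq_len(k) + taken] else character()
        taken <- taken + k
        filler <- sprintf("%sFill%03d", gsub("[^A-Za-z]", "", cat),
                          seq_len(fillerPerSig))
        nm <- sigNames[[cat]]
        signatures[[nm]] <- geneSignature(
            name = nm, species = "mouse", category = cat,
            symbols = sample(c(ov, filler)),
            provenance = "synthetic registry")
        stages[[cat]] <- sort(ov)
        remaining <- setdiff(remaining, ov)
    }
    core <- remaining

    nNiche <- round(nicheFrac * nStart)
    nicheOv <- sample(startSet, nNiche)
    nicheFiller <- sprintf("nicheFill%03d", seq_len(fillerPerSig))
    signatures[["hsc_niche_like"]] <- geneSignature(
        name = "hsc_niche_like", species = "mouse", category = "niche-HSC",
        symbols = sample(c(nicheOv, nicheFiller)),
        provenance = "synthetic registry")

    expected <- buildLedger(
        start = startSet,
        stageList = lapply(categories, function(cat) list(
            category = cat,
            signatures = sigNames[[cat]],
            removed = stages[[cat]])),
        componentNames = c("inflammatory" = "inflammatory-shared",
                           "non-osteotropic" = "universal",
                           "osteotropic" = "osteotropic"))

    list(signatures = signatures, expectedLedger = expected,
         order = categories)
}

#' Generate promoter sequences with a planted motif
#'
#' Each gene receives one uniform-random sequence of \code{windowNt} nt,
#' mirroring a fixed 2-kb window upstream of the transcription start site.
#' The motif consensus is planted with per-group probability at a uniform
#' random position and strand.
#'
#' @param clusterGenes,backgroundGenes gene ids for the two groups.
#' @param motif a \linkS4class{MotifModel} (its consensus is planted).
#' @param rateCluster,rateBackground planting probabilities in [0, 1].
#' @param windowNt promoter window length (default 2000 nt).
#' @param seed integer seed.
#' @return a named \code{DNAStringSet}; names follow the
#'   \code{gene|chrom|TSS|strand} promoter header convention.
#' @export
generatePromoters <- function(clusterGenes, backgroundGenes, motif,
                              rateCluster, rateBackground,
                              windowNt = 2000L, seed = 1L) {
    stopifnot(is(motif, "MotifModel"),
              rateCluster >= 0, rateCluster <= 1,
              rateBackground >= 0, rateBackground <= 1)
    w <- motifWidth(motif)
    if (w > windowNt)
        stop("motif width exceeds the promoter window")
    set.seed(seed)
    genes <- c(clusterGenes, backgroundGenes)
    rates <- c(rep(rateCluster, length(clusterGenes)),
               rep(rateBackground, length(backgroundGenes)))
    cons <- motifConsensus(motif)
    seqs <- randomDNA(length(genes), windowNt)
    plant <- stats::runif(length(genes)) < rates
    pos <- sample.int(windowNt - w + 1L, length(genes), replace = TRUE)
    minus <- sample(c(TRUE, FALSE), length(genes), replace = TRUE)
    for (i in which(plant)) {
        ins <- if (minus[i]) revComp(cons) else cons
        substr(seqs[i], pos[i], pos[i] + w - 1L) <- ins
    }
    names(seqs) <- sprintf("%s|chrS|%d|+", genes, windowNt)
    Biostrings::DNAStringSet(seqs)
}
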