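## Overlap statistics between the curated stroma transcriptome and external
## gene signatures (hypergeometric upper tail), and PWM promoter motif
## enrichment against matched random gene-background draws. "Frequency" in
## the enrichment factor is binary per gene (fraction of genes with at least
## one promoter hit); a hit-density mode counts total hits per promoter.

#' Hypergeometric overlap test against a gene signature
#'
#' Draws: a query list of n genes from a universe of N, of which K belong to
#' the signature (the signature is intersected with the universe first). The
#' p-value is the one-sided upper-tail probability of observing at least k
#' overlapping genes; coverage is k/K as a percentage; fold enrichment is
#' (k/n) / (K/N).
#'
#' @param query gene set (subset of universe; trimmed with a message
#'   otherwise).
#' @param signature a \linkS4class{GeneSignature} or character vector.
#' @param universe background gene universe.
#' @param queryName optional label.
#' @return an \linkS4class{OverlapResult}.
#' @examples
#' overlapTest(paste0("g", 1:20), paste0("g", c(1:5, 50:60)),
#'             paste0("g", 1:100))
#' @export
overlapTest <- function(query, signature, universe, queryName = "query") {
    sigName <- "signature"
    if (is(signature, "GeneSignature")) {
        sigName <- signature@name
        signature <- signatureSymbols(signature)
    }
    universe <- unique(universe)
    if (!length(universe)) stop("empty gene universe")
    query <- unique(query)
    outside <- setdiff(query, universe)
    if (length(outside)) {
        message(sprintf("overlapTest: %d query genes outside the universe dropped",
                        length(outside)))
        query <- intersect(query, universe)
    }
    sig <- intersect(unique(signature), universe)
    k <- length(intersect(query, sig))
    K <- length(sig)
    n <- length(query)
    N <- length(universe)
    p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    fold <- if (n > 0 && K > 0) (k / n) / (K / N) else NA_real_
    new("OverlapResult",
        k = as.integer(k), K = as.integer(K), n = as.integer(n),
        N = as.integer(N),
        coverage = if (K > 0) 100 * k / K else NA_real_,
        p = p, fold = fold,
        signature = sigName, query = queryName)
}

## per-column log2-odds matrix vs uniform background, after adding the
## pseudocount and renormalizing
logOddsMatrix <- function(motif, pseudocount = 1e-3) {
    m <- motif@matrix + pseudocount
    m <- sweep(m, 2, colSums(m), "/")
    log2(m / 0.25)
}

scanOneStrand <- function(codes, lom, minScore) {
    w <- ncol(lom)
    nW <- length(codes) - w + 1L
    if (nW < 1L) return(logical(0))
    score <- numeric(nW)
    naHit <- logical(nW)
    for (j in seq_len(w)) {
        cj <- codes[j:(j + nW - 1L)]
        bad <- is.na(cj)
        naHit <- naHit | bad
        cj[bad] <- 1L
        score <- score + lom[cbind(cj, j)]
    }
    (score >= minScore) & !naHit
}

#' Count PWM motif hits in sequences
#'
#' Scores every window of motif width on both strands with the log2-odds of
#' the (pseudocount-regularized) PWM against a uniform background; a window
#' is a hit when its score reaches \code{scoreThreshold} times the maximum
#' achievable score. Windows containing N never hit.
#'
#' @param seqs a \code{DNAStringSet} or character vector (ACGTN).
#' @param motif a \linkS4class{MotifModel}.
#' @param pseudocount added to PWM columns before the log (default 1e-3).
#' @return integer vector of hit counts, one per sequence.
#' @export
scanMotif <- function(seqs, motif, pseudocount = 1e-3) {
    stopifnot(is(motif, "MotifModel"))
    if (is(seqs, "DNAStringSet")) seqs <- as.character(seqs)
    bad <- !grepl("^[ACGTN]*$", seqs)
    if (any(bad)) stop("sequences contain characters outside ACGTN")
    w <- motifWidth(motif)
    if (any(nchar(seqs) < w))
        stop("all sequences must be at least as long as the motif")
    lom <- logOddsMatrix(motif, pseudocount)
    minScore <- motif@scoreThreshold * sum(apply(lom, 2, max))
    vapply(seqs, function(s) {
        codes <- match(strsplit(s, NULL)[[1]], BASES)
        rcCodes <- rev(5L - codes)
        sum(scanOneStrand(codes, lom, minScore)) +
            sum(scanOneStrand(rcCodes, lom, minScore))
    }, integer(1), USE.NAMES = FALSE)
}

promoterGene <- function(headers) {
    vapply(strsplit(headers, "|", fixed = TRUE), `[[`, character(1), 1L)
}

#' Promoter motif enrichment against matched random backgrounds
#'
#' The cluster's hit frequency (fraction of cluster genes with >= 1 promoter
#' hit, or mean hit count in density mode) is compared with
#' \code{nResamples} random draws of the same number of genes from the
#' background pool. EF is the cluster frequency over the mean resampled
#' frequency; the p-value is the +1-corrected fraction of draws at least as
#' frequent as the cluster. The result is flagged for reporting when EF
#' reaches \code{efMin} (the reported band's lower bound) and p falls below
#' \code{pMax}.
#'
#' @param cluster gene ids of the query cluster.
#' @param backgroundPool gene ids to draw backgrounds from (cluster genes
#'   are excluded from draws).
#' @param promoters named \code{DNAStringSet} of promoter windows; names are
#'   gene ids or \code{gene|chrom|TSS|strand} headers.
#' @param motif a \linkS4class{MotifModel}.
#' @param nResamples number of background draws (default 10000).
#' @param seed integer seed for the draws.
#' @param mode "binary" (fraction of genes with a hit, default) or
#'   "density" (mean hits per promoter).
#' @param efMin,pMax reporting rule thresholds (defaults 1.2 and 1e-4).
#' @return a \linkS4class{MotifEnrichmentResult}.
#' @export
motifEnrichment <- function(cluster, backgroundPool, promoters, motif,
                            nResamples = 10000L, seed = 1L,
                            mode = c("binary", "density"),
                            efMin = 1.2, pMax = 1e-4) {
    mode <- match.arg(mode)
    stopifnot(is(motif, "MotifModel"))
    genes <- promoterGene(names(promoters))
    if (anyDuplicated(genes)) stop("duplicate promoter gene ids")
    cluster <- unique(cluster)
    pool <- setdiff(unique(backgroundPool), cluster)
    if (length(cluster) > length(pool))
        stop("cluster larger than the background pool: resampling infeasible")
    if (length(pool) < 2L * length(cluster))
        warning("background pool is less than twice the cluster size; ",
                "without-replacement draws have little variation and the ",
                "resampling p-value is unreliable (degenerate at equality)")
    missing <- setdiff(c(cluster, pool), genes)
    if (length(missing))
        stop("promoters missing for: ", paste(utils::head(missing, 5),
                                              collapse = ", "))
    hits <- scanMotif(promoters, motif)
    stat <- if (mode == "binary") as.numeric(hits >= 1L) else as.numeric(hits)
    names(stat) <- genes

    freqCluster <- mean(stat[cluster])
    nC <- length(cluster)
    set.seed(seed)
    poolStat <- stat[pool]
    freqDraws <- vapply(seq_len(nResamples), function(b)
        mean(poolStat[sample.int(length(poolStat), nC)]), numeric(1))
    freqBackground <- mean(freqDraws)
    EF <- if (freqBackground > 0) freqCluster / freqBackground else Inf
    p <- (1 + sum(freqDraws >= freqCluster)) / (nResamples + 1)
    new("MotifEnrichmentResult",
        motifName = motif@name, EF = EF, p = p,
        nResamples = as.integer(nResamples), seed = as.integer(seed),
        freqCluster = freqCluster, freqBackground = freqBackground,
        reported = (EF >= efMin) && (p < pMax))
}
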