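# Independent brute-force oracles. These deliberately share no code with the
# package internals: plain string/vector arithmetic, exhaustive enumeration,
# and convex-hull geometry.

oracleRevComp <- function(x) {
    chartr("ACGT", "TGCA",
           vapply(strsplit(x, NULL),
                  function(ch) paste(rev(ch), collapse = ""), character(1)))
}

# longest substring of `probe` occurring exactly in any target (either
# strand): try every length from longest down, every offset
oracleLongestMatch <- function(probe, targets, bothStrands = TRUE) {
    hay <- paste(c(targets, if (bothStrands) oracleRevComp(targets)),
                 collapse = "#")
    plen <- nchar(probe)
    for (L in plen:1) {
        subs <- unique(substring(probe, 1:(plen - L + 1), L:plen))
        if (any(vapply(subs, function(s) grepl(s, hay, fixed = TRUE),
                       logical(1))))
            return(L)
    }
    0L
}

# best ungapped full-probe identity at any offset where the probe fits
# entirely inside a target (either strand); shifted vector comparison
oracleBestIdentity <- function(probe, targets, bothStrands = TRUE) {
    pv <- strsplit(probe, NULL)[[1]]
    plen <- length(pv)
    best <- 0
    for (t in c(targets, if (bothStrands) oracleRevComp(targets))) {
        tv <- strsplit(t, NULL)[[1]]
        nOff <- length(tv) - plen + 1L
        if (nOff < 1L) next
        matches <- integer(nOff)
        for (j in seq_len(plen))
            matches <- matches + (tv[j:(j + nOff - 1L)] == pv[j])
        best <- max(best, max(matches) / plen)
    }
    best
}

# exhaustive hypergeometric null: probability of overlap >= k when drawing
# n from a universe of N containing K marked elements, by enumerating all
# C(N, n) draws
oracleHyperUpperTail <- function(k, N, n, K) {
    draws <- utils::combn(N, n)
    marked <- seq_len(K)
    overlaps <- apply(draws, 2, function(d) sum(d %in% marked))
    mean(overlaps >= k)
}

# Grenander density: slopes of the least concave majorant of the ECDF,
# constructed by gift wrapping from (0, 0) -- at each hull vertex pick the
# steepest remaining slope, farthest point among ties. Valid for continuous
# p-values (no mass at exactly 0). Returns f evaluated at each p.
oracleGrenander <- function(p) {
    x <- unique(c(0, sort(p), 1))
    y <- vapply(x, function(v) mean(p <= v), numeric(1))
    hx <- 0; hy <- 0
    while (hx[length(hx)] < 1) {
        cand <- which(x > hx[length(hx)])
        slopes <- (y[cand] - hy[length(hy)]) / (x[cand] - hx[length(hx)])
        ties <- which(slopes >= max(slopes) - 1e-12)
        j <- cand[ties[length(ties)]]
        hx <- c(hx, x[j]); hy <- c(hy, y[j])
    }
    slopes <- diff(hy) / diff(hx)
    idx <- findInterval(p, hx, rightmost.closed = TRUE, all.inside = TRUE)
    slopes[idx]
}

# all-window PWM scoring of one sequence, both strands
oracleScanMotif <- function(seq, mat, thresholdFrac, pseudocount = 1e-3) {
    m <- mat + pseudocount
    m <- sweep(m, 2, colSums(m), "/")
    lom <- log2(m / 0.25)
    w <- ncol(lom)
    hits <- 0L
    for (s in c(seq, oracleRevComp(seq))) {
        sv <- match(strsplit(s, NULL)[[1]], c("A", "C", "G", "T"))
        for (i in seq_len(nchar(s) - w + 1L)) {
            window <- sv[i:(i + w - 1L)]
            if (anyNA(window)) next
            score <- sum(lom[cbind(window, seq_len(w))])
            if (score >= thresholdFrac * sum(apply(lom, 2, max)))
                hits <- hits + 1L
        }
    }
    hits
}
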