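# Independent oracles used across the suite. Each recomputes a quantity by
# a route different from the package implementation.

# two-sided Fisher p by direct enumeration in probability space
fisherOracle <- function(a, b, c, d) {
    r1 <- a + b
    r2 <- c + d
    k <- a + c
    if (r1 == 0 || r2 == 0 || k == 0 || k == r1 + r2) return(1)
    x <- max(0, k - r2):min(k, r1)
    dd <- dhyper(x, r1, r2, k)
    sum(dd[dd <= dhyper(a, r1, r2, k) * (1 + 1e-7)])
}

# AUROC as the explicit mean over all (positive, negative) pairs
aurocOracle <- function(scores, labels) {
    sp <- scores[labels == 1]
    sn <- scores[labels == 0]
    tot <- 0
    for (p in sp) tot <- tot + sum(p > sn) + 0.5 * sum(p == sn)
    tot / (length(sp) * length(sn))
}

# average precision from explicit PR-curve points at every unique threshold
auprOracle <- function(scores, labels) {
    th <- sort(unique(scores), decreasing = TRUE)
    nPos <- sum(labels == 1)
    prevR <- 0
    ap <- 0
    for (t in th) {
        sel <- scores >= t
        prec <- sum(labels[sel] == 1) / sum(sel)
        rec <- sum(labels[sel] == 1) / nPos
        ap <- ap + (rec - prevR) * prec
        prevR <- rec
    }
    ap
}

# gene symbols overlapped by >= 1 peak, by all-pairs coordinate scan on
# 0-based half-open intervals
bruteOverlap <- function(win, pk) {
    hit <- character(0)
    for (i in seq_len(nrow(win))) {
        for (j in seq_len(nrow(pk))) {
            if (win$chrom[i] == pk$chrom[j] &&
                pk$start[j] < win$end[i] && pk$end[j] > win$start[i]) {
                hit <- c(hit, win$symbol[i])
                break
            }
        }
    }
    unique(hit)
}

# random small-instance generator for the overlap oracle (BED coordinates)
randomOverlapInstance <- function(nGenes, nPeaks, span = 2e6) {
    chroms <- c("chr1", "chr2")
    ws <- sample(span, nGenes, replace = TRUE)
    win <- data.frame(chrom = sample(chroms, nGenes, replace = TRUE),
                      start = ws, end = ws + sample(2000, nGenes, TRUE),
                      symbol = sprintf("G%04d", seq_len(nGenes)))
    ps <- sample(span, nPeaks, replace = TRUE)
    pk <- data.frame(chrom = sample(chroms, nPeaks, replace = TRUE),
                     start = ps, end = ps + sample(500, nPeaks, TRUE))
    list(win = win, pk = pk)
}

# GRanges views of a brute-force instance (BED -> 1-based closed)
asWindowGRanges <- function(win) {
    GenomicRanges::GRanges(win$chrom,
                           IRanges::IRanges(win$start + 1L, win$end),
                           symbol = win$symbol)
}
asPeakGRanges <- function(pk) {
    GenomicRanges::GRanges(pk$chrom, IRanges::IRanges(pk$start + 1L, pk$end))
}

# small feasible fixture configuration for fast tests
smallFixtureConfig <- function(...) {
    fixtureConfig(n_genes = 300, n_chroms = 2, gene_spacing = 12000,
                  n_tfs = 4, experiments_per_tf = 2, targets_per_tf = 25,
                  background_peaks_per_experiment = 120,
                  n_chemicals = 5, n_up = 25, n_down = 20,
                  n_diseases = 3, tfs_per_disease = 2, seed = 17, ...)
}
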