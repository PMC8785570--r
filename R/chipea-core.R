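#' @include genome-windows.R
NULL

#' Build the 2x2 overlap table for one (chemical, experiment) pair
#'
#' Rows of the table are the up- and down-regulated gene sets, columns are
#' overlapped / not overlapped by the experiment's peaks. Only symbols
#' present in the annotation participate: a DEG with no transcript (hence no
#' TSS window) cannot be tested and is excluded rather than counted as
#' non-overlapping.
#'
#' @param up,down disjoint character vectors of gene symbols.
#' @param hit symbols overlapped by the experiment's peaks (from
#'   [overlappingSymbols()]).
#' @param annotated symbols present in the window annotation.
#' @return named integer vector `c(a, b, c, d)` — up-overlapped,
#'   up-not-overlapped, down-overlapped, down-not-overlapped — or `NULL`
#'   when either side is empty after annotation filtering (the exact test is
#'   undefined on an empty margin; such records are skipped).
#' @export
makeContingencyTable <- function(up, down, hit, annotated) {
    if (length(intersect(up, down)))
        stop("up and down sets must be disjoint")
    upA <- intersect(up, annotated)
    downA <- intersect(down, annotated)
    if (!length(upA) || !length(downA)) return(NULL)
    a <- sum(upA %in% hit)
    cc <- sum(downA %in% hit)
    c(a = a, b = length(upA) - a, c = cc, d = length(downA) - cc)
}

#' Two-tailed Fisher's exact test on a 2x2 table
#'
#' Exact two-sided p-value under the standard definition: with both margins
#' fixed, sum the hypergeometric probabilities of every table whose
#' probability does not exceed that of the observed table (up to a 1e-7
#' relative tolerance against floating-point ties, the convention of
#' mainstream implementations). Probabilities are accumulated in log space
#' so large margins stay numerically stable.
#'
#' @param a,b,c,d non-negative integer cell counts (`a`/`b`: up-regulated
#'   genes overlapped/not; `c`/`d`: down-regulated genes overlapped/not).
#'   `a` may also be a length-4 vector holding the whole table.
#' @return the two-sided p-value in (0, 1].
#' @examples
#' fisherTwoTailed(5, 5, 5, 5)   # identical proportions -> 1
#' fisherTwoTailed(2, 0, 0, 2)   # 1/3 by full enumeration
#' @export
fisherTwoTailed <- function(a, b = NULL, c = NULL, d = NULL) {
    if (length(a) == 4L && is.null(b)) {
        d <- a[[4]]; c <- a[[3]]; b <- a[[2]]; a <- a[[1]]
    }
    cells <- c(a, b, c, d)
    if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
        stop("table cells must be non-negative integers")
    r1 <- a + b; r2 <- c + d; n <- r1 + r2; k <- a + c
    if (r1 == 0 || r2 == 0 || k == 0 || k == n) return(1)
    x <- max(0, k - r2):min(k, r1)
    lp <- lchoose(r1, x) + lchoose(r2, k - x) - lchoose(n, k)
    lpObs <- lp[x == a]
    keep <- lp <= lpObs + log1p(1e-7)
    if (all(keep)) return(1)
    m <- max(lp[keep])
    min(exp(m) * sum(exp(lp[keep] - m)), 1)
}

#' Enrichment score: -log10(p), capped
#'
#' @param p p-value in (0, 1].
#' @param scoreCap upper bound on the score; p-values below `10^-scoreCap`
#'   (including log-space underflow to zero) score exactly `scoreCap`.
#' @return non-negative enrichment score.
#' @export
enrichmentScore <- function(p, scoreCap = 320) {
    if (any(is.na(p)) || any(p < 0) || any(p > 1))
        stop("p must lie in (0, 1]")
    pmin(-log10(pmax(p, 10^(-scoreCap))), scoreCap)
}

#' Fold enrichment of up- over down-regulated overlap fractions
#'
#' `(a / (a + b)) / (c / (c + d))`: the fraction of up-regulated genes
#' overlapped divided by the fraction of down-regulated genes overlapped.
#' Conventions for degenerate tables: no overlaps on either side (a = c = 0)
#' gives 1 (no evidence); overlaps only on the up side (c = 0, a > 0) gives
#' `Inf`.
#'
#' @inheritParams fisherTwoTailed
#' @return fold enrichment (> 1 means up-biased binding).
#' @export
foldEnrichment <- function(a, b = NULL, c = NULL, d = NULL) {
    if (length(a) == 4L && is.null(b)) {
        d <- a[[4]]; c <- a[[3]]; b <- a[[2]]; a <- a[[1]]
    }
    if (a == 0 && c == 0) return(1)
    if (c == 0) return(Inf)
    (a / (a + b)) / (c / (c + d))
}

.direction <- function(a, b, c, d) {
    # compare a/(a+b) vs c/(c+d) exactly in integers
    lhs <- a * (c + d); rhs <- c * (a + b)
    if (lhs > rhs) "up-biased" else if (lhs < rhs) "down-biased" else "neutral"
}

#' Run ChIP-seq enrichment analysis for a set of chemicals
#'
#' For every (chemical profile, ChIP-seq experiment) pair, counts how many
#' up- and how many down-regulated genes have a TSS window overlapped by the
#' experiment's peaks, tests the 2x2 table with the two-tailed Fisher's
#' exact test, and reports the enrichment score -log10(p) together with the
#' fold enrichment and binding-bias direction. Pairs whose table is
#' undefined (one side empty after annotation filtering) are skipped and
#' counted in the `skipped` attribute.
#'
#' @param profiles [GeneSignatureSet-class] of chemical DEG profiles.
#' @param peaks GRanges of peaks with an `experiment_id` metadata column.
#' @param meta experiment metadata (experiment_id, antigen).
#' @param windows GRanges from [tssWindows()].
#' @param scoreCap cap on the enrichment score (see [enrichmentScore()]).
#' @return data frame of enrichment records (chemical_id, experiment_id, tf,
#'   a, b, c, d, p, score, fold, direction), ordered by chemical then
#'   experiment id; attribute `skipped` counts undefined pairs.
#' @export
runChipea <- function(profiles, peaks, meta, windows, scoreCap = 320) {
    stopifnot(is(profiles, "GeneSignatureSet"))
    if (!nrow(meta)) stop("no experiments in metadata")
    expIds <- sort(meta$experiment_id)
    antigen <- meta$antigen[match(expIds, meta$experiment_id)]
    annotated <- unique(S4Vectors::mcols(windows)$symbol)

    ov <- GenomicRanges::findOverlaps(peaks, windows)
    pe <- S4Vectors::mcols(peaks)$experiment_id[S4Vectors::queryHits(ov)]
    sy <- S4Vectors::mcols(windows)$symbol[S4Vectors::subjectHits(ov)]
    hitPairs <- unique(data.frame(e = pe, s = sy, stringsAsFactors = FALSE))
    hitSets <- split(hitPairs$s, hitPairs$e)

    out <- vector("list", length(profiles@ids) * length(expIds))
    skipped <- 0L
    r <- 0L
    for (i in seq_along(profiles@ids)) {
        up <- profiles@up[[i]]
        down <- profiles@down[[i]]
        for (j in seq_along(expIds)) {
            hit <- hitSets[[expIds[j]]]
            if (is.null(hit)) hit <- character(0)
            tab <- makeContingencyTable(up, down, hit, annotated)
            if (is.null(tab)) { skipped <- skipped + 1L; next }
            p <- fisherTwoTailed(tab)
            r <- r + 1L
            out[[r]] <- data.frame(
                chemical_id = profiles@ids[i], experiment_id = expIds[j],
                tf = antigen[j], a = tab[["a"]], b = tab[["b"]],
                c = tab[["c"]], d = tab[["d"]], p = p,
                score = enrichmentScore(p, scoreCap),
                fold = foldEnrichment(tab),
                direction = .direction(tab[["a"]], tab[["b"]], tab[["c"]],
                                       tab[["d"]]),
                stringsAsFactors = FALSE)
        }
    }
    res <- do.call(rbind, out[seq_len(r)])
    if (is.null(res))
        res <- data.frame(chemical_id = character(0),
                          experiment_id = character(0), tf = character(0),
                          a = integer(0), b = integer(0), c = integer(0),
                          d = integer(0), p = numeric(0), score = numeric(0),
                          fold = numeric(0), direction = character(0))
    rownames(res) <- NULL
    attr(res, "skipped") <- skipped
    res
}

#' Aggregate enrichment records to chemical-TF scores
#'
#' A TF is usually covered by several ChIP-seq experiments; per (chemical,
#' TF) the record with the highest enrichment score is adopted. Ties are
#' broken by the lexicographically smallest experiment id, so aggregation is
#' deterministic.
#'
#' @param records enrichment records from [runChipea()].
#' @return data frame chemical_id, tf, score, direction,
#'   best_experiment_id — one row per (chemical, TF).
#' @export
aggregateByTF <- function(records) {
    if (!nrow(records))
        return(data.frame(chemical_id = character(0), tf = character(0),
                          score = numeric(0), direction = character(0),
                          best_experiment_id = character(0)))
    o <- order(records$chemical_id, records$tf, -records$score,
               records$experiment_id, method = "radix")
    records <- records[o, , drop = FALSE]
    first <- !duplicated(records[, c("chemical_id", "tf")])
    res <- data.frame(chemical_id = records$chemical_id[first],
                      tf = records$tf[first],
                      score = records$score[first],
                      direction = records$direction[first],
                      best_experiment_id = records$experiment_id[first],
                      stringsAsFactors = FALSE)
    rownames(res) <- NULL
    res
}
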