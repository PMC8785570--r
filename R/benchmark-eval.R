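#' @include disease-linkage.R
NULL

.checkLabels <- function(labels) {
    labels <- as.numeric(labels)
    if (any(is.na(labels)) || !all(labels %in% c(0, 1)))
        stop("labels must be binary 0/1")
    labels
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability: the fraction of
#' (positive, negative) pairs where the positive scores higher, with tied
#' pairs contributing 1/2. Equals the trapezoidal area under the ROC curve
#' and is invariant under strictly monotone score transforms.
#'
#' @param scores numeric prediction scores.
#' @param labels binary 0/1 truth labels, same length.
#' @return AUROC in \[0, 1\] (0.5 = random ranking).
#' @export
auroc <- function(scores, labels) {
    labels <- .checkLabels(labels)
    stopifnot(length(scores) == length(labels))
    nPos <- sum(labels == 1)
    nNeg <- sum(labels == 0)
    if (nPos == 0 || nNeg == 0)
        stop("AUROC undefined: need at least one positive and one negative")
    r <- rank(scores)
    (sum(r[labels == 1]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision: sweeping thresholds from the highest score
#' down, each newly recalled positive contributes the precision at that
#' point; tied scores are processed as one block using the precision at the
#' block's end. A constant score vector therefore yields exactly the
#' positive prevalence — the random baseline of the PR curve.
#'
#' @inheritParams auroc
#' @return AUPR in \[0, 1\].
#' @export
aupr <- function(scores, labels) {
    labels <- .checkLabels(labels)
    stopifnot(length(scores) == length(labels))
    nPos <- sum(labels == 1)
    if (nPos == 0) stop("AUPR undefined: no positive labels")
    o <- order(-scores)
    s <- scores[o]
    l <- labels[o]
    newBlock <- c(TRUE, s[-1] != s[-length(s)])
    cumTP <- cumsum(l)
    ends <- which(c(newBlock[-1], TRUE))
    tpEnd <- cumTP[ends]
    tpBlock <- diff(c(0, tpEnd))
    sum(tpBlock * tpEnd / ends) / nPos
}

#' Per-chemical AUROC/AUPR over an association matrix
#'
#' Evaluates each chemical (row) whose labels contain both classes; rows
#' lacking a positive or a negative among the scored entities cannot be
#' ranked against themselves and are excluded with a count.
#'
#' @param x labelled [AssociationMatrix-class].
#' @return list with `per_chemical` (data frame chemical_id, auroc, aupr,
#'   n_pos, n_neg), `mean_auroc`, `median_auroc`, `mean_aupr`,
#'   `median_aupr`, `n_excluded`.
#' @export
perChemicalEval <- function(x) {
    stopifnot(is(x, "AssociationMatrix"))
    if (!hasLabels(x)) stop("association matrix carries no truth labels")
    s <- scoreMatrix(x)
    l <- labelMatrix(x)
    rows <- lapply(seq_len(nrow(s)), function(i) {
        nPos <- sum(l[i, ] == 1)
        nNeg <- sum(l[i, ] == 0)
        if (nPos == 0 || nNeg == 0) return(NULL)
        data.frame(chemical_id = rownames(s)[i],
                   auroc = auroc(s[i, ], l[i, ]),
                   aupr = aupr(s[i, ], l[i, ]),
                   n_pos = nPos, n_neg = nNeg, stringsAsFactors = FALSE)
    })
    keep <- !vapply(rows, is.null, TRUE)
    if (!any(keep)) stop("no evaluable chemicals (every row single-class)")
    pc <- do.call(rbind, rows[keep])
    rownames(pc) <- NULL
    list(per_chemical = pc,
         mean_auroc = mean(pc$auroc), median_auroc = median(pc$auroc),
         mean_aupr = mean(pc$aupr), median_aupr = median(pc$aupr),
         n_excluded = sum(!keep))
}

#' Global AUROC/AUPR over an association matrix
#'
#' `column_max` mode condenses the matrix to one element per entity
#' (TF/disease): the maximum enrichment score in the column, labelled 1 iff
#' any cell attaining that maximum is a true pair. `pooled` mode flattens
#' all m x n (score, label) cells into a single vector. Both emphasize the
#' actual score values rather than within-chemical ranking.
#'
#' @param x labelled [AssociationMatrix-class].
#' @param mode `"column_max"` (default) or `"pooled"`.
#' @return list with `auroc`, `aupr` and `n` (vector length evaluated).
#' @export
globalEval <- function(x, mode = c("column_max", "pooled")) {
    stopifnot(is(x, "AssociationMatrix"))
    if (!hasLabels(x)) stop("association matrix carries no truth labels")
    mode <- match.arg(mode)
    s <- scoreMatrix(x)
    l <- labelMatrix(x)
    if (mode == "column_max") {
        scores <- apply(s, 2, max)
        labels <- vapply(seq_len(ncol(s)), function(j) {
            as.numeric(any(l[s[, j] == scores[j], j] == 1))
        }, 0)
    } else {
        scores <- as.vector(s)
        labels <- as.vector(l)
    }
    list(auroc = auroc(scores, labels), aupr = aupr(scores, labels),
         n = length(scores))
}

# exact two-sided rank-sum p by dynamic programming over doubled midranks
.wilcoxExact <- function(x, y) {
    r2 <- as.integer(round(2 * rank(c(x, y))))
    n1 <- length(x)
    n <- length(r2)
    wObs <- sum(r2[seq_len(n1)])
    mu <- n1 * (n + 1)
    maxS <- sum(r2)
    dp <- matrix(0, n1 + 1, maxS + 1)
    dp[1, 1] <- 1
    for (v in r2) {
        kmax <- min(n1, nrow(dp) - 1)
        for (k in kmax:1) {
            idx <- (v + 1):(maxS + 1)
            dp[k + 1, idx] <- dp[k + 1, idx] + dp[k, idx - v]
        }
    }
    counts <- dp[n1 + 1, ]
    sSum <- 0:maxS
    sum(counts[abs(sSum - mu) >= abs(wObs - mu) - 1e-9]) / choose(n, n1)
}

#' Two-sided Wilcoxon rank-sum comparison of two score lists
#'
#' Used to compare per-chemical AUROC (or AUPR) distributions between
#' methods. When both samples have at most 12 observations, the p-value is
#' computed by exact enumeration over all group assignments of the pooled
#' midranks (ties handled exactly); otherwise the normal approximation with
#' tie and continuity corrections is used.
#'
#' @param a,b numeric vectors (e.g. per-chemical AUROCs of two methods).
#' @return two-sided p-value.
#' @examples
#' compareMethods(c(1, 2, 3), c(4, 5, 6))  # 0.1 by full enumeration
#' @export
compareMethods <- function(a, b) {
    if (!length(a) || !length(b)) stop("both score lists must be non-empty")
    if (length(a) <= 12 && length(b) <= 12) return(.wilcoxExact(a, b))
    if (length(unique(c(a, b))) == 1) return(1)  # all tied: no evidence
    suppressWarnings(
        stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
}

#' Do members of a subset sit higher in a ranked list than non-members?
#'
#' Two-sided Wilcoxon rank-sum test comparing the rank positions (1 = top)
#' of subset members against non-members in an ordered list — e.g. whether
#' database-annotated genes rank higher in a frequency-ranked gene list.
#'
#' @param rankedItems character vector in rank order (best first).
#' @param subset character vector of member items.
#' @return two-sided p-value.
#' @export
rankOverlapTest <- function(rankedItems, subset) {
    member <- rankedItems %in% subset
    if (!any(member) || all(member))
        stop("rank-overlap test undefined: need members and non-members")
    ranks <- seq_along(rankedItems)
    compareMethods(ranks[member], ranks[!member])
}
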