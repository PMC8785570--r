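#' @include benchmark-eval.R
NULL

#' Classify every gene of a universe as up, down or non-DEG
#'
#' @param universe character vector of gene symbols (the annotation's
#'   deduplicated symbol set); duplicates are removed.
#' @param up,down the profile's up-/down-regulated symbol sets (disjoint).
#'   Profile genes absent from the universe are ignored and counted in the
#'   `n_ignored` attribute.
#' @return factor over the universe with levels `up`, `down`, `non-DEG`,
#'   named by gene symbol.
#' @export
classifyGenes <- function(universe, up, down) {
    if (!length(universe)) stop("empty gene universe")
    universe <- unique(toupper(universe))
    up <- toupper(up)
    down <- toupper(down)
    if (length(intersect(up, down)))
        stop("up and down sets must be disjoint")
    lab <- rep("non-DEG", length(universe))
    lab[universe %in% up] <- "up"
    lab[universe %in% down] <- "down"
    res <- factor(lab, levels = c("up", "down", "non-DEG"))
    names(res) <- universe
    attr(res, "n_ignored") <- length(setdiff(c(up, down), universe))
    res
}

#' Cross-tabulate two gene classifications
#'
#' Builds the 2x2 frequency table of a chemical's against a disease's gene
#' classification over a shared universe, in one of two ways:
#' `deg_vs_nondeg` contrasts DEG (up or down) against non-DEG status —
#' n1 = DEG in both, n2 = DEG only in the chemical, n3 = DEG only in the
#' disease, n4 = DEG in neither; `up_vs_down` restricts to genes that are
#' DEGs in both profiles and contrasts the direction — n1 = up/up,
#' n2 = up/down, n3 = down/up, n4 = down/down.
#'
#' @param chem,dis classification factors from [classifyGenes()] over the
#'   same universe.
#' @param mode `"deg_vs_nondeg"` or `"up_vs_down"`.
#' @return named integer vector `c(n1, n2, n3, n4)`, or `NULL` in
#'   `up_vs_down` mode when no gene is a DEG in both profiles (the pair is
#'   unscorable).
#' @export
crossTab <- function(chem, dis, mode = c("deg_vs_nondeg", "up_vs_down")) {
    mode <- match.arg(mode)
    if (length(chem) != length(dis))
        stop("classifications must share one universe")
    if (mode == "deg_vs_nondeg") {
        cd <- chem != "non-DEG"
        dd <- dis != "non-DEG"
        tab <- c(n1 = sum(cd & dd), n2 = sum(cd & !dd),
                 n3 = sum(!cd & dd), n4 = sum(!cd & !dd))
    } else {
        joint <- chem != "non-DEG" & dis != "non-DEG"
        if (!any(joint)) return(NULL)
        cu <- chem[joint] == "up"
        du <- dis[joint] == "up"
        tab <- c(n1 = sum(cu & du), n2 = sum(cu & !du),
                 n3 = sum(!cu & du), n4 = sum(!cu & !du))
    }
    tab
}

#' DEG-connected baseline: score chemical-disease pairs without TFs
#'
#' The TF-free comparator: each (chemical, disease) pair is scored by a
#' two-tailed Fisher's exact test on the cross-tabulation of their gene
#' classifications ([crossTab()]), the null being independence of the two
#' profiles' labels given the margins. Scores are -log10(p); pairs with an
#' invalid table (no jointly-DEG gene in `up_vs_down` mode) score 0.
#'
#' @param chemProfiles [GeneSignatureSet-class] of chemical DEG profiles.
#' @param diseaseSigs [GeneSignatureSet-class] of disease signatures.
#' @param universe gene universe (annotation symbols, deduplicated).
#' @param mode cross-tabulation mode, see [crossTab()].
#' @param scoreCap cap on -log10(p) (see [enrichmentScore()]).
#' @return An [AssociationMatrix-class] (chemicals x diseases, sorted axes)
#'   without labels.
#' @export
baselineScores <- function(chemProfiles, diseaseSigs, universe,
                           mode = c("deg_vs_nondeg", "up_vs_down"),
                           scoreCap = 320) {
    stopifnot(is(chemProfiles, "GeneSignatureSet"),
              is(diseaseSigs, "GeneSignatureSet"))
    if (!length(chemProfiles) || !length(diseaseSigs))
        stop("profiles must be non-empty")
    mode <- match.arg(mode)
    universe <- unique(toupper(universe))
    chemCls <- lapply(seq_along(chemProfiles@ids), function(i)
        classifyGenes(universe, chemProfiles@up[[i]], chemProfiles@down[[i]]))
    disCls <- lapply(seq_along(diseaseSigs@ids), function(i)
        classifyGenes(universe, diseaseSigs@up[[i]], diseaseSigs@down[[i]]))
    chemIds <- sort(chemProfiles@ids)
    disIds <- sort(diseaseSigs@ids)
    m <- matrix(0, length(chemIds), length(disIds),
                dimnames = list(chemIds, disIds))
    for (ci in seq_along(chemIds)) {
        cc <- chemCls[[match(chemIds[ci], chemProfiles@ids)]]
        for (di in seq_along(disIds)) {
            dd <- disCls[[match(disIds[di], diseaseSigs@ids)]]
            tab <- crossTab(cc, dd, mode)
            if (is.null(tab)) next
            m[ci, di] <- enrichmentScore(fisherTwoTailed(tab), scoreCap)
        }
    }
    AssociationMatrix(m)
}
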