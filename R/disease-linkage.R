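#' @include chipea-core.R
NULL

#' Link chemical-TF scores to diseases through protein-disease associations
#'
#' A chemical-disease prediction exists iff at least one TF scored for the
#' chemical is recorded as a disease-associated protein; the prediction
#' inherits the highest enrichment score among those TFs (no new score is
#' invented). When several TFs tie at the maximum, the lexicographically
#' smallest TF symbol is reported as the mediator.
#'
#' @param tfScores chemical-TF scores from [aggregateByTF()].
#' @param assoc protein-disease associations from [readProteinDisease()].
#' @return data frame chemical_id, disease_id, disease_name, score,
#'   mediating_tf, direction.
#' @export
linkDiseases <- function(tfScores, assoc) {
    if (!nrow(assoc)) stop("empty protein-disease association list")
    m <- merge(tfScores, assoc, by.x = "tf", by.y = "protein")
    if (!nrow(m))
        return(data.frame(chemical_id = character(0),
                          disease_id = character(0),
                          disease_name = character(0), score = numeric(0),
                          mediating_tf = character(0),
                          direction = character(0)))
    o <- order(m$chemical_id, m$disease_id, -m$score, m$tf, method = "radix")
    m <- m[o, , drop = FALSE]
    first <- !duplicated(m[, c("chemical_id", "disease_id")])
    res <- data.frame(chemical_id = m$chemical_id[first],
                      disease_id = m$disease_id[first],
                      disease_name = m$disease_name[first],
                      score = m$score[first],
                      mediating_tf = m$tf[first],
                      direction = m$direction[first],
                      stringsAsFactors = FALSE)
    rownames(res) <- NULL
    res
}

#' Arrange pair scores into a dense chemicals x entities matrix
#'
#' Missing (chemical, entity) cells are filled with score 0 ("no evidence"),
#' giving the total ordering that ROC/PR evaluation requires. Axes are
#' sorted, so the result is independent of input row order.
#'
#' @param pairs data frame of scored pairs; must contain `chemical_id`,
#'   the entity column and `score`.
#' @param chemicals,entities axis values; default: sorted unique values
#'   observed in `pairs`.
#' @param entityCol name of the entity column (`"disease_id"` for
#'   predictions from [linkDiseases()], `"tf"` for [aggregateByTF()] output).
#' @return An [AssociationMatrix-class] without labels.
#' @export
predictionMatrix <- function(pairs, chemicals = NULL, entities = NULL,
                             entityCol = "disease_id") {
    if (is.null(chemicals)) chemicals <- unique(pairs$chemical_id)
    if (is.null(entities)) entities <- unique(pairs[[entityCol]])
    chemicals <- sort(as.character(chemicals))
    entities <- sort(as.character(entities))
    m <- matrix(0, length(chemicals), length(entities),
                dimnames = list(chemicals, entities))
    i <- match(pairs$chemical_id, chemicals)
    j <- match(pairs[[entityCol]], entities)
    keep <- !is.na(i) & !is.na(j)
    m[cbind(i[keep], j[keep])] <- pairs$score[keep]
    AssociationMatrix(m)
}
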