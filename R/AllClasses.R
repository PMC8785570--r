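#' @include chipea-package.R
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' GeneSignatureSet: up/down gene-symbol sets keyed by identifier
#'
#' Container for signed expression signatures: one record per chemical (CTD
#' dialect) or per disease (signature dialect), each holding the set of
#' up-regulated and the set of down-regulated gene symbols. The two sets of a
#' record are disjoint by construction.
#'
#' @slot ids character, unique record identifiers (chemical or disease ids).
#' @slot labels character, display names parallel to `ids`.
#' @slot up list of character vectors, up-regulated symbols per record.
#' @slot down list of character vectors, down-regulated symbols per record.
#'
#' @seealso [readChemicalDegs()], [readDiseaseSignatures()]
#' @exportClass GeneSignatureSet
setClass("GeneSignatureSet",
    representation(ids = "character", labels = "character",
                   up = "list", down = "list"))

setValidity("GeneSignatureSet", function(object) {
    n <- length(object@ids)
    if (length(object@labels) != n || length(object@up) != n ||
        length(object@down) != n)
        return("ids, labels, up and down must have equal length")
    if (anyDuplicated(object@ids))
        return("ids must be unique")
    if (n > 0 && (any(is.na(object@ids)) || any(!nzchar(object@ids))))
        return("ids must be non-empty strings")
    for (i in seq_len(n)) {
        if (length(intersect(object@up[[i]], object@down[[i]])))
            return(sprintf("record '%s': up and down sets overlap",
                           object@ids[i]))
    }
    TRUE
})

#' Construct a GeneSignatureSet
#'
#' @param ids character vector of unique record identifiers.
#' @param up,down lists of character vectors (one element per id). Symbols
#'   are upper-cased and de-duplicated; symbols present in both sets of one
#'   record are removed from both (the enrichment test needs disjoint
#'   categories).
#' @param labels optional display names (defaults to `ids`).
#' @return A [GeneSignatureSet-class] object.
#' @examples
#' gs <- GeneSignatureSet("D001", up = list(c("TP53", "MYC")),
#'                        down = list("GATA1"))
#' upGenes(gs, "D001")
#' @export
GeneSignatureSet <- function(ids, up, down, labels = ids) {
    ids <- as.character(ids)
    up <- lapply(up, function(x) unique(toupper(as.character(x))))
    down <- lapply(down, function(x) unique(toupper(as.character(x))))
    for (i in seq_along(ids)) {
        both <- intersect(up[[i]], down[[i]])
        if (length(both)) {
            up[[i]] <- setdiff(up[[i]], both)
            down[[i]] <- setdiff(down[[i]], both)
        }
    }
    new("GeneSignatureSet", ids = ids, labels = as.character(labels),
        up = unname(up), down = unname(down))
}

#' @describeIn GeneSignatureSet number of records
#' @param x a `GeneSignatureSet`
#' @export
setMethod("length", "GeneSignatureSet", function(x) length(x@ids))

#' @describeIn GeneSignatureSet subset by index, logical or id
#' @param i index, logical vector or character id
#' @param j,drop,... ignored
#' @export
setMethod("[", "GeneSignatureSet", function(x, i, j, ..., drop = FALSE) {
    if (is.character(i)) i <- match(i, x@ids)
    if (anyNA(i)) stop("unknown signature id")
    new("GeneSignatureSet", ids = x@ids[i], labels = x@labels[i],
        up = x@up[i], down = x@down[i])
})

setMethod("show", "GeneSignatureSet", function(object) {
    n <- length(object)
    cat(sprintf("GeneSignatureSet with %d record%s\n", n,
                if (n == 1) "" else "s"))
    if (n) {
        sizes <- sprintf("%s (up %d / down %d)", object@ids,
                         lengths(object@up), lengths(object@down))
        cat(" ", paste(head(sizes, 5), collapse = ", "),
            if (n > 5) ", ..." else "", "\n", sep = "")
    }
})

.sigIndex <- function(x, id) {
    i <- if (is.character(id)) match(id, x@ids) else as.integer(id)
    if (anyNA(i) || any(i < 1L) || any(i > length(x@ids)))
        stop("unknown signature id: ", id)
    i
}

#' @rdname GeneSignatureSet
#' @export
signatureIds <- function(x) x@ids

#' @rdname GeneSignatureSet
#' @export
signatureLabels <- function(x) x@labels

#' @rdname GeneSignatureSet
#' @param id record identifier (string) or index
#' @export
upGenes <- function(x, id) x@up[[.sigIndex(x, id)]]

#' @rdname GeneSignatureSet
#' @export
downGenes <- function(x, id) x@down[[.sigIndex(x, id)]]

#' AssociationMatrix: chemicals x entities score matrix with optional truth
#'
#' Dense score matrix over chemicals (rows) and entities — TFs or diseases —
#' (columns), optionally carrying a binary truth matrix of identical shape.
#' The substrate for all AUROC/AUPR evaluation.
#'
#' @slot scores numeric matrix with dimnames (chemicals x entities).
#' @slot labels binary (0/1) matrix of the same shape, or NULL.
#'
#' @exportClass AssociationMatrix
setClass("AssociationMatrix",
    representation(scores = "matrix", labels = "matrixOrNULL"))

setValidity("AssociationMatrix", function(object) {
    s <- object@scores
    if (!is.numeric(s)) return("scores must be numeric")
    if (is.null(rownames(s)) || is.null(colnames(s)))
        return("scores must carry dimnames (chemicals x entities)")
    l <- object@labels
    if (!is.null(l)) {
        if (!identical(dim(l), dim(s)))
            return("labels shape must match scores shape")
        if (!all(l %in% c(0, 1)))
            return("labels must be binary 0/1")
    }
    TRUE
})

#' Construct an AssociationMatrix
#'
#' @param scores numeric matrix with row (chemical) and column (entity) names.
#' @param labels optional 0/1 matrix of the same shape.
#' @return An [AssociationMatrix-class] object.
#' @export
AssociationMatrix <- function(scores, labels = NULL) {
    if (!is.null(labels)) {
        labels <- as.matrix(labels)
        storage.mode(labels) <- "double"
        dimnames(labels) <- dimnames(scores)
    }
    new("AssociationMatrix", scores = as.matrix(scores), labels = labels)
}

#' @rdname AssociationMatrix
#' @param x an `AssociationMatrix`
#' @export
scoreMatrix <- function(x) x@scores

#' @rdname AssociationMatrix
#' @export
labelMatrix <- function(x) x@labels

#' @rdname AssociationMatrix
#' @export
hasLabels <- function(x) !is.null(x@labels)

#' @rdname AssociationMatrix
#' @export
chemicals <- function(x) rownames(x@scores)

#' @rdname AssociationMatrix
#' @export
entities <- function(x) colnames(x@scores)

#' @describeIn AssociationMatrix matrix dimensions
#' @export
setMethod("dim", "AssociationMatrix", function(x) dim(x@scores))

setMethod("show", "AssociationMatrix", function(object) {
    d <- dim(object@scores)
    cat(sprintf("AssociationMatrix: %d chemicals x %d entities (%s labels)\n",
                d[1], d[2], if (hasLabels(object)) "with" else "no"))
    if (hasLabels(object))
        cat(sprintf("  positives: %d of %d cells\n",
                    sum(object@labels), length(object@labels)))
})

#' Attach binary truth labels from a standard of known positive pairs
#'
#' @param x an [AssociationMatrix-class].
#' @param positives data frame whose first column is the chemical id and
#'   second column the entity id of each known true association; pairs
#'   outside the matrix axes are ignored.
#' @return The matrix with a 0/1 label matrix attached.
#' @export
addTruthLabels <- function(x, positives) {
    stopifnot(is(x, "AssociationMatrix"))
    lab <- matrix(0, nrow(x@scores), ncol(x@scores),
                  dimnames = dimnames(x@scores))
    i <- match(as.character(positives[[1]]), rownames(lab))
    j <- match(as.character(positives[[2]]), colnames(lab))
    keep <- !is.na(i) & !is.na(j)
    lab[cbind(i[keep], j[keep])] <- 1
    AssociationMatrix(x@scores, lab)
}
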