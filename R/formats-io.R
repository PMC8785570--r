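#' @include AllClasses.R
NULL

# headered TSV/CSV reader with required-column check
.readTable <- function(path, required, sep = "\t") {
    if (!file.exists(path)) stop("cannot read file: ", path)
    dt <- data.table::fread(path, sep = sep, header = TRUE,
                            data.table = FALSE, colClasses = "character")
    miss <- setdiff(required, names(dt))
    if (length(miss))
        stop("missing required column(s) in ", path, ": ",
             paste(miss, collapse = ", "))
    dt
}

#' Read a refFlat gene annotation
#'
#' Parses the standard 11-column UCSC refFlat dialect (tab-separated, no
#' header): geneName, name, chrom, strand, txStart, txEnd, cdsStart, cdsEnd,
#' exonCount, exonStarts, exonEnds. Coordinates are 0-based half-open as
#' distributed by UCSC. Rows with malformed coordinates (non-numeric, or
#' txStart >= txEnd) or a strand other than +/- are skipped with a warning.
#' Gene symbols are upper-cased. Duplicate (symbol, transcript) rows are
#' retained as separate transcript models.
#'
#' @param path path to a refFlat file.
#' @return data frame with columns `symbol`, `txname`, `chrom`, `strand`,
#'   `txStart`, `txEnd` (0-based half-open), one row per transcript.
#' @export
readRefFlat <- function(path) {
    if (!file.exists(path)) stop("cannot read refFlat file: ", path)
    dt <- data.table::fread(path, sep = "\t", header = FALSE,
                            data.table = FALSE, colClasses = "character")
    if (ncol(dt) < 6) stop("refFlat file has fewer than 6 columns: ", path)
    txStart <- suppressWarnings(as.numeric(dt[[5]]))
    txEnd <- suppressWarnings(as.numeric(dt[[6]]))
    ok <- !is.na(txStart) & !is.na(txEnd) & txStart < txEnd &
        dt[[4]] %in% c("+", "-") & nzchar(dt[[1]])
    if (any(!ok))
        warning(sum(!ok), " malformed refFlat row(s) skipped")
    if (!any(ok)) stop("no valid rows in refFlat file: ", path)
    data.frame(symbol = toupper(dt[[1]][ok]), txname = dt[[2]][ok],
               chrom = dt[[3]][ok], strand = dt[[4]][ok],
               txStart = txStart[ok], txEnd = txEnd[ok],
               stringsAsFactors = FALSE)
}

#' Read ChIP-seq peak calls (BED4/BED5) and experiment metadata
#'
#' Column 4 of the BED file is the experiment accession; an optional column 5
#' is a numeric peak score. Metadata is a two-column headered TSV
#' (experiment_id, antigen) mapping each experiment to its ChIP antigen (TF).
#' Peaks whose experiment lacks metadata are dropped with a counted warning;
#' when `minScore` is given and the file has scores, peaks with
#' score < `minScore` are dropped (threshold inclusive).
#'
#' @param path BED4/BED5 peak file (0-based half-open intervals).
#' @param metadataPath experiment metadata TSV.
#' @param minScore optional inclusive lower bound on the score column.
#' @return list with `peaks` (a [GenomicRanges::GRanges] with metadata
#'   columns `experiment_id` and `score`; BED intervals converted to the
#'   1-based closed GRanges convention), `meta` (data frame experiment_id,
#'   antigen) and `dropped` (named counts of excluded peaks).
#' @export
readPeaks <- function(path, metadataPath, minScore = NULL) {
    if (!file.exists(path)) stop("cannot read peak file: ", path)
    nf <- utils::count.fields(path, sep = "\t", quote = "",
                              comment.char = "")
    if (!length(nf)) stop("empty peak file: ", path)
    bad <- which(nf != nf[1])
    if (length(bad))
        stop("inconsistent column count in ", path, " at line ", bad[1],
             " (", nf[bad[1]], " columns, expected ", nf[1], ")")
    if (!nf[1] %in% c(4L, 5L))
        stop("peak file must be BED4 or BED5, got ", nf[1], " columns")
    dt <- data.table::fread(path, sep = "\t", header = FALSE,
                            data.table = FALSE)
    meta <- .readTable(metadataPath, c("experiment_id", "antigen"))
    meta$antigen <- toupper(meta$antigen)
    meta <- unique(meta[, c("experiment_id", "antigen")])
    if (anyDuplicated(meta$experiment_id))
        stop("conflicting antigen assignments in ", metadataPath)

    score <- if (ncol(dt) >= 5) as.numeric(dt[[5]]) else rep(NA_real_, nrow(dt))
    keep <- rep(TRUE, nrow(dt))
    droppedScore <- 0L
    if (!is.null(minScore) && ncol(dt) >= 5) {
        keep <- is.na(score) | score >= minScore
        droppedScore <- sum(!keep)
    }
    known <- dt[[4]] %in% meta$experiment_id
    droppedUnknown <- sum(keep & !known)
    if (droppedUnknown > 0)
        warning(droppedUnknown,
                " peak(s) dropped: experiment id missing from metadata")
    keep <- keep & known
    peaks <- GenomicRanges::GRanges(
        seqnames = dt[[1]][keep],
        ranges = IRanges::IRanges(start = dt[[2]][keep] + 1L,
                                  end = dt[[3]][keep]),
        experiment_id = as.character(dt[[4]][keep]),
        score = score[keep])
    list(peaks = peaks, meta = meta,
         dropped = c(unknown_experiment = droppedUnknown,
                     below_score = droppedScore))
}

#' Read chemically induced DEG profiles (CTD chemical-gene dialect)
#'
#' Reads a CSV with columns ChemicalName, ChemicalID, GeneSymbol, Organism
#' and InteractionActions. Only rows for `organismFilter` carrying an
#' expression-direction token — `increases^expression` or
#' `decreases^expression` — in the actions field are used; the free-text
#' interaction sentence, if present, is ignored. Per chemical the up and
#' down gene-symbol sets are formed (upper-cased); a symbol curated in both
#' directions for the same chemical is removed from both sets. Profiles with
#' fewer than `minEach` genes on either side are dropped; the default 11
#' realizes the "more than ten each" admission rule.
#'
#' @param path chemical-gene interaction CSV.
#' @param organismFilter organism string to retain (default "Homo sapiens").
#' @param minEach minimum size of each of the up and down sets.
#' @return A [GeneSignatureSet-class] keyed by ChemicalID with ChemicalName
#'   labels.
#' @export
readChemicalDegs <- function(path, organismFilter = "Homo sapiens",
                             minEach = 11L) {
    dt <- .readTable(path, c("ChemicalName", "ChemicalID", "GeneSymbol",
                             "Organism", "InteractionActions"), sep = ",")
    dt <- dt[dt$Organism == organismFilter, , drop = FALSE]
    inc <- grepl("increases^expression", dt$InteractionActions, fixed = TRUE)
    dec <- grepl("decreases^expression", dt$InteractionActions, fixed = TRUE)
    dt <- dt[inc | dec, , drop = FALSE]
    ids <- unique(dt$ChemicalID)
    up <- down <- vector("list", length(ids))
    labs <- character(length(ids))
    for (k in seq_along(ids)) {
        rows <- dt$ChemicalID == ids[k]
        incK <- grepl("increases^expression", dt$InteractionActions[rows],
                      fixed = TRUE)
        decK <- grepl("decreases^expression", dt$InteractionActions[rows],
                      fixed = TRUE)
        up[[k]] <- unique(dt$GeneSymbol[rows][incK])
        down[[k]] <- unique(dt$GeneSymbol[rows][decK])
        labs[k] <- dt$ChemicalName[rows][1]
    }
    gs <- GeneSignatureSet(ids, up, down, labels = labs)
    keep <- lengths(gs@up) >= minEach & lengths(gs@down) >= minEach
    gs[which(keep)]
}

#' Read protein-disease associations
#'
#' Headered TSV with columns `protein`, `disease_id`, `disease_name`
#' (curated gene/protein-disease dialect). Duplicate (protein, disease_id)
#' pairs are collapsed; protein symbols are upper-cased.
#'
#' @param path association TSV.
#' @return data frame protein, disease_id, disease_name.
#' @export
readProteinDisease <- function(path) {
    dt <- .readTable(path, c("protein", "disease_id", "disease_name"))
    dt$protein <- toupper(dt$protein)
    dt <- dt[!duplicated(dt[, c("protein", "disease_id")]), , drop = FALSE]
    if (!nrow(dt)) stop("empty protein-disease association set: ", path)
    rownames(dt) <- NULL
    dt
}

#' Read a chemical-protein interaction standard
#'
#' Headered TSV with columns `chemical_id`, `protein`; returns the
#' de-duplicated pair set (protein symbols upper-cased).
#'
#' @param path interaction TSV.
#' @return data frame chemical_id, protein (unique pairs).
#' @export
readChemicalProtein <- function(path) {
    dt <- .readTable(path, c("chemical_id", "protein"))
    dt$protein <- toupper(dt$protein)
    dt <- unique(dt[, c("chemical_id", "protein")])
    if (!nrow(dt)) stop("empty chemical-protein association set: ", path)
    rownames(dt) <- NULL
    dt
}

#' Read a chemical-disease association standard
#'
#' Headered TSV with columns `chemical_id`, `disease_id`; returns the
#' de-duplicated pair set.
#'
#' @param path association TSV.
#' @return data frame chemical_id, disease_id (unique pairs).
#' @export
readChemicalDisease <- function(path) {
    dt <- .readTable(path, c("chemical_id", "disease_id"))
    dt <- unique(dt[, c("chemical_id", "disease_id")])
    if (!nrow(dt)) stop("empty chemical-disease association set: ", path)
    rownames(dt) <- NULL
    dt
}

#' Read disease expression signatures (signed per-gene scores)
#'
#' JSON array of records `{"disease_id": ..., "scores": {gene: score, ...}}`.
#' Genes with positive score become the up set, negative the down set; a
#' score of exactly 0 is excluded from both.
#'
#' @param path JSON signature file.
#' @return A [GeneSignatureSet-class] keyed by disease_id.
#' @export
readDiseaseSignatures <- function(path) {
    if (!file.exists(path)) stop("cannot read signature file: ", path)
    recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    if (!length(recs)) stop("empty disease signature file: ", path)
    ids <- vapply(recs, function(r) as.character(r$disease_id), "")
    up <- lapply(recs, function(r) {
        s <- unlist(r$scores)
        names(s)[s > 0]
    })
    down <- lapply(recs, function(r) {
        s <- unlist(r$scores)
        names(s)[s < 0]
    })
    GeneSignatureSet(ids, up, down)
}

.writeTsv <- function(df, path) {
    ok <- tryCatch({
        # suppress the R-level connection warning that precedes the error
        suppressWarnings(write.table(df, path, sep = "\t", quote = FALSE,
                                     row.names = FALSE, col.names = TRUE))
        TRUE
    }, error = function(e) e)
    if (!isTRUE(ok)) stop("cannot write output file ", path, ": ",
                          conditionMessage(ok))
    invisible(path)
}

#' Write an enrichment table
#'
#' Serializes per-experiment enrichment records as a headered TSV with
#' deterministic ordering: descending score, ties broken lexicographically
#' by (tf, experiment_id). An infinite fold enrichment is written as `Inf`.
#'
#' @param records data frame as returned by [runChipea()].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writeEnrichmentTable <- function(records, path) {
    cols <- c("chemical_id", "experiment_id", "tf", "a", "b", "c", "d",
              "p", "score", "fold", "direction")
    records <- records[, cols, drop = FALSE]
    o <- order(-records$score, records$tf, records$experiment_id,
               records$chemical_id, method = "radix")
    .writeTsv(records[o, , drop = FALSE], path)
}

#' Write a chemical-disease prediction table
#'
#' Headered TSV with deterministic ordering: descending score, ties broken
#' lexicographically by (chemical_id, disease_id).
#'
#' @param predictions data frame as returned by [linkDiseases()].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
writePredictionTable <- function(predictions, path) {
    cols <- c("chemical_id", "disease_id", "disease_name", "score",
              "mediating_tf", "direction")
    predictions <- predictions[, cols, drop = FALSE]
    o <- order(-predictions$score, predictions$chemical_id,
               predictions$disease_id, method = "radix")
    .writeTsv(predictions[o, , drop = FALSE], path)
}
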