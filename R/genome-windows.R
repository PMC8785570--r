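#' @include formats-io.R
NULL

#' Build TSS-flank windows for every transcript
#'
#' For each transcript the window spans the transcription start site plus and
#' minus `flank` bp: on the + strand the TSS is `txStart`, on the - strand it
#' is `txEnd` (the half-open end coordinate, standard UCSC practice). Window
#' arithmetic is done in BED coordinates (0-based half-open) and clipped at
#' the chromosome origin; no right clipping is applied because refFlat does
#' not carry chromosome lengths (harmless for overlap testing). Every
#' transcript of a symbol keeps its own window — overlap is gene-level
#' binary, so no merging is needed.
#'
#' @param genes data frame from [readRefFlat()].
#' @param flank half-width of the window in bp (default 5000, i.e. TSS +/-
#'   5 kb).
#' @return [GenomicRanges::GRanges] of windows with a `symbol` metadata
#'   column (1-based closed coordinates).
#' @examples
#' genes <- data.frame(symbol = "G1", txname = "T1", chrom = "chr1",
#'                     strand = "+", txStart = 100000, txEnd = 105000)
#' tssWindows(genes, flank = 5000)
#' @export
tssWindows <- function(genes, flank = 5000L) {
    if (!is.data.frame(genes) || !nrow(genes)) stop("empty gene list")
    if (!is.numeric(flank) || length(flank) != 1L || flank <= 0)
        stop("flank must be a single positive number")
    tss <- ifelse(genes$strand == "+", genes$txStart, genes$txEnd)
    start0 <- pmax(tss - flank, 0)
    end0 <- tss + flank
    GenomicRanges::GRanges(
        seqnames = genes$chrom,
        ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
        symbol = toupper(genes$symbol))
}

#' Gene symbols whose TSS window overlaps at least one peak
#'
#' bedtools-intersect semantics on half-open intervals: a symbol is reported
#' iff at least one of its windows shares >= 1 bp with at least one peak.
#' Abutting intervals do not overlap. Each symbol is reported once however
#' many peaks or windows hit it.
#'
#' @param windows GRanges from [tssWindows()].
#' @param peaks GRanges of peak calls (any subset, typically one
#'   experiment's).
#' @return character vector of unique overlapped symbols.
#' @export
overlappingSymbols <- function(windows, peaks) {
    if (!length(peaks)) return(character(0))
    hits <- GenomicRanges::findOverlaps(peaks, windows)
    unique(S4Vectors::mcols(windows)$symbol[S4Vectors::subjectHits(hits)])
}

#' Export TSS windows as a BED file (debugging aid)
#'
#' @param windows GRanges from [tssWindows()].
#' @param path output BED path (0-based half-open, name column = symbol).
#' @return the path, invisibly.
#' @export
exportWindowsBed <- function(windows, path) {
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(windows)),
                     start = GenomicRanges::start(windows) - 1L,
                     end = GenomicRanges::end(windows),
                     name = S4Vectors::mcols(windows)$symbol)
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}
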