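test_that("refFlat parsing maps fields, skips malformed rows, fails on empty", {
    f <- withr::local_tempfile(fileext = ".txt")
    rows <- c("Gene1\tNM_1\tchr1\t+\t1000\t5000\t1000\t5000\t1\t1000,\t5000,",
              "gene2\tNM_2\tchr2\t-\t200\t800\t200\t800\t1\t200,\t800,",
              "BAD\tNM_3\tchr1\t+\t5000\t1000\t.\t.\t1\t.,\t.,",     # start >= end
              "BAD2\tNM_4\tchr1\t*\t10\t20\t.\t.\t1\t.,\t.,")       # bad strand
    writeLines(rows, f)
    expect_warning(g <- readRefFlat(f), "malformed")
    expect_equal(nrow(g), 2)
    expect_equal(g$symbol, c("GENE1", "GENE2"))  # upper-cased
    expect_equal(g$txStart, c(1000, 200))
    expect_equal(g$strand, c("+", "-"))

    writeLines(rows[3:4], f)
    expect_warning(expect_error(readRefFlat(f), "no valid rows"))
    expect_error(readRefFlat(file.path(tempdir(), "nope.txt")), "cannot read")
})

test_that("refFlat round-trips through the fixture generator's writer", {
    d <- withr::local_tempdir()
    f <- workedExample(d)
    g1 <- readRefFlat(f[["refflat"]])
    # rewrite what was read, re-read, compare
    f2 <- file.path(d, "again.txt")
    write.table(data.frame(g1$symbol, g1$txname, g1$chrom, g1$strand,
                           g1$txStart, g1$txEnd, g1$txStart, g1$txEnd, 1L,
                           paste0(g1$txStart, ","), paste0(g1$txEnd, ",")),
                f2, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    expect_identical(readRefFlat(f2), g1)
})

test_that("peak reading: metadata join, unknown experiments, score threshold", {
    d <- withr::local_tempdir()
    bed <- file.path(d, "p.bed")
    meta <- file.path(d, "m.tsv")
    writeLines(c("experiment_id\tantigen", "SRX001\tar"), meta)

    writeLines(c("chr1\t100\t200\tSRX001", "chr1\t300\t400\tSRXUNKNOWN"), bed)
    expect_warning(res <- readPeaks(bed, meta), "missing from metadata")
    expect_equal(length(res$peaks), 1)
    expect_equal(unname(res$dropped["unknown_experiment"]), 1L)
    expect_equal(res$meta$antigen, "AR")  # upper-cased
    # BED half-open [100, 200) becomes 1-based closed [101, 200]
    expect_equal(GenomicRanges::start(res$peaks), 101)
    expect_equal(GenomicRanges::end(res$peaks), 200)

    writeLines(c("chr1\t100\t200\tSRX001\t49",
                 "chr1\t300\t400\tSRX001\t50"), bed)
    res <- readPeaks(bed, meta, minScore = 50)
    expect_equal(length(res$peaks), 1)          # 49 dropped, 50 kept
    expect_equal(S4Vectors::mcols(res$peaks)$score, 50)

    writeLines(c("chr1\t100\t200\tSRX001", "chr1\t300\t400\tSRX001\t50"), bed)
    expect_error(readPeaks(bed, meta), "line 2")
})

.degCsv <- function(path, rows) {
    writeLines(c("ChemicalName,ChemicalID,GeneSymbol,Organism,InteractionActions",
                 rows), path)
}

test_that("chemical DEG admission: direction tokens, disjointness, size filter", {
    f <- withr::local_tempfile(fileext = ".csv")
    mk <- function(chem, genes, act, org = "Homo sapiens")
        sprintf("%s,%s,%s,%s,%s", chem, chem, genes, org, act)
    rows <- c(mk("A", sprintf("u%02d", 1:11), "increases^expression"),
              mk("A", sprintf("d%02d", 1:11), "decreases^expression"),
              # chemical B: only 10 up -> dropped despite 200 down
              mk("B", sprintf("u%02d", 1:10), "increases^expression"),
              mk("B", sprintf("d%03d", 1:200), "decreases^expression"),
              # mouse rows never count
              mk("A", "mousegene", "increases^expression", org = "Mus musculus"),
              # non-expression action ignored
              mk("A", "phosgene", "increases^phosphorylation"))
    .degCsv(f, rows)
    gs <- readChemicalDegs(f, minEach = 11)
    expect_equal(signatureIds(gs), "A")
    expect_setequal(upGenes(gs, "A"), toupper(sprintf("u%02d", 1:11)))
    expect_false("MOUSEGENE" %in% upGenes(gs, "A"))
    expect_false("PHOSGENE" %in% upGenes(gs, "A"))

    # gene reported in both directions disappears from both sets
    .degCsv(f, c(mk("A", c(sprintf("u%02d", 1:11), "both"),
                    "increases^expression"),
                 mk("A", c(sprintf("d%02d", 1:11), "both"),
                    "decreases^expression")))
    gs <- readChemicalDegs(f, minEach = 11)
    expect_false("BOTH" %in% c(upGenes(gs, "A"), downGenes(gs, "A")))

    # admission boundary: exactly minEach on each side is retained
    expect_equal(length(upGenes(gs, "A")), 11)
    expect_equal(length(downGenes(gs, "A")), 11)

    writeLines("ChemicalName,ChemicalID,GeneSymbol\nA,A,g", f)
    expect_error(readChemicalDegs(f), "missing required column")
})

test_that("chemical DEG parsing is row-order independent", {
    f1 <- withr::local_tempfile(fileext = ".csv")
    f2 <- withr::local_tempfile(fileext = ".csv")
    mk <- function(chem, gene, act)
        sprintf("%s,%s,%s,Homo sapiens,%s", chem, chem, gene, act)
    rows <- c(vapply(sprintf("u%02d", 1:12), function(g)
                  mk("A", g, "increases^expression"), ""),
              vapply(sprintf("d%02d", 1:12), function(g)
                  mk("A", g, "decreases^expression"), ""))
    .degCsv(f1, rows)
    set.seed(3)
    .degCsv(f2, sample(rows))
    g1 <- readChemicalDegs(f1, minEach = 11)
    g2 <- readChemicalDegs(f2, minEach = 11)
    expect_setequal(upGenes(g1, "A"), upGenes(g2, "A"))
    expect_setequal(downGenes(g1, "A"), downGenes(g2, "A"))
})

test_that("association and signature readers dedupe and split by sign", {
    d <- withr::local_tempdir()
    f <- file.path(d, "pd.tsv")
    writeLines(c("protein\tdisease_id\tdisease_name",
                 "tp53\tC01\tcancer", "TP53\tC01\tcancer", "MYC\tC02\tother"),
               f)
    pd <- readProteinDisease(f)
    expect_equal(nrow(pd), 2)        # case-normalized duplicate collapsed
    expect_true(all(pd$protein %in% c("TP53", "MYC")))

    f <- file.path(d, "cp.tsv")
    writeLines(c("chemical_id\tprotein", "D1\tAR", "D1\tAR", "D2\tESR1"), f)
    expect_equal(nrow(readChemicalProtein(f)), 2)
    writeLines("chemical_id\tprotein", f)
    expect_error(readChemicalProtein(f), "empty")

    f <- file.path(d, "sig.json")
    writeLines(jsonlite::toJSON(list(list(disease_id = "C01",
                                          scores = list(g1 = 2.1, g2 = -0.3,
                                                        g3 = 0))),
                                auto_unbox = TRUE), f)
    sig <- readDiseaseSignatures(f)
    expect_equal(upGenes(sig, "C01"), "G1")
    expect_equal(downGenes(sig, "C01"), "G2")   # score 0 in neither set
})

test_that("enrichment table writing: ordering, degenerate input, round-trip", {
    rec <- data.frame(chemical_id = "D1",
                      experiment_id = c("SRX2", "SRX1", "SRX3"),
                      tf = c("AR", "AR", "MYC"),
                      a = 2L, b = 1L, c = 1L, d = 2L,
                      p = c(0.5, 0.5, 1 / 3),
                      score = c(0.301029995663981, 0.301029995663981,
                                0.477121254719662),
                      fold = c(2, 2, Inf),
                      direction = "up-biased", stringsAsFactors = FALSE)
    f <- withr::local_tempfile(fileext = ".tsv")
    writeEnrichmentTable(rec, f)
    back <- read.delim(f)
    # descending score first; equal scores ordered by (tf, experiment_id)
    expect_equal(back$experiment_id, c("SRX3", "SRX1", "SRX2"))
    expect_equal(back$fold[1], Inf)
    expect_equal(back$p, c(1 / 3, 0.5, 0.5), tolerance = 1e-6)
    expect_equal(back$score, sort(rec$score, decreasing = TRUE),
                 tolerance = 1e-6)

    writeEnrichmentTable(rec[0, ], f)
    expect_equal(nrow(read.delim(f)), 0)   # header-only file
    expect_error(writeEnrichmentTable(rec, file.path(tempdir(), "no/dir/x")),
                 "cannot write")
})
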