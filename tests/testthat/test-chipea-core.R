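test_that("contingency tables count annotated DEGs and reject overlap", {
    expect_equal(makeContingencyTable(c("g1", "g2"), c("g3", "g4"),
                                      hit = c("g1", "g3"),
                                      annotated = paste0("g", 1:4)),
                 c(a = 1, b = 1, c = 1, d = 1))
    # unannotated DEG drops out of the table entirely
    expect_equal(makeContingencyTable(c("g1", "g2"), "g3", hit = "g1",
                                      annotated = c("g1", "g3")),
                 c(a = 1, b = 0, c = 0, d = 1))
    expect_equal(makeContingencyTable(c("g1", "g2"), c("g3", "g4"),
                                      hit = character(0),
                                      annotated = paste0("g", 1:4)),
                 c(a = 0, b = 2, c = 0, d = 2))
    # one side empty after annotation filtering -> undefined table
    expect_null(makeContingencyTable(c("g1", "g2"), "g9", hit = "g1",
                                     annotated = c("g1", "g2")))
    expect_error(makeContingencyTable("g1", "g1", "g1", "g1"), "disjoint")
})

test_that("two-tailed exact p matches hand enumeration on tiny tables", {
    expect_equal(fisherTwoTailed(5, 5, 5, 5), 1)
    # margins 2/2, overlap 2: probabilities {1/6, 4/6, 1/6}; sum of <= 1/6
    expect_equal(fisherTwoTailed(2, 0, 0, 2), 1 / 3, tolerance = 1e-12)
    expect_equal(fisherTwoTailed(c(2, 0, 0, 2)), 1 / 3, tolerance = 1e-12)
    expect_error(fisherTwoTailed(-1, 1, 1, 1), "non-negative")
})

test_that("exact p agrees with enumeration and fisher.test over a sweep", {
    for (r1 in c(1, 3, 7)) for (r2 in c(1, 4, 8)) {
        for (a in 0:r1) for (cc in 0:r2) {
            tab <- c(a, r1 - a, cc, r2 - cc)
            expect_equal(fisherTwoTailed(tab), do.call(fisherOracle,
                                                       as.list(tab)),
                         tolerance = 1e-12)
        }
    }
    # independent cross-check against the reference implementation
    set.seed(5)
    for (i in 1:40) {
        tab <- as.vector(rmultinom(1, sample(8:60, 1), rep(0.25, 4)))
        if (sum(tab[1:2]) == 0 || sum(tab[3:4]) == 0) next
        ft <- fisher.test(matrix(tab, 2, byrow = TRUE))$p.value
        expect_equal(fisherTwoTailed(tab), ft, tolerance = 1e-9)
    }
})

test_that("enrichment score and fold enrichment follow their conventions", {
    expect_equal(enrichmentScore(1), 0)
    expect_equal(enrichmentScore(0.001), 3)
    expect_equal(enrichmentScore(fisherTwoTailed(2, 0, 0, 2)), 0.4771213,
                 tolerance = 1e-7)
    expect_equal(enrichmentScore(1e-400), 320)     # capped at the floor
    expect_error(enrichmentScore(0 - 1e-9), "p must lie")
    expect_error(enrichmentScore(1.5), "p must lie")

    expect_equal(foldEnrichment(10, 10, 5, 15), 2)
    expect_equal(foldEnrichment(0, 5, 0, 5), 1)    # no evidence
    expect_equal(foldEnrichment(3, 2, 0, 5), Inf)  # up-only overlap
    expect_equal(foldEnrichment(0, 5, 3, 2), 0)
})

test_that("swapping up and down sets keeps p, inverts fold and direction", {
    set.seed(11)
    for (i in 1:25) {
        tab <- sample(0:12, 4, replace = TRUE)
        if (sum(tab[1:2]) == 0 || sum(tab[3:4]) == 0) next
        sw <- tab[c(3, 4, 1, 2)]
        expect_equal(fisherTwoTailed(tab), fisherTwoTailed(sw),
                     tolerance = 1e-12)
        f1 <- do.call(foldEnrichment, as.list(tab))
        f2 <- do.call(foldEnrichment, as.list(sw))
        if (f1 == 1) expect_equal(f2, 1)
        else if (is.infinite(f1)) expect_equal(f2, 0)
        else if (f1 == 0) expect_equal(f2, Inf)
        else expect_equal(f2, 1 / f1, tolerance = 1e-12)
    }
})

test_that("the worked example yields its hand-computed enrichment records", {
    d <- withr::local_tempdir()
    f <- workedExample(d)
    genes <- readRefFlat(f[["refflat"]])
    pk <- readPeaks(f[["peaks"]], f[["experiments"]])
    prof <- readChemicalDegs(f[["chem_gene"]], minEach = 1)
    win <- tssWindows(genes, 5000)
    rec <- runChipea(prof, pk$peaks, pk$meta, win)
    expect_equal(nrow(rec), 2)
    ar <- rec[rec$tf == "AR", ]
    expect_equal(unlist(ar[, c("a", "b", "c", "d")], use.names = FALSE),
                 c(2, 0, 0, 2))
    expect_equal(ar$p, 1 / 3, tolerance = 1e-12)
    expect_equal(ar$score, 0.4771213, tolerance = 1e-6)
    expect_equal(ar$direction, "up-biased")
    ng <- rec[rec$tf == "NANOG", ]
    expect_equal(ng$p, 1)
    expect_equal(ng$score, 0)
    expect_equal(ng$direction, "neutral")

    # permuting peak order leaves the records unchanged
    set.seed(2)
    pkShuf <- pk$peaks[sample(length(pk$peaks))]
    expect_equal(runChipea(prof, pkShuf, pk$meta, win), rec,
                 ignore_attr = "skipped")
})

test_that("experiments with no peaks near DEGs score zero, not NA", {
    genes <- data.frame(symbol = c("U1", "D1"), txname = c("t1", "t2"),
                        chrom = "chr1", strand = "+",
                        txStart = c(1e5, 2e5), txEnd = c(1e5, 2e5) + 2000)
    win <- tssWindows(genes, 5000)
    pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(9e5, 9e5 + 100),
                                 experiment_id = "E1", score = NA_real_)
    meta <- data.frame(experiment_id = "E1", antigen = "TFX")
    prof <- GeneSignatureSet("C1", up = list("U1"), down = list("D1"))
    rec <- runChipea(prof, pk, meta, win)
    expect_equal(rec$p, 1)
    expect_equal(rec$score, 0)
    expect_equal(rec$fold, 1)
})

test_that("TF aggregation keeps the best experiment deterministically", {
    rec <- data.frame(chemical_id = "D1",
                      experiment_id = c("SRX9", "SRX2", "SRX5", "SRX1"),
                      tf = c("AR", "AR", "MYC", "MYC"),
                      a = 1L, b = 1L, c = 1L, d = 1L, p = 1,
                      score = c(5.2, 9.1, 4, 4),
                      fold = 1, direction = c("up-biased", "down-biased",
                                              "up-biased", "up-biased"))
    agg <- aggregateByTF(rec)
    expect_equal(agg$score[agg$tf == "AR"], 9.1)
    expect_equal(agg$best_experiment_id[agg$tf == "AR"], "SRX2")
    expect_equal(agg$direction[agg$tf == "AR"], "down-biased")
    # tie between MYC experiments -> smallest experiment id
    expect_equal(agg$best_experiment_id[agg$tf == "MYC"], "SRX1")
    # an extra lower-scoring record cannot change the aggregate
    extra <- rbind(rec, within(rec[1, ], {
        experiment_id <- "SRX0"; score <- 1 }))
    expect_equal(aggregateByTF(extra)$score,  agg$score)
})
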