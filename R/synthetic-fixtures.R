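#' @include deg-baseline.R
NULL

#' Configuration for the synthetic benchmark generator
#'
#' Defaults describe the desk-scale study conditions: a 3-chromosome toy
#' genome of 12,000 genes at 10 kb spacing; 12 TFs with two ChIP-seq
#' experiments each and 850 disjoint target genes per TF; 8,000 uniform
#' background peaks per experiment (a promoter hit rate near 0.5, mirroring
#' the dense promoter coverage of real ChIP-seq compendia); 24 chemicals
#' with 850 up- and 750 down-regulated DEGs each (curated profiles run
#' from 11 to several thousand DEGs; strong perturbagens reach four
#' figures), of which a fraction `signal_fraction` is drawn from the
#' targets of one planted up-driver and one planted down-driver TF; and 10
#' diseases associated with 2 TFs each, assigned so that every TF backs at
#' least one disease. The DEG-set sizes are deliberately large and unequal:
#' the exact test's p-value support is then fine-grained and free of the
#' modal ties that equal margins create, so the null p-value distribution
#' is nearly continuous — which calibration diagnostics presuppose — while
#' staying within the range of real curated profiles.
#'
#' @param n_genes,n_chroms,gene_spacing,gene_length toy genome geometry (bp).
#' @param flank TSS window half-width used for peak placement (bp).
#' @param n_tfs,experiments_per_tf,targets_per_tf planted regulator layout.
#' @param background_peaks_per_experiment,peak_width background noise model.
#' @param n_chemicals,drivers_per_chemical,n_up,n_down,signal_fraction
#'   chemical DEG profile model; `drivers_per_chemical` counts drivers per
#'   direction (one up-driver and one down-driver by default).
#' @param n_diseases,tfs_per_disease disease-association layout.
#' @param seed RNG seed; identical config + seed reproduce byte-identical
#'   fixture directories.
#' @return validated configuration list.
#' @export
fixtureConfig <- function(n_genes = 12000, n_chroms = 3,
                          gene_spacing = 10000,
                          gene_length = 2000, flank = 5000,
                          n_tfs = 12, experiments_per_tf = 2,
                          targets_per_tf = 850,
                          background_peaks_per_experiment = 8000,
                          peak_width = 200,
                          n_chemicals = 24, drivers_per_chemical = 1,
                          n_up = 850, n_down = 750, signal_fraction = 0.8,
                          n_diseases = 10, tfs_per_disease = 2, seed = 17) {
    cfg <- list(n_genes = n_genes, n_chroms = n_chroms,
                gene_spacing = gene_spacing, gene_length = gene_length,
                flank = flank, n_tfs = n_tfs,
                experiments_per_tf = experiments_per_tf,
                targets_per_tf = targets_per_tf,
                background_peaks_per_experiment =
                    background_peaks_per_experiment,
                peak_width = peak_width, n_chemicals = n_chemicals,
                drivers_per_chemical = drivers_per_chemical,
                n_up = n_up, n_down = n_down,
                signal_fraction = signal_fraction,
                n_diseases = n_diseases, tfs_per_disease = tfs_per_disease,
                seed = seed)
    counts <- cfg[setdiff(names(cfg), c("signal_fraction", "seed"))]
    bad <- names(counts)[!vapply(counts, function(v)
        is.numeric(v) && length(v) == 1 && v > 0, TRUE)]
    if (length(bad))
        stop("config values must be positive numbers: ",
             paste(bad, collapse = ", "))
    if (signal_fraction < 0 || signal_fraction > 1)
        stop("signal_fraction must lie in [0, 1]")
    if (gene_length >= gene_spacing)
        stop("gene_length must be smaller than gene_spacing")
    if (peak_width >= 2 * flank)
        stop("peak_width must be smaller than the TSS window")
    if (n_tfs * targets_per_tf > n_genes)
        stop("infeasible geometry: n_tfs * targets_per_tf exceeds n_genes")
    if (ceiling(signal_fraction * max(n_up, n_down)) >
        drivers_per_chemical * targets_per_tf)
        stop("infeasible: driver target pool smaller than the DEG signal")
    nBg <- (n_up + n_down) - 2 * floor(signal_fraction * min(n_up, n_down))
    if (n_genes - 2 * drivers_per_chemical * targets_per_tf < nBg)
        stop("infeasible: background gene pool too small for the DEG sets")
    if (tfs_per_disease > n_tfs)
        stop("infeasible: tfs_per_disease exceeds n_tfs")
    if (2 * drivers_per_chemical > n_tfs)
        stop("infeasible: need 2 * drivers_per_chemical distinct TFs")
    cfg
}

.fwriteBare <- function(df, path, sep = "\t", header = TRUE) {
    data.table::fwrite(df, path, sep = sep, col.names = header,
                       quote = FALSE, eol = "\n", scipen = 50)
}

#' Generate the synthetic benchmark fixture with planted ground truth
#'
#' Writes every file dialect the pipeline reads — refFlat annotation, BED4
#' peaks plus experiment metadata, chemical-gene CSV, protein-disease TSV,
#' chemical-protein and chemical-disease standards, and disease signature
#' JSON — into `outDir`, and returns the planted ground truth.
#'
#' Construction: genes are laid out on a regular grid (strand random); each
#' TF receives a disjoint block of target genes from one random permutation.
#' Every experiment of a TF places one peak uniformly inside each target's
#' TSS window (the signal) plus uniform background peaks over the
#' chromosome spans, rejection-free, so background may hit windows by
#' chance — that is the noise model. Each chemical draws
#' `signal_fraction * n_up` up-DEGs from its up-driver's targets and the
#' rest uniformly from non-driver-target genes (down analogous). Disease
#' signatures draw their up sets from their TFs' targets the same way, with
#' positive scores for up and negative for down genes. All randomness comes
#' from one Mersenne-Twister stream seeded with `config$seed` and consumed
#' in a fixed order (strands, target permutation, peaks per experiment,
#' chemicals, disease assignment, disease signatures), so identical
#' config + seed reproduce byte-identical files.
#'
#' @param config from [fixtureConfig()].
#' @param outDir output directory (created if missing).
#' @return invisibly, a list with the `config`, the `genes` table,
#'   `tf_targets` (named list), `drivers` (chemical_id, tf, direction),
#'   `disease_tfs` (named list), the derived positive pair sets
#'   `chem_tf_positives` and `chem_disease_positives`, and `files` (named
#'   paths of everything written).
#' @export
generateFixture <- function(config = fixtureConfig(), outDir) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    set.seed(config$seed, kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection")
    cf <- config

    # --- toy genome -------------------------------------------------------
    perChrom <- ceiling(cf$n_genes / cf$n_chroms)
    margin <- cf$flank
    chromLen <- perChrom * cf$gene_spacing + 2 * margin
    idx <- seq_len(cf$n_genes) - 1L
    chromI <- idx %/% perChrom + 1L
    slot <- idx %% perChrom
    txStart <- margin + slot * cf$gene_spacing
    txEnd <- txStart + cf$gene_length
    strand <- sample(c("+", "-"), cf$n_genes, replace = TRUE)
    genes <- data.frame(symbol = sprintf("G%05d", seq_len(cf$n_genes)),
                        txname = sprintf("T%05d", seq_len(cf$n_genes)),
                        chrom = paste0("chr", chromI), strand = strand,
                        txStart = txStart, txEnd = txEnd,
                        stringsAsFactors = FALSE)
    tss <- ifelse(strand == "+", txStart, txEnd)

    # --- TF target blocks (disjoint) -------------------------------------
    tfs <- sprintf("TF%02d", seq_len(cf$n_tfs))
    perm <- sample(cf$n_genes)
    tfTargets <- lapply(seq_len(cf$n_tfs), function(j)
        genes$symbol[perm[((j - 1) * cf$targets_per_tf + 1):
                          (j * cf$targets_per_tf)]])
    names(tfTargets) <- tfs
    targetIdx <- lapply(seq_len(cf$n_tfs), function(j)
        perm[((j - 1) * cf$targets_per_tf + 1):(j * cf$targets_per_tf)])

    # --- peaks ------------------------------------------------------------
    expIds <- sprintf("SRX%04d", seq_len(cf$n_tfs * cf$experiments_per_tf))
    expTf <- rep(tfs, each = cf$experiments_per_tf)
    w <- cf$peak_width
    peakList <- vector("list", length(expIds))
    for (e in seq_along(expIds)) {
        ti <- targetIdx[[match(expTf[e], tfs)]]
        sigStart <- tss[ti] - cf$flank +
            floor(runif(length(ti)) * (2 * cf$flank - w + 1))
        nBg <- cf$background_peaks_per_experiment
        bgChrom <- sample(cf$n_chroms, nBg, replace = TRUE)
        bgStart <- floor(runif(nBg) * (chromLen - w + 1))
        peakList[[e]] <- data.frame(
            chrom = c(genes$chrom[ti], paste0("chr", bgChrom)),
            start = c(sigStart, bgStart),
            end = c(sigStart, bgStart) + w,
            experiment_id = expIds[e], stringsAsFactors = FALSE)
    }
    peaks <- do.call(rbind, peakList)

    # --- chemicals: planted drivers and DEG draws -------------------------
    chemIds <- sprintf("D%03d", seq_len(cf$n_chemicals))
    chemNames <- sprintf("chemical_%03d", seq_len(cf$n_chemicals))
    k <- cf$drivers_per_chemical
    driverRows <- vector("list", cf$n_chemicals)
    ctdRows <- vector("list", cf$n_chemicals)
    chemUp <- chemDown <- vector("list", cf$n_chemicals)
    for (i in seq_len(cf$n_chemicals)) {
        dr <- sample(cf$n_tfs, 2 * k)
        upDr <- dr[seq_len(k)]
        downDr <- dr[k + seq_len(k)]
        upPool <- unlist(tfTargets[upDr], use.names = FALSE)
        downPool <- unlist(tfTargets[downDr], use.names = FALSE)
        nSigUp <- round(cf$signal_fraction * cf$n_up)
        nSigDown <- round(cf$signal_fraction * cf$n_down)
        bgPool <- setdiff(genes$symbol, c(upPool, downPool))
        up <- sample(upPool, nSigUp)
        bgUp <- sample(bgPool, cf$n_up - nSigUp)
        up <- c(up, bgUp)
        down <- c(sample(downPool, nSigDown),
                  sample(setdiff(bgPool, bgUp), cf$n_down - nSigDown))
        chemUp[[i]] <- up
        chemDown[[i]] <- down
        driverRows[[i]] <- data.frame(
            chemical_id = chemIds[i], tf = tfs[c(upDr, downDr)],
            direction = rep(c("up", "down"), each = k),
            stringsAsFactors = FALSE)
        ctdRows[[i]] <- data.frame(
            ChemicalName = chemNames[i], ChemicalID = chemIds[i],
            GeneSymbol = c(up, down), Organism = "Homo sapiens",
            InteractionActions = rep(c("increases^expression",
                                       "decreases^expression"),
                                     c(length(up), length(down))),
            stringsAsFactors = FALSE)
    }
    drivers <- do.call(rbind, driverRows)

    # --- diseases ---------------------------------------------------------
    disIds <- sprintf("C%04d", seq_len(cf$n_diseases))
    disNames <- sprintf("disease %d", seq_len(cf$n_diseases))
    tfPerm <- sample(cf$n_tfs)
    nSlots <- cf$n_diseases * cf$tfs_per_disease
    slotTf <- tfPerm[(seq_len(nSlots) - 1L) %% cf$n_tfs + 1L]
    diseaseTfs <- split(tfs[slotTf],
                        rep(disIds, each = cf$tfs_per_disease))
    diseaseTfs <- diseaseTfs[disIds]

    sigRecords <- vector("list", cf$n_diseases)
    for (d in seq_len(cf$n_diseases)) {
        pool <- unique(unlist(tfTargets[diseaseTfs[[d]]], use.names = FALSE))
        nSig <- min(round(cf$signal_fraction * cf$n_up), length(pool))
        upSig <- sample(pool, nSig)
        bgPool <- setdiff(genes$symbol, pool)
        upBg <- sample(bgPool, cf$n_up - nSig)
        up <- c(upSig, upBg)
        down <- sample(setdiff(bgPool, upBg), cf$n_down)
        scores <- c(round(runif(length(up), 0.5, 5), 3),
                    -round(runif(length(down), 0.5, 5), 3))
        names(scores) <- c(up, down)
        sigRecords[[d]] <- list(disease_id = disIds[d],
                                scores = as.list(scores))
    }

    # --- derived ground truth --------------------------------------------
    chemTfPos <- drivers[, c("chemical_id", "tf")]
    pdRows <- data.frame(
        protein = unlist(diseaseTfs, use.names = FALSE),
        disease_id = rep(disIds, lengths(diseaseTfs)),
        disease_name = rep(disNames, lengths(diseaseTfs)),
        stringsAsFactors = FALSE)
    cdPos <- unique(merge(chemTfPos, pdRows, by.x = "tf",
                          by.y = "protein")[, c("chemical_id", "disease_id")])
    cdPos <- cdPos[order(cdPos$chemical_id, cdPos$disease_id), , drop = FALSE]
    rownames(cdPos) <- NULL

    # --- write files ------------------------------------------------------
    files <- c(refflat = file.path(outDir, "refflat.txt"),
               peaks = file.path(outDir, "peaks.bed"),
               experiments = file.path(outDir, "experiments.tsv"),
               chem_gene = file.path(outDir, "chem_gene_ixns.csv"),
               protein_disease = file.path(outDir, "protein_disease.tsv"),
               chemical_protein = file.path(outDir,
                                            "chemical_protein_standard.tsv"),
               chemical_disease = file.path(outDir,
                                            "chemical_disease_standard.tsv"),
               signatures = file.path(outDir, "disease_signatures.json"))
    refflat <- data.frame(genes$symbol, genes$txname, genes$chrom,
                          genes$strand, genes$txStart, genes$txEnd,
                          genes$txStart, genes$txEnd, 1L,
                          paste0(genes$txStart, ","),
                          paste0(genes$txEnd, ","))
    .fwriteBare(refflat, files["refflat"], header = FALSE)
    .fwriteBare(peaks, files["peaks"], header = FALSE)
    .fwriteBare(data.frame(experiment_id = expIds, antigen = expTf),
                files["experiments"])
    .fwriteBare(do.call(rbind, ctdRows), files["chem_gene"], sep = ",")
    .fwriteBare(pdRows, files["protein_disease"])
    .fwriteBare(stats::setNames(chemTfPos, c("chemical_id", "protein")),
                files["chemical_protein"])
    .fwriteBare(cdPos, files["chemical_disease"])
    writeLines(jsonlite::toJSON(sigRecords, auto_unbox = TRUE, digits = 8),
               files["signatures"])

    invisible(list(config = cf, genes = genes, tf_targets = tfTargets,
                   drivers = drivers, disease_tfs = diseaseTfs,
                   chem_tf_positives = chemTfPos,
                   chem_disease_positives = cdPos, files = files))
}

#' Write the tiny fully enumerable worked-example fixture
#'
#' Six genes on one chromosome, two TFs (AR with peaks at the G1/G2 TSSs,
#' NANOG with peaks at G1/G3), one chemical (up = G1, G2; down = G3, G4)
#' and one disease associated with AR. Every table is hand-checkable: the
#' AR experiment gives the 2x2 table (2, 0, 0, 2), whose two-tailed exact
#' p-value is 1/3 (enrichment score -log10(1/3) = 0.4771), and disease
#' linkage yields exactly one chemical-disease prediction mediated by AR.
#' No randomness is involved. Note the example profile has two genes per
#' side, so pipelines over this fixture must relax the DEG admission filter
#' (`minEach = 1`).
#'
#' @param outDir output directory (created if missing).
#' @return invisibly, the named file paths.
#' @export
workedExample <- function(outDir) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    tssPos <- (1:6) * 100000
    genes <- data.frame(symbol = paste0("G", 1:6),
                        txname = paste0("T", 1:6), chrom = "chr1",
                        strand = "+", txStart = tssPos,
                        txEnd = tssPos + 2000)
    files <- c(refflat = file.path(outDir, "refflat.txt"),
               peaks = file.path(outDir, "peaks.bed"),
               experiments = file.path(outDir, "experiments.tsv"),
               chem_gene = file.path(outDir, "chem_gene_ixns.csv"),
               protein_disease = file.path(outDir, "protein_disease.tsv"),
               chemical_protein = file.path(outDir,
                                            "chemical_protein_standard.tsv"),
               chemical_disease = file.path(outDir,
                                            "chemical_disease_standard.tsv"),
               signatures = file.path(outDir, "disease_signatures.json"))
    refflat <- data.frame(genes$symbol, genes$txname, genes$chrom,
                          genes$strand, genes$txStart, genes$txEnd,
                          genes$txStart, genes$txEnd, 1L,
                          paste0(genes$txStart, ","),
                          paste0(genes$txEnd, ","))
    .fwriteBare(refflat, files["refflat"], header = FALSE)
    peakAt <- function(g, e) data.frame(chrom = "chr1",
                                        start = tssPos[g] - 100,
                                        end = tssPos[g] + 100,
                                        experiment_id = e)
    .fwriteBare(rbind(peakAt(1, "SRX0001"), peakAt(2, "SRX0001"),
                      peakAt(1, "SRX0002"), peakAt(3, "SRX0002")),
                files["peaks"], header = FALSE)
    .fwriteBare(data.frame(experiment_id = c("SRX0001", "SRX0002"),
                           antigen = c("AR", "NANOG")),
                files["experiments"])
    .fwriteBare(data.frame(ChemicalName = "examplechem",
                           ChemicalID = "D001",
                           GeneSymbol = c("G1", "G2", "G3", "G4"),
                           Organism = "Homo sapiens",
                           InteractionActions = rep(c("increases^expression",
                                                      "decreases^expression"),
                                                    each = 2)),
                files["chem_gene"], sep = ",")
    .fwriteBare(data.frame(protein = "AR", disease_id = "C0001",
                           disease_name = "example disease"),
                files["protein_disease"])
    .fwriteBare(data.frame(chemical_id = "D001", protein = "AR"),
                files["chemical_protein"])
    .fwriteBare(data.frame(chemical_id = "D001", disease_id = "C0001"),
                files["chemical_disease"])
    writeLines(jsonlite::toJSON(list(list(disease_id = "C0001",
                                          scores = list(G1 = 2.1, G3 = -0.3,
                                                        G5 = 0))),
                                auto_unbox = TRUE, digits = 8),
               files["signatures"])
    invisible(files)
}
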