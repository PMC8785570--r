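#' @include synthetic-fixtures.R
NULL

#' Pipeline configuration
#'
#' Bundles the file locations and the analysis knobs of the end-to-end run.
#' The tunable method parameters are deliberately few: the TSS flank, the
#' DEG admission threshold, the global evaluation mode and the score cap.
#'
#' @param fixtureDir directory holding the input files (the layout written
#'   by [generateFixture()] / [workedExample()]).
#' @param outDir directory for result tables and the run manifest.
#' @param flank TSS window half-width in bp (default 5000, i.e. +/- 5 kb).
#' @param minEach DEG admission threshold: minimum number of up- and of
#'   down-regulated genes per profile (default 11, "more than ten each").
#' @param globalMode global AUROC/AUPR construction, `"column_max"` or
#'   `"pooled"` (see [globalEval()]).
#' @param scoreCap cap on enrichment scores (see [enrichmentScore()]).
#' @param minScore optional inclusive peak-score threshold (see
#'   [readPeaks()]).
#' @param organism organism filter for the chemical-gene table.
#' @param seed seed used by [cmdSimulate()] when generating a fixture.
#' @return validated configuration list of class `ChipeaConfig`.
#' @export
pipelineConfig <- function(fixtureDir, outDir, flank = 5000, minEach = 11,
                           globalMode = c("column_max", "pooled"),
                           scoreCap = 320, minScore = NULL,
                           organism = "Homo sapiens", seed = 17) {
    if (!is.numeric(flank) || length(flank) != 1 || flank <= 0)
        stop("invalid config value for 'flank': must be > 0")
    if (!is.numeric(minEach) || length(minEach) != 1 || minEach < 1)
        stop("invalid config value for 'minEach': must be >= 1")
    if (!is.numeric(scoreCap) || scoreCap <= 0)
        stop("invalid config value for 'scoreCap': must be > 0")
    globalMode <- match.arg(globalMode)
    structure(list(fixtureDir = fixtureDir, outDir = outDir, flank = flank,
                   minEach = minEach, globalMode = globalMode,
                   scoreCap = scoreCap, minScore = minScore,
                   organism = organism, seed = seed),
              class = "ChipeaConfig")
}

.fixtureFiles <- function(dir) {
    c(refflat = file.path(dir, "refflat.txt"),
      peaks = file.path(dir, "peaks.bed"),
      experiments = file.path(dir, "experiments.tsv"),
      chem_gene = file.path(dir, "chem_gene_ixns.csv"),
      protein_disease = file.path(dir, "protein_disease.tsv"),
      chemical_protein = file.path(dir, "chemical_protein_standard.tsv"),
      chemical_disease = file.path(dir, "chemical_disease_standard.tsv"),
      signatures = file.path(dir, "disease_signatures.json"))
}

.checkInputs <- function(files, need) {
    for (f in files[need]) if (!file.exists(f)) stop("missing input file: ", f)
}

#' Generate the default synthetic fixture for a pipeline run
#'
#' @param config a [pipelineConfig()]; `config$seed` seeds the generator.
#' @param fixture optional [fixtureConfig()] overriding the defaults
#'   (its seed is replaced by `config$seed`).
#' @return the ground-truth list from [generateFixture()], invisibly.
#' @export
cmdSimulate <- function(config, fixture = NULL) {
    if (is.null(fixture)) fixture <- fixtureConfig(seed = config$seed)
    else fixture$seed <- config$seed
    generateFixture(fixture, config$fixtureDir)
}

#' Run the enrichment stage: per-experiment records and chemical-TF scores
#'
#' Reads annotation, peaks and chemical DEG profiles from the fixture
#' directory, runs [runChipea()] over TSS windows of `config$flank`, writes
#' `enrichment.tsv` and `chem_tf_scores.tsv` into `config$outDir`, and
#' returns the tables.
#'
#' @param config a [pipelineConfig()].
#' @return list with `records`, `tfScores`, `profiles`, `meta`, `genes`.
#' @export
cmdChipea <- function(config) {
    files <- .fixtureFiles(config$fixtureDir)
    .checkInputs(files, c("refflat", "peaks", "experiments", "chem_gene"))
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    genes <- readRefFlat(files["refflat"])
    pk <- readPeaks(files["peaks"], files["experiments"],
                    minScore = config$minScore)
    profiles <- readChemicalDegs(files["chem_gene"],
                                 organismFilter = config$organism,
                                 minEach = config$minEach)
    if (!length(profiles)) stop("no chemical profile passes the DEG filter")
    windows <- tssWindows(genes, flank = config$flank)
    records <- runChipea(profiles, pk$peaks, pk$meta, windows,
                         scoreCap = config$scoreCap)
    tfScores <- aggregateByTF(records)
    writeEnrichmentTable(records, file.path(config$outDir, "enrichment.tsv"))
    .writeTsv(tfScores, file.path(config$outDir, "chem_tf_scores.tsv"))
    list(records = records, tfScores = tfScores, profiles = profiles,
         meta = pk$meta, genes = genes)
}

#' Run the disease-linkage stage
#'
#' @param config a [pipelineConfig()].
#' @param tfScores chemical-TF scores (from [cmdChipea()]); read from
#'   `chem_tf_scores.tsv` in `config$outDir` when omitted.
#' @return the prediction data frame (also written to `predictions.tsv`).
#' @export
cmdLink <- function(config, tfScores = NULL) {
    files <- .fixtureFiles(config$fixtureDir)
    .checkInputs(files, "protein_disease")
    if (is.null(tfScores)) {
        path <- file.path(config$outDir, "chem_tf_scores.tsv")
        if (!file.exists(path)) stop("missing input file: ", path)
        tfScores <- utils::read.delim(path, colClasses = c(score = "numeric"))
    }
    assoc <- readProteinDisease(files["protein_disease"])
    predictions <- linkDiseases(tfScores, assoc)
    writePredictionTable(predictions,
                         file.path(config$outDir, "predictions.tsv"))
    predictions
}

#' Run the DEG-connected baseline stage
#'
#' Scores every (chemical, disease) pair by Fisher tests on the DEG
#' cross-tabulations in both modes and writes one TSV per mode.
#'
#' @param config a [pipelineConfig()].
#' @return list of [AssociationMatrix-class] objects, one per mode.
#' @export
cmdBaseline <- function(config) {
    files <- .fixtureFiles(config$fixtureDir)
    .checkInputs(files, c("refflat", "chem_gene", "signatures"))
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    genes <- readRefFlat(files["refflat"])
    profiles <- readChemicalDegs(files["chem_gene"],
                                 organismFilter = config$organism,
                                 minEach = config$minEach)
    sigs <- readDiseaseSignatures(files["signatures"])
    universe <- unique(genes$symbol)
    out <- list()
    for (mode in c("deg_vs_nondeg", "up_vs_down")) {
        mat <- baselineScores(profiles, sigs, universe, mode = mode,
                              scoreCap = config$scoreCap)
        s <- scoreMatrix(mat)
        long <- data.frame(chemical_id = rep(rownames(s), ncol(s)),
                           disease_id = rep(colnames(s), each = nrow(s)),
                           score = as.vector(s), mode = mode)
        o <- order(-long$score, long$chemical_id, long$disease_id,
                   method = "radix")
        .writeTsv(long[o, ], file.path(config$outDir,
                                       paste0("baseline_", mode, ".tsv")))
        out[[mode]] <- mat
    }
    out
}

#' Run the evaluation stage
#'
#' Builds labelled association matrices from the standards in the fixture
#' directory and summarizes per-chemical and global AUROC/AUPR for the
#' chemical-TF scores, the TF-mediated chemical-disease predictions and
#' the DEG-connected baselines, plus rank-sum comparisons of the
#' per-chemical AUROC/AUPR distributions between the TF-mediated method
#' and each baseline. Writes `evaluation.tsv` (summary rows) and
#' `evaluation_per_chemical.tsv`.
#'
#' @param config a [pipelineConfig()].
#' @param stages optional precomputed list with `tfScores`, `predictions`,
#'   `baseline` (as produced by the respective stages); recomputed from the
#'   fixture when omitted.
#' @return list with labelled matrices, per-method summaries and the
#'   method-comparison p-values.
#' @export
cmdEvaluate <- function(config, stages = NULL) {
    files <- .fixtureFiles(config$fixtureDir)
    .checkInputs(files, c("chemical_protein", "chemical_disease"))
    if (is.null(stages)) {
        ch <- cmdChipea(config)
        stages <- list(tfScores = ch$tfScores,
                       predictions = cmdLink(config, ch$tfScores),
                       baseline = cmdBaseline(config))
    }
    chemProt <- readChemicalProtein(files["chemical_protein"])
    chemDis <- readChemicalDisease(files["chemical_disease"])

    tfMat <- addTruthLabels(
        predictionMatrix(stages$tfScores, entityCol = "tf"), chemProt)
    predMat <- addTruthLabels(
        predictionMatrix(stages$predictions,
                         chemicals = unique(stages$tfScores$chemical_id),
                         entities = unique(chemDis$disease_id)),
        chemDis)
    baseMats <- lapply(stages$baseline, addTruthLabels, positives = chemDis)

    # per-chemical and global evaluation can each be legitimately undefined
    # at small scale (single-class rows everywhere; column_max over a
    # standard where every entity has a true pair): degrade to NA rather
    # than abort the run
    emptyPc <- list(per_chemical = data.frame(chemical_id = character(0),
                                              auroc = numeric(0),
                                              aupr = numeric(0),
                                              n_pos = integer(0),
                                              n_neg = integer(0)),
                    mean_auroc = NA_real_, median_auroc = NA_real_,
                    mean_aupr = NA_real_, median_aupr = NA_real_,
                    n_excluded = NA_integer_)
    evalOne <- function(mat) {
        pc <- tryCatch(perChemicalEval(mat), error = function(e) {
            out <- emptyPc
            out$n_excluded <- nrow(scoreMatrix(mat))
            out
        })
        gl <- tryCatch(globalEval(mat, mode = config$globalMode),
                       error = function(e) list(auroc = NA_real_,
                                                aupr = NA_real_, n = NA))
        list(per_chemical = pc, global = gl)
    }
    methods <- c(list(chem_tf = tfMat, chipea_disease = predMat),
                 stats::setNames(baseMats,
                                 paste0("baseline_", names(baseMats))))
    summaries <- lapply(methods, evalOne)

    comparisons <- lapply(names(baseMats), function(mode) {
        a <- summaries$chipea_disease$per_chemical$per_chemical
        b <- summaries[[paste0("baseline_", mode)]]$per_chemical$per_chemical
        if (!nrow(a) || !nrow(b))
            return(list(mode = mode, p_auroc = NA_real_, p_aupr = NA_real_))
        list(mode = mode,
             p_auroc = compareMethods(a$auroc, b$auroc),
             p_aupr = compareMethods(a$aupr, b$aupr))
    })

    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    summary <- do.call(rbind, lapply(names(summaries), function(m) {
        s <- summaries[[m]]
        data.frame(method = m,
                   n_chemicals = nrow(s$per_chemical$per_chemical),
                   n_excluded = s$per_chemical$n_excluded,
                   mean_auroc = s$per_chemical$mean_auroc,
                   median_auroc = s$per_chemical$median_auroc,
                   mean_aupr = s$per_chemical$mean_aupr,
                   median_aupr = s$per_chemical$median_aupr,
                   global_mode = config$globalMode,
                   global_auroc = s$global$auroc,
                   global_aupr = s$global$aupr)
    }))
    .writeTsv(summary, file.path(config$outDir, "evaluation.tsv"))
    perChem <- do.call(rbind, lapply(names(summaries), function(m) {
        pc <- summaries[[m]]$per_chemical$per_chemical
        if (!nrow(pc)) return(NULL)
        cbind(method = m, pc)
    }))
    if (is.null(perChem))
        perChem <- cbind(method = character(0), emptyPc$per_chemical)
    .writeTsv(perChem, file.path(config$outDir,
                                 "evaluation_per_chemical.tsv"))
    list(matrices = methods, summaries = summaries, summary_table = summary,
         comparisons = comparisons)
}

#' Run the whole pipeline end to end
#'
#' Executes enrichment, disease linkage, both baselines and the evaluation
#' over an existing fixture directory (generate one first with
#' [cmdSimulate()] or [workedExample()]), then writes a run manifest
#' listing inputs, configuration, package version and every output file.
#' Given identical inputs and configuration the result files are
#' byte-identical across runs (the manifest timestamp aside).
#'
#' @param config a [pipelineConfig()].
#' @return the [cmdEvaluate()] result list, with `records` and
#'   `predictions` attached.
#' @export
runPipeline <- function(config) {
    ch <- cmdChipea(config)
    predictions <- cmdLink(config, ch$tfScores)
    baseline <- cmdBaseline(config)
    ev <- cmdEvaluate(config, stages = list(tfScores = ch$tfScores,
                                            predictions = predictions,
                                            baseline = baseline))
    outputs <- c("enrichment.tsv", "chem_tf_scores.tsv", "predictions.tsv",
                 "baseline_deg_vs_nondeg.tsv", "baseline_up_vs_down.tsv",
                 "evaluation.tsv", "evaluation_per_chemical.tsv")
    manifest <- list(
        package = "chipea",
        version = as.character(utils::packageVersion("chipea")),
        timestamp = format(Sys.time(), tz = "UTC"),
        config = unclass(config)[!vapply(unclass(config), is.null, TRUE)],
        inputs = as.list(.fixtureFiles(config$fixtureDir)),
        outputs = as.list(file.path(config$outDir, outputs)))
    jsonlite::write_json(manifest, file.path(config$outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    ev$records <- ch$records
    ev$predictions <- predictions
    ev
}
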