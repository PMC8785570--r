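# chipea

Infer which transcription factors (TFs) organize a chemical's
transcriptional response, and through them which diseases the chemical may
be relevant to, from three ingredients: curated chemically induced gene
expression changes, a compendium of ChIP-seq peak calls, and protein–disease
associations. The package is aimed at computational pharmacologists and
regulatory genomicists who want a TF-centric alternative to comparing
differentially expressed gene (DEG) lists directly.

## The statistic at the core

For a chemical *C* with disjoint up- and down-regulated gene sets and a
ChIP-seq experiment for TF *T*, count how many genes of each set have at
least one peak within ±5 kb of a transcription start site (TSS):

|            | overlapped | not overlapped |
|------------|-----------:|---------------:|
| up-genes   | *a*        | *b*            |
| down-genes | *c*        | *d*            |

Under the null hypothesis that peaks overlap both sets in the same
proportion, the table is tested with the two-tailed Fisher's exact test
(all tables with the observed margins whose hypergeometric probability does
not exceed that of the observed table are summed). The **enrichment score**
is −log₁₀(*p*), the **fold enrichment** is (*a*/(*a*+*b*)) / (*c*/(*c*+*d*)),
and a TF covered by several experiments keeps its best-scoring one. TF
scores propagate to diseases through protein–disease associations — a
chemical–disease pair inherits the highest score among the disease's
associated TFs. Predictions are benchmarked per chemical and globally
(AUROC and average-precision AUPR) against chemical–protein and
chemical–disease interaction standards, next to a TF-free baseline that
cross-tabulates the chemical's and a disease signature's DEG labels and
applies the same exact test.

Everything runs on a deterministic synthetic benchmark with planted driver
TFs, so no external database download is needed.

## Worked example

A six-gene fixture small enough to check by hand: the chemical up-regulates
G1, G2 and down-regulates G3, G4; the AR experiment has peaks at the G1 and
G2 TSSs only, NANOG at G1 and G3; the one disease is associated with AR.

```r
library(chipea)
dir <- file.path(tempdir(), "chipea-example")
files <- workedExample(dir)
genes   <- readRefFlat(files[["refflat"]])
peaks   <- readPeaks(files[["peaks"]], files[["experiments"]])
profile <- readChemicalDegs(files[["chem_gene"]], minEach = 1)
windows <- tssWindows(genes, flank = 5000)
records <- runChipea(profile, peaks$peaks, peaks$meta, windows)
records[, c("tf", "a", "b", "c", "d", "p", "score", "fold", "direction")]
#>      tf a b c d         p     score fold direction
#> 1    AR 2 0 0 2 0.3333333 0.4771213  Inf up-biased
#> 2 NANOG 1 1 1 1 1.0000000 0.0000000    1   neutral

predictions <- linkDiseases(aggregateByTF(records),
                            readProteinDisease(files[["protein_disease"]]))
predictions
#>   chemical_id disease_id    disease_name     score mediating_tf direction
#> 1        D001      C0001 example disease 0.4771213           AR up-biased
```

The AR table (2, 0, 0, 2) has margins 2/2; of the three attainable tables
the two extreme ones each have probability 1/6, so the two-sided p-value is
1/3 and the score is −log₁₀(1/3) ≈ 0.477. NANOG's balanced table scores 0.
The disease inherits AR's score — exactly one prediction.

For the full synthetic benchmark use `generateFixture()` +
`runPipeline(pipelineConfig(...))`, or the command-line front end:

```sh
Rscript inst/scripts/chipea-cli.R simulate --fixture-dir fx
Rscript inst/scripts/chipea-cli.R run-all  --fixture-dir fx --out-dir out
```

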