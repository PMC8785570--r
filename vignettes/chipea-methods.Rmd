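---
title: "TF-binding enrichment for drug mode-of-action inference: methods and design"
author: "chipea package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TF-binding enrichment: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipea)
```

## The model

A bioactive chemical reshapes transcription largely through a handful of
master-regulator transcription factors (TFs). If a TF mediates the
response, its experimentally mapped binding sites should sit near the genes
the chemical up-regulates in a different proportion than near the genes it
down-regulates. The package operationalizes that intuition in four stages:

1. **Windows.** Each transcript contributes a promoter-proximal window:
   the transcription start site (TSS) ± `flank` bp. On the + strand the
   TSS is `txStart`; on the − strand it is `txEnd`.
2. **Overlap.** For one ChIP-seq experiment, a gene symbol is "overlapped"
   iff any of its windows shares at least one base with at least one peak
   (half-open interval semantics, as in `bedtools intersect`). Overlap is
   binary per gene: the 2×2 test below needs counts bounded by the gene-set
   sizes, so peak multiplicity is deliberately ignored.
3. **Test.** For a chemical with disjoint up/down DEG sets, the table
   (a, b, c, d) = (up overlapped, up not, down overlapped, down not) is
   tested with the two-tailed Fisher's exact test; the enrichment score is
   −log₁₀(p) and the fold enrichment (a/(a+b)) / (c/(c+d)). Per (chemical,
   TF) the best-scoring experiment is kept.
4. **Linkage.** A chemical–disease pair is predicted iff one of the
   chemical's scored TFs is a disease-associated protein; it inherits the
   highest such score. No new score is ever invented, so every prediction
   is traceable to one (chemical, experiment) table via its mediating TF.

The unsigned score is used downstream: a TF whose binding is biased toward
*down*-regulated genes (a repressed or inhibited factor) is as informative
about mechanism as an activated one, so direction ("up-biased",
"down-biased", "neutral" — decided by comparing a/(a+b) with c/(c+d) in
exact integer arithmetic) is reported but never filtered on.

## Parameters that matter

| parameter | default | meaning and rationale |
|---|---|---|
| `flank` | 5000 bp | promoter-proximal half-width; ±5 kb captures most proximal regulatory binding while keeping windows gene-specific |
| `minEach` | 11 | DEG admission: at least 11 genes on each side ("more than ten each"); smaller sets make the exact test uninformative |
| `scoreCap` | 320 | −log₁₀ p is capped where double precision underflows; far above any attainable desk-scale score |
| `globalMode` | `column_max` | global evaluation vector construction (see below) |
| `minScore` | none | optional inclusive peak-score threshold; shipped peak sets are assumed pre-thresholded upstream by the peak caller |

## Numerical and convention choices

* **Two-sided definition.** The p-value sums the probabilities of all
  tables with the observed margins whose hypergeometric probability is at
  most that of the observed table, with a 1e−7 relative tolerance against
  floating-point ties — the convention of mainstream exact-test
  implementations. Accumulation happens in log space, so margins in the
  thousands remain stable; if every table qualifies the p-value is exactly 1.
* **Degenerate tables.** An empty margin (no annotated up- or down-genes)
  leaves the test undefined: the record is skipped and counted, not scored
  0. Fold enrichment conventions: a = c = 0 → 1 (no evidence); c = 0 <
  a → +∞ (serialized `Inf`). Swapping the up and down sets provably leaves
  p unchanged and maps fold → 1/fold with 0 ↔ ∞.
* **Unannotated DEGs** (symbols absent from the annotation) have no window
  to test and are excluded from the table rather than counted as
  non-overlapping.
* **Genes curated in both directions** for one chemical are removed from
  both sets: the test requires disjoint categories.
* **Tie-breaks** are lexicographic everywhere (best experiment id per TF,
  mediating TF symbol per disease, output row ordering), so every result
  table is deterministic and input-order independent.
* **Coordinates.** BED inputs are 0-based half-open and converted to
  1-based closed `GRanges` at the I/O boundary; window arithmetic is done
  in BED coordinates and clipped at the chromosome origin only (refFlat
  carries no chromosome lengths; right clipping is irrelevant for overlap
  testing). Gene symbols are upper-cased on input everywhere, since three
  external vocabularies must be joined by symbol.

## Evaluation

Per chemical, AUROC is the Mann–Whitney probability (ties count 1/2) and
AUPR is step-wise average precision with tied scores processed as one block
— which makes a constant score vector score exactly the positive
prevalence, the PR random baseline. Rows whose labels are single-class
cannot be ranked against themselves and are excluded with a count.

Two "global" constructions emphasize absolute score values across
chemicals: `column_max` keeps one element per entity (the column's maximal
score, labelled 1 iff any cell attaining the maximum is a true pair) and
`pooled` flattens all m×n cells. Both are provided because the two
descriptions in circulation — a per-column maximum vector and a merged
inter-chemical score vector — differ, and neither is privileged here. At
desk scale `column_max` is often degenerate: with a planted standard every
entity column's maximum is a true pair, the label vector is single-class,
and `globalEval()` raises an undefined-result error (the pipeline summary
degrades to NA). The acceptance script therefore reports pooled globals.

Method comparisons use the two-sided Wilcoxon rank-sum test: exact
enumeration over group assignments of pooled midranks (dynamic programming,
ties handled exactly) when both samples have ≤ 12 values, otherwise the
normal approximation with tie and continuity corrections. The same routine
backs `rankOverlapTest()`, which asks whether members of a gene subset sit
systematically higher in a ranked list than non-members.

## The DEG-connected baseline

The TF-free comparator classifies every gene of the annotation universe as
up, down or non-DEG for a chemical profile and for a disease signature, and
tests one of two 2×2 cross-tabulations: **DEGs vs non-DEGs** over the whole
universe, or **up vs down** restricted to genes that are DEGs in both
profiles (that table has no non-DEG category by construction; a pair with
no jointly-DEG gene is unscorable and gets score 0). The null — the two
profiles' labels are distributed independently given the margins — uses the
same two-tailed exact test, so baseline and TF-mediated scores live on one
scale.

## What the synthetic benchmark emulates — and what it does not

`generateFixture()` writes every input dialect the pipeline reads, with
planted ground truth. The default study conditions: 12,000 genes on 3
chromosomes at 10 kb spacing; 12 TFs × 2 experiments with 850 disjoint
target genes each; per experiment, one peak placed uniformly inside every
target's TSS window plus 8,000 uniform background peaks (a promoter hit
rate near 0.5, mirroring the dense promoter coverage of real ChIP-seq
compendia — background may hit windows by chance, which is the noise
model); 24 chemicals with 850 up- / 750 down-regulated DEGs, a fraction
`signal_fraction` (default 0.8) drawn from one up-driver's and one
down-driver's targets and the rest from non-driver genes; 10 diseases × 2
TFs, assigned so every TF backs at least one disease, which makes every
planted chemical–TF positive realizable as a chemical–disease positive.

The DEG-set sizes are deliberately **large and unequal**. The exact test's
p-value support is discrete; its intrinsic conservatism scales with the
modal hypergeometric probability, and exactly equal margins create paired
modal tables that double the point mass at p = 1. With ~800 genes per side
and unequal counts — both well within the range of real curated profiles,
where strong perturbagens reach four figures and up/down counts never
coincide — the null p-value distribution is fine-grained enough for
KS-style calibration diagnostics to be meaningful. Disease signatures are
drawn from their TFs' target pools the same way, with signed per-gene
scores (positive = up); a score of exactly 0 belongs to neither set.

All randomness flows from a single seeded Mersenne-Twister stream consumed
in a documented fixed order, so identical configuration and seed reproduce
byte-identical files; tests verify this by checksum.

What passing the synthetic benchmark does **not** show: real ChIP-seq peaks
cluster by chromatin context rather than falling uniformly; real TF target
sets overlap heavily (the fixture's are disjoint); real DEG profiles carry
cell-type and dose structure; and gene symbols in real databases disagree
across vocabularies far more than the generator's clean symbol space. The
benchmark validates the machinery — counting, testing, aggregation,
linkage, evaluation — not biological discovery performance.

## Problem sizes in the shipped tests

The suite checks the exact test against full hypergeometric enumeration on
every table with margins ≤ 12 plus 500 random tables with totals ≤ 60;
window overlap against a brute-force all-pairs scan on 50 random instances
up to 500 genes × 5,000 peaks; AUROC/AUPR against pairwise and PR-sweep
oracles on 200 random labelled vectors (ties included); and the full
pipeline on the default fixture (planted recovery, signal-free calibration
over 576 records, method ordering, byte-level determinism). These sizes
keep each property statistically meaningful while the whole suite stays in
the minutes range on one core.

## Known limitations

* Only promoter-proximal binding is considered; distal enhancers, long-range
  contacts and chromatin accessibility are out of scope.
* Binding is binarized; peak strength and TSS distance are not weighted.
* "Binding near" is not "regulates": the score measures association of
  binding with induced expression change, not causality.
* TFs without ChIP-seq coverage are invisible to the method.
* Multiple-testing correction is intentionally absent: scores are used for
  ranking, never as calibrated significance statements.

## A fully enumerable example

```{r worked-example}
dir <- file.path(tempdir(), "chipea-vignette")
files <- workedExample(dir)
records <- runChipea(readChemicalDegs(files[["chem_gene"]], minEach = 1),
                     readPeaks(files[["peaks"]], files[["experiments"]])$peaks,
                     readPeaks(files[["peaks"]], files[["experiments"]])$meta,
                     tssWindows(readRefFlat(files[["refflat"]]), 5000))
records[, c("tf", "a", "b", "c", "d", "p", "score")]
linkDiseases(aggregateByTF(records),
             readProteinDisease(files[["protein_disease"]]))
```

The AR table (2, 0, 0, 2) admits three tables at its margins with
probabilities 1/6, 4/6, 1/6; the two-sided p-value is 1/3 and the score
−log₁₀(1/3) ≈ 0.4771. The single prediction inherits that score through
the AR–disease association.
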