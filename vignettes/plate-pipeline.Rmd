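---
title: "Methods: plate-based barcoded-bead scRNA-seq processing in scplate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plate-based barcoded-bead scRNA-seq processing in scplate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

scplate processes sequencing data from microwell-plate single-cell RNA-seq
libraries built on barcoded capture beads, and ships a simulator that
generates such data with complete ground truth. This vignette documents
the model behind each stage, the tunable parameters, the numerical and
design choices that were genuinely open, and the limits of what the
synthetic data can demonstrate.

## The read model

Each well's bead carries one oligo species:
`primer – barcode(6 bp) – UMI(7 bp) – (T)n`. Sequencing reads the oligo
end as Read 1 (20 bp): bases 1–6 are the cell barcode, bases 7–13 the
UMI, and bases 14–20 fall into the poly-T tail. The simulator writes
literal `T`s there and the parser ignores them, so the pad carries no
information either way. Read 2 (50 bp) is a fragment of the captured
transcript; because priming happens at the poly-A tail, the simulator
draws the window near the 3' end, jittering its start uniformly over the
last `window_3prime` (default 150) bases. PCR duplication emits each
molecule `k` times with `k - 1 ~ Poisson(duplication_mean - 1)`, so every
molecule is seen at least once; substitution errors hit every base
independently at `error_rate`. Fragment-length variation, adapter
read-through, indels and realistic quality strings are deliberately not
modelled — none of them interacts with the logic under test.

## Barcode whitelists and the limits of 6-mer codes

Hamming-distance-1 barcode correction is unambiguous exactly when the
whitelist has minimum pairwise distance ≥ 3. But 6-mer codes at distance
3 are small: sphere packing bounds them at 4096/19 ≈ 215 barcodes, the
best known explicit constructions reach only ~164, and the randomized
greedy search used here finds ~90. A 224-well plate therefore cannot have
a distance-3 whitelist; this is a mathematical constraint, not an
implementation limit.

`design_plate()` consequently defaults to `min_distance = 2`, which keeps
a weaker but sufficient guarantee: if an observed barcode is one
substitution away from its true well, the true well is always among the
distance-1 candidates, so the read is either rescued to the correct well
or rejected as ambiguous — never reassigned to a different well.
Mis-assignment would require the observed barcode to *exactly equal*
another whitelist entry, which a single substitution cannot achieve when
all pairs are at distance ≥ 2. The cost of distance 2 relative to
distance 3 is rescue rate, not accuracy. Plates of up to ~90 wells can
request `min_distance = 3`, and the test suite verifies exact rescue by
exhaustive single-substitution enumeration on such a whitelist.
`N` bases count as mismatches everywhere. No quality filtering is
applied (a hook exists, default off).

## Transcript assignment

A genome aligner is out of scope; Read 2 is assigned through a k-mer
seed-and-verify matcher over the two-species transcript reference
(`k = 21` by default, seeds at the start, middle and end of the read,
both orientations). A candidate gene is confirmed when the full read
matches the transcript at the seeded offset with at most
`max_mismatches = 2` substitutions; one confirmed gene → assigned, two or
more → ambiguous, none → unassigned. Ambiguous reads are discarded from
counting, the common practice for multi-gene reads in digital expression
pipelines. The interface is pluggable: any table of
(barcode, UMI, gene) records can be fed to `build_dge()`, so externally
aligned data can replace the built-in matcher.

## UMI collapse semantics

Reads within a (cell, gene) pair are collapsed at Hamming distance 1.
Distance-1 collapse admits two standard interpretations: connected
components of the distance graph ("cluster"), or the count-weighted
directional variant that only merges a low-count UMI into a neighbour
with substantially higher count. Since no count threshold is specified
for this protocol, scplate implements the cluster method: the molecule
count of a UMI multiset is the number of connected components among its
distinct sequences, with edges joining pairs at distance ≤ 1. This is the
package's main interpretive choice; it is slightly conservative (chains
of UMIs merge transitively), and it is what the ground-truth tables use
too (see below). Collapse is done per gene, not per isoform — the output
matrix is gene-level.

## Ground truth under UMI collisions

The simulator draws UMIs uniformly over 7-mers, so two true molecules of
the same (cell, gene) occasionally receive identical or distance-1 UMIs.
Such collisions are physically unresolvable downstream — any
distance-1-collapsing pipeline must merge them. The ground-truth count
table (`truth_counts()`) therefore applies the same equivalence relation
to the simulated molecules, implemented independently in plain R
(breadth-first search over a position-wise distance matrix) from the
pipeline's C++ union-find. The end-to-end identity check — simulated
reads at zero error rate reproduce the truth table entry for entry — thus
exercises two independent implementations of the collapse rule plus the
entire read path, and the collapse rule itself is separately validated
against a brute-force oracle on random multisets.

## Expression simulation

Per-cell molecule totals follow a Gamma–Poisson (negative binomial) law
with mean `mean_molecules_per_cell` and dispersion `dispersion`
(variance = m + φm²; default φ = 0.1, total counts CV ≈ 33%, a
realistic well-to-well capture spread). Gene identities are multinomial
given the total, with log-normal relative abundances (σ = 1) fixed per
reference; mitochondrial genes are rescaled to carry `mito_share`
(default 2%) of each species' mass, comfortably below the 5% QC ceiling.
Condition effects multiply gene weights by `2^log2fc`. Ambient RNA adds
`Poisson(ambient_fraction × mean_molecules_per_cell)` molecules to every
well — negative controls included — drawn from the pooled two-species
profile, emulating free mRNA captured during pooled reverse
transcription. Doublet wells draw two cells (one per species; the second
scaled by `doublet_ratio`, default 1) under a single barcode.

Two consequences worth noting. First, the ambient estimator
(mean negative-well count over mean identified-cell count) has
expectation `a/(1+a)` rather than `a`, because cell wells also capture
ambient molecules — at the default 5% this bias is ~4.8% relative, well
inside the estimator's sampling noise. Second, because the DGE is
compositional under CPM, boosting a set of genes in one condition pushes
every other gene's relative abundance slightly down; with 40 of 200
genes doubled, unperturbed genes shift by about −log2(1.2) ≈ −0.26 on
the log2 scale. This is faithful to real closed-composition data, and it
is why differential-expression results near the |log2 FC| = 0.25
boundary should be read with the composition in mind.

## Barnyard QC

Specificity is the fraction of a cell's molecules mapping to one
species; with a two-species reference the two specificities sum to 1 for
any cell with molecules. A cell is called a species only when its
specificity strictly exceeds 0.9; 0.95 is kept separately as a
descriptive "high-purity" report threshold, not a calling rule. Filters
follow the stated verbs strictly: genes must *exceed* 500 (upper bound
`max_genes`, 6000–10,000 depending on experiment), the mitochondrial
ratio must be *below* 0.05. The transcript window 5×10³–6×10⁴ is treated
as inclusive at both ends ("between" is ambiguous; the choice is
documented and configurable). All filters are independently switchable
because protocols differ in which they apply.

Doublet flagging formalizes what is usually an ad-hoc judgment: a
heterogeneous doublet presents as species-unidentified with an abnormally
high molecule count. Two rules are provided — above the transcript-window
ceiling (fixed), or above median + 3×MAD of identified cells (robust) —
and the default flags their union. Unidentified cells with *low* counts
are deliberately never flagged: they look like negative controls
(ambient-only wells), not doublets. Negative wells are identified from
plate metadata only, never inferred from the data.

## The analysis stack

* **Normalisation**: `value = log2(1e6 · count/total + 1)`; inverting
  recovers cell totals of exactly 10⁶ CPM (the suite asserts this to
  1e-6 relative tolerance). Zero-total cells must be removed first; the
  error names the offending barcode.
* **log2 fold change** is defined as the *difference of group means on
  the log2(CPM+1) scale*. This differs from ratio-of-means conventions
  and is stated prominently because the |log2 FC| > 0.25 significance
  rule depends on it.
* **Variable genes**: dispersion (variance/mean of CPM) standardised
  within 20 mean-expression bins; zero-dispersion genes rank last; ties
  break lexicographically. No method is canonical here; binned dispersion
  is the classic choice.
* **PCA**: genes centred, not scaled; components 1–4 by default; signs
  fixed by making each component's largest-magnitude loading positive, so
  results are bit-reproducible.
* **Clustering**: k-nearest-neighbour graph (k = 20, Euclidean, in PC
  space), Jaccard-weighted shared-neighbour edges pruned below 1/15,
  Louvain modularity at `resolution` (default 1.5) under a fixed seed,
  labels 0-based by decreasing size. Exact label-for-label parity with
  any particular toolkit is not promised; the correctness surface is
  cluster recovery on data with known structure. Note that the
  modularity resolution appropriate for a dataset depends on its size
  and separation — on two clean 60-cell blobs, resolution 1.5
  over-partitions and ~0.8 recovers the blobs exactly, which is why the
  recovery tests run below the drug-experiment default.
* **Wilcoxon rank-sum**: exact permutation enumeration over all group
  assignments when both groups are ≤ 8 (valid under ties, which keep
  midranks); otherwise the normal approximation with tie correction and
  continuity correction. The exact path is checked against an
  independent enumeration oracle, the approximate path against R's
  `wilcox.test`. The family for BH adjustment is all genes with a
  nonzero value in the union of the two groups, adjusted per contrast.
  No fold-change prefilter is applied before testing.
* **Cell-cycle scoring**: phase score = mean marker expression − mean of
  an expression-matched background (25 genes per marker drawn from the
  same mean-expression bin, fixed seed, markers excluded); phase is the
  argmax of the S and G2M scores when positive, else G1. Background
  matching only works when genes of comparable mean expression exist —
  flat synthetic matrices defeat it, which the test fixtures account for
  by simulating dispersed baseline expression.
* **Batch removal**: per-gene linear model of expression on condition
  plus sum-to-zero-coded batch; fitted batch terms are subtracted,
  condition means preserved. Purely additive per-gene offsets are
  removed exactly; aliased designs (batch confounded with condition) are
  rejected with the aliasing named. The implementation is checked against
  limma's equivalent.
* **Pseudobulk**: per-condition mean log2(CPM+1) profiles with pairwise
  Pearson r and R².
* **Heatmap gene set**: union of genes with FDR < 0.05 in any contrast
  ("adjusted to 0.05" is read as BH-adjusted, configurable to raw p).
* t-SNE is a visualization pass-through with no correctness contract and
  is not part of the package's tested surface.

## Reproducibility machinery

Every stochastic function takes a seed; the pipeline derives per-stage
streams by salting one global seed with the stage name, so stages rerun
independently yet a full run is a pure function of (inputs, config).
All thresholds live in `default_config()` with the workflow's standard
values as defaults; none is hard-coded. Each run directory receives the
serialized YAML config for provenance.

## Problem sizes used in validation

The validation suite simulates 200 genes per species with 500-base
transcripts; the full-plate checks use the 96 + 96 + 32 geometry with a
mean of 2,600 molecules per cell at 3× duplication (~1.5 M read pairs),
ambient-recovery and differential-expression checks use 5,000 molecules
per cell, and the drug-arm comparisons use the 48 vs 144 cell group
sizes. These sizes were chosen to exercise every code path (including
UMI collisions, which are common at these densities) while keeping a
complete run in the minutes range on one CPU.

## What the synthetic data does and does not show

Passing on simulation demonstrates that the pipeline's logic is correct:
parsing, correction, assignment, collapse, classification and statistics
do what they claim, exactly, under known truth. It does not demonstrate
performance on real libraries: random transcripts have no homology, so
cross-species mismapping is structurally absent; there are no isoforms,
introns, repeats or rRNA; ambient RNA is drawn from the global profile
rather than lysis-prone cell types; doublets are always cross-species
and 1:1; and real descriptive statistics (genes per cell, transcripts
per cell, retention rates, specific gene lists) depend on the organism,
depth and chemistry and are not reproducible from synthetic data. Those
quantities are computed and reported by the pipeline, but their values
on simulation characterise the simulation, not any real experiment.
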