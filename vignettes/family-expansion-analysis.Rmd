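---
title: "Methods: classifying gene-family expansion from a chromosome-scale annotation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying gene-family expansion from a chromosome-scale annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famdup)
```

## The problem

Large secreted-lectin families such as the bivalve C1q-domain-containing
(C1qDC) proteins expand by small-scale gene duplication. On a
chromosome-scale assembly the mechanism of each duplication is legible from
gene geometry: unequal crossing over produces copies adjacent to (tandem)
or near (proximal) their source, while transposon-mediated copying leaves
dispersed paralogs. `famdup` classifies every family gene's duplication
mode from two ingredients only — a paralog-cluster partition of the family
proteins and the coordinate-sorted order of *all* annotated genes — and
surrounds that core with architecture classification, density profiling
and a per-site selection analysis of paralog clusters.

## Architecture classification

Family proteins are categorized by a fixed decision cascade over
externally predicted features (signal peptide, transmembrane segments,
coiled-coil segments with probabilities, profile-HMM domain hits):

1. a protein with no C1q-domain hit is rejected (not a family member);
2. no signal peptide, or any transmembrane segment → `OTHER_UNCERTAIN`;
3. ≥ 2 C1q domains → `SMULTI_C1Q`;
4. a SUEL lectin hit before the C1q domain → `SSUEL_C1Q`;
5. a collagen hit before the C1q domain → `C1Q_LIKE_TYPE_I`;
6. a coiled-coil segment (probability > 0.5) strictly between the
   cleavage site and the C1q start → `C1Q_LIKE_TYPE_II`;
7. a C1q domain starting within the linker tolerance after the cleavage
   site → `SGH_C1Q`;
8. otherwise `OTHER_UNCERTAIN`.

Two choices here were genuinely open. *"Immediately followed by the
domain"* has no standard numeric reading; we use a linker tolerance of
30 aa (configurable), long enough for the short unannotated linkers seen
in real secreted lectins and short enough to exclude genuine N-terminal
extensions. And the multi-domain check precedes all N-terminal checks
because multi-C1q proteins may or may not also carry a coiled-coil; the
SUEL/collagen checks precede the coiled-coil check because an annotated
N-terminal domain is stronger evidence than a propensity-based coil
prediction. Domain hits are pre-filtered at e-value ≤ 0.05 and model
coverage ≥ 0.6; the coverage cutoff operationalizes the removal of
partial domains, for which no published numeric convention exists.

## Paralog clustering

Pairwise identities come from global Needleman–Wunsch alignment with
BLOSUM62 scores and affine gap costs (open 10, extend 1) — unstated in
most published family analyses, so standard defaults are used — with
identity defined as identical aligned positions divided by the *shorter*
sequence length. That denominator matches the convention of
representative-clustering tools (CD-HIT-style) whose "> 50% identity"
thresholds these analyses quote; an aligned-length denominator is
selectable.

The default partition is the **single-linkage** one: connected components
of the graph with an edge wherever identity strictly exceeds the
threshold. Single linkage is order-invariant, admits an exact brute-force
oracle (graph components over the full identity matrix, used in the
tests), and refines monotonically as the threshold rises. A greedy
representative mode (longest-first, join the first representative
exceeding the threshold) is provided for parity with the
representative-clustering tools themselves; it is order-dependent by
construction and is not used by the pipeline defaults.

## Duplication-mode classification

With clusters fixed, each family gene is classified as:

* `SINGLETON` — its cluster has size 1;
* `TANDEM` — an immediate neighbor in the full gene order of its
  chromosome belongs to the same cluster;
* `PROXIMAL` — not tandem, but the nearest same-cluster paralog on the
  same chromosome lies within 100 kb (inclusive);
* `DISPERSED` — everything else.

Distances are intergenic gaps between nearer gene boundaries
(overlapping or abutting genes have distance 0): "within 100 kb" is
ambiguous between start-to-start and gap conventions, and the gap is the
conservative, overlap-safe reading. Strand is ignored — tandem copies are
usually co-oriented but the rule does not depend on it. Flanking
neighbors are taken from the order of *all* annotated gene features, so
any intervening gene (family or not) breaks tandem adjacency; a neighbor
from a *different* cluster does not make a gene tandem. Mode fractions
are reported as percentages rounded to two decimals, half away from zero
(`round_half_up()`), so printed summaries are platform-independent.

## Density landscape

Windowed counts use 1-Mb tiling windows `[k·w+1, (k+1)·w]`; a gene is
assigned to the window containing its start coordinate (the simplest
reproducible convention — assignment differences affect only boundary
genes). Chromosome densities are genes per Mb of exact bp length,
reported at two decimals.

## Counting-based per-site selection analysis

For each large paralog cluster (default ≥ 10 members) with an in-frame
codon alignment, the caller:

1. builds a neighbor-joining guide tree from Jukes–Cantor-corrected
   nucleotide p-distances (p capped at 0.74 to stay inside the
   correction's domain);
2. reconstructs ancestral codons by Fitch parsimony over the observed
   codon states, resolving ties by fewest nucleotide differences from the
   children's candidate sets and then lexicographic codon order, so the
   reconstruction is deterministic;
3. counts synonymous and nonsynonymous changes per site along every
   branch, averaging over all minimal mutational paths between parent and
   child codons with equal weights; paths through stop codons are
   excluded (in the standard code every sense-codon pair retains at least
   one stop-free minimal path; the nonsynonymous-only fallback is purely
   defensive);
4. computes the neutral expectation at each site as the mean
   potential-synonymous-site fraction of the codons observed there — per
   codon position, the fraction of non-stop single-nucleotide mutants that
   are synonymous, summed over the three positions and divided by 3 (for
   TTT this gives 1/9: only TTC among the nine mutants is synonymous);
5. applies a two-sided binomial test of the observed synonymous count
   against that expectation. Because path averaging yields fractional
   counts, the binomial tails are evaluated through the regularized
   incomplete beta function, which extends the exact test continuously to
   non-integer counts. Sites with p < 0.05 are `POSITIVE` when synonymous
   changes are depleted and `NEGATIVE` when enriched; zero-substitution
   sites are `NEUTRAL` with p = 1. P-values are reported raw (an optional
   Benjamini–Hochberg mode exists but is off by default, matching the
   per-method α = 0.05 convention of the selection servers whose site
   lists the consensus step consumes).

External methods' positive-site lists enter `consensus_support()`:
detection by ≥ 2 methods is `STRONG`, by exactly one `MODERATE`.

### Power of the counting method

The tests and the acceptance script calibrate the caller on simulated
alignments of 20 sequences × 200 codons. On all-neutral data the
`POSITIVE` rate is far below the nominal 5% (the binomial is discrete and
the test conservative). On sites planted at ω = 5 the measured per-site
power is, however, very low at α = 0.05. Both causes are intrinsic to
counting methods rather than to this implementation: at divergences low
enough for parsimony counting to be accurate, a site carries only a
handful of substitutions, and a two-sided binomial with expected
synonymous fraction ≈ 0.21 cannot reach significance unless essentially
zero synonymous events are observed — yet the synonymous background (whose
rate ω does not change) alone contributes one or more; at higher
divergences parsimony saturates, nonsynonymous changes are undercounted
roughly two-fold, and multi-nucleotide codon differences decompose into
paths whose synonymous step fraction drifts toward the neutral value,
erasing the signal. This is why site-level inference in practice leans on
the likelihood and Bayesian methods whose site lists this package merges;
the counting caller is the transparent, dependency-free member of the
method set, most useful for the `NEGATIVE` (purifying) calls and for the
consensus merge.

## The synthetic-data generator

`simulate_genome()` emulates exactly the observables the pipeline
consumes. Each tandem array grows from an independent random template
protein by iterated adjacent copy-insertion with per-copy CDS divergence
(default 0.05 substitutions/site, transition:transversion 2:1, stop
codons forbidden), gaps of 1–10 kb between copies; proximal copies attach
behind 1–3 background genes within 100 kb of their array; dispersed
copies are placed on another chromosome (or beyond 100 kb) and never
gene-order-adjacent to a same-cluster paralog. Background genes separate
family units so that planted truth modes satisfy the same partition rules
the classifier applies. A configurable fraction of copies (default 0.15)
is created at zero divergence, emulating very recent duplications and
giving the near-identical-paralog statistics something to recover. Genes
carry a single intron evolving at 3× the exonic rate with occasional
short indels, so exon/intron divergence contrasts exist in the emitted
sequences. Architecture features are emitted directly from each array's
template (predictors are not simulated; a noise option can flip feature
flags). The default scale — 3 chromosomes of 20 Mb, 300 background genes,
12 arrays of 3–15 copies, 20 proximal and 15 dispersed copies — yields
~130–150 family genes, large enough for stable recovery statistics and
small enough that a full identity matrix takes seconds.

What the generator does **not** emulate: annotation errors (truncated or
fused gene models), pseudogenes, nested or overlapping genes,
transposable-element sequence context, segmental duplications and
whole-genome duplication traces, and inter-array sequence similarity
(each array descends from an independent template, so clusters and arrays
coincide by construction). Passing recovery tests therefore demonstrates
the correctness of the classification logic under the stated geometric
model, not robustness to the annotation noise of real assemblies.

`simulate_selection_alignment()` evolves codons along a random pure-birth
(Yule) tree — the natural null model for a duplication history, and more
evenly branched than a coalescent — scaled to a root-to-tip depth in
expected neutral substitutions per nucleotide site (default 0.5,
representative of recently expanded paralog clusters). Each
single-nucleotide codon change has rate 1/3 if synonymous and ω/3 if
nonsynonymous, so one unit of branch length is one expected neutral
substitution per site; the realized substitution history is recorded
per site as ground truth.

## Numerical conventions and degenerate inputs

* Coordinates are 1-based inclusive throughout (GFF3 convention); all
  distance arithmetic converts explicitly.
* Gene order ties (identical starts) break by end coordinate, then gene
  ID; closest-paralog ties break lexicographically — every reported
  quantity is permutation-invariant.
* Neighbor joining falls back to a trivial star tree with a warning below
  three taxa; negative NJ branch lengths are clamped to zero.
* Percentages and densities round half away from zero at two decimals.
* Empty inputs yield empty-but-typed results (all-zero matrices, empty
  hit tables); invariant violations (end < start, duplicate IDs, internal
  stops, intervals outside the protein) abort with the offending record
  named.

## Problem sizes used by the test-suite

The suite validates on simulations sized to finish in seconds: the
default three-chromosome genome (~430 genes) for the recovery criteria,
two-chromosome miniatures (~20–40 family genes) for property checks, 50
random protein sets of ≤ 25 sequences for the clustering oracle, and
20 × 200-codon alignments for selection calibration. These sizes are the
package's validation choice; all generators scale to larger settings
through their configuration objects.
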