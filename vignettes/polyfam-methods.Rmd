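---
title: "Methods: gene-family characterization in a polyploid genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-family characterization in a polyploid genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polyfam)
```

`polyfam` packages, as one tested pipeline, the analyses that make up a
genome-wide characterization of a gene family in an allohexaploid genome:
identification and naming, physicochemical profiling, phylogeny, duplication
and homoeolog-triad structure, Ka/Ks-based dating, expression, and qPCR. The
reference use case is the PHD-finger (plant homeodomain) family of bread
wheat, a ~50–80 residue zinc-binding domain with a Cys4-His-Cys3 ligand
arrangement, but every stage is parameterized and none is wheat-specific.

This vignette explains each stage's model and assumptions, the parameters
that matter, the synthetic-data generators used for testing, and the design
choices made where the methodology was genuinely open.

## Family identification

A protein enters the family catalog iff it passes two independent gates:

1. **Similarity gate.** Optimal local alignment (Smith–Waterman with affine
   gaps, BLOSUM62, gap open 11, gap extend 1, via
   `Biostrings::pairwiseAlignment`) against a set of query proteins — known
   family members from related species in practice. Significance uses the
   Karlin–Altschul form \(E = K m n e^{-\lambda S}\) with the ungapped
   BLOSUM62-style constants \(K = 0.041\), \(\lambda = 0.267\); the gate is
   \(E < 10^{-5}\). The E-value model is deliberately simple: its role is to
   reproduce the *decision rule* of a BLASTP screen with a self-contained,
   oracle-testable scorer, not to re-implement BLAST's edge corrections.

2. **Domain gate.** A direct scan for the spaced zinc-ligand pattern
   C-x(1,3)-C-x(8,21)-C-x(2,4)-C-x(4,6)-H-x(1,2)-C-x(10,46)-C-x(2,3)-C with
   total span constrained to 50–80 residues. Spacer ranges follow the
   canonical PHD consensus and are configuration-exposed
   (`default_spacer_ranges()`). Matching is leftmost-shortest (smallest
   admissible end per start, scanning resumes after each hit), implemented
   as a bounded depth-first search over ligand placements, so the scanner is
   exact rather than regex-greedy. Profile-HMM scoring is out of scope; a
   real screen's web-service consensus (CDD/PFAM/SMART agreement) is not
   recoverable from a published workflow and is replaced by this single
   explicit pattern.

Accepted genes are named `prefix1..N` in chromosomal order: chromosome
number, then subgenome letter (A < B < D), then start coordinate, ties by
gene id; unplaced (`U`) genes take the final indices ordered by id. Genes
that pass both gates but lack coordinates are reported in an `unplaced`
attribute, never silently dropped. When a proteome carries several isoforms
per gene, `select_representative_isoforms()` keeps the lexicographically
first transcript id — a reproducible reading of "first splice variant".

## Protein statistics

`summarize_properties()` computes, per catalog protein: length; molecular
weight (ExPASy average residue masses + one water, 18.0153 Da); theoretical
pI (bisection on net charge under the Bjellqvist pKa set — N-terminus 7.5,
C-terminus 3.55, D 4.05, E 4.45, H 5.98, C 9.0, Y 10.0, K 10.0, R 12.0 —
to |charge| < 1e-4); GRAVY (mean Kyte–Doolittle hydropathy); aliphatic index
(mole-percent formula with weights 1, 2.9, 3.9); and Guruprasad's
instability index (10/L times the sum of DIWV dipeptide weights). Stability
uses the strict convention: II < 40 is stable, exactly 40 is unstable.
Unknown residues (X/B/Z) error in strict mode; in tolerant mode they carry
the mean residue mass, no hydropathy, no instability weight, and no
ionizable group.

## Phylogeny

Distances between aligned proteins are Poisson-corrected p-distances,
\(d = -\ln(1 - p)\), with pairwise deletion of gapped columns (this
maximizes usable sites; complete deletion would discard whole columns for a
single ragged sequence). \(p = 1\) is rejected as saturation rather than
mapped to infinity. Trees are built by Saitou–Nei neighbor joining,
implemented in-package with deterministic first-minimum tie-breaking and
negative branch lengths clamped to zero; `ape::nj` serves as an independent
cross-check in the test suite. Bootstrap supports resample alignment columns
with replacement; each replicate's draw is keyed by `seed + replicate`, so
supports are reproducible and independent of taxon input order. Support is
the percentage of replicate trees containing each internal bipartition of
the full-data tree.

Published family trees are usually *partitioned into clades by eye*;
`assign_clades(tree, k)` operationalizes that as cutting the k−1 longest
internal edges (ties by lexicographic bipartition; pendant edges are used
only in the degenerate regime k close to n, and a cut is kept only if it
actually splits a leaf group). The output is labeled as this
operationalization, not as a claim about the published partition.

Multiple sequence alignment itself is out of scope: the module consumes any
pre-made alignment. The demo pipeline trims unaligned family proteins to a
common length as a stand-in alignment, which is adequate only because the
synthetic family is indel-free.

## Duplication, collinearity and homoeolog triads

Anchors are homologous gene pairs annotated with each gene's rank along its
chromosome (computed over *all* genes, not only family members). Collinear
blocks are maximal chains of anchors, strictly monotone in both rank axes
(same or inverted orientation), with rank gaps at most `max_gap`, extracted
best-first by longest-increasing-subsequence dynamic programming; chains
shorter than `min_anchors` are dropped. Defaults `min_anchors = 5`,
`max_gap = 25` follow the published defaults of the standard collinearity
scanner; `tandem_window = 5` treats near-adjacent same-chromosome homologs
as tandem arrays. A duplicate pair is `tandem` (same chromosome, rank gap ≤
window — takes precedence), else `segmental` (anchor of a detected block),
else `dispersed`.

Homoeologous groups are single-linkage components over reciprocal-best
cross-subgenome hits restricted to identical chromosome numbers (the
overwhelmingly dominant pattern in an allopolyploid). Two refinements make
this robust:

* **Co-best ties** (within 5% of the best score) count as best, so a
  duplicated homoeolog joins its group instead of losing the
  reciprocal-best contest to its twin.
* **Identity floor**: a hit qualifies as a candidate homoeolog pair only if
  its score is at least `min_self_frac = 0.75` of the smaller self-alignment
  score. Homoeologs are near-identical; cross-group paralogs are not.
  Without this floor, a group that lost subgenome X reciprocally links to a
  same-chromosome group that retained X, because neither side has a
  within-group competitor in X — the classic failure mode of bare RBH
  orthology on families with missing members.

Each group's (nA, nB, nD, nU) counts classify it as `1:1:1` (complete
triad), `n:1:1-type` (one subgenome duplicated), `loss-of-one`, `orphan`
(singleton), `other` (mixed ratios, including groups with unplaced
members), or `uncategorized` (several copies confined to one subgenome —
no homoeologous ratio is measurable). `summarize_triads()` renders the
census with gene percentages at one decimal. The same census runs on the
packaged domain-architecture table fixture, treating each printed row as
one group and parsing its subgenome-composition string (parentheses
stripped, `U` counted as unplaced).

## Ka/Ks and divergence dating

`ka_ks()` implements the Nei–Gojobori (1986) counting method. Per codon,
synonymous site counts are the per-position fraction of the three possible
single-nucleotide changes that are synonymous, with changes to stop codons
excluded from the denominator, so s + n = 3 exactly. Differences between a
codon pair are averaged with equal weight over all minimal mutational
pathways (1, 2, or 6 orderings); pathways through stop codons are excluded
and the remainder renormalized — the common NG86 convention, since the
original calculator's exact stop handling is not recoverable. Site counts
are averaged over the two sequences; proportions are Jukes–Cantor
corrected, \(K = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)\). Pairs with
\(p \ge 3/4\) (saturation) or Ks = 0 are flagged `incalculable` rather than
given fabricated values — the same behavior the wheat–dicot comparisons
show in practice. Selection is classified as purifying/neutral/positive at
ω = 1 with a 1e-6 equality guard.

Divergence dating uses the molecular clock \(T = K_s / (2\lambda)\) with the
grass synonymous rate \(\lambda = 6.5\times10^{-9}\) site⁻¹ year⁻¹,
reported in Mya (i.e. divided by 10⁶). As printed, the source formula's
\(10^{-6}\) placement is dimensionally ambiguous; this reading reproduces
the magnitude of the published cross-species ages (e.g. Ks ≈ 0.166 → 12.78
Mya for a wheat–barley comparison).

## Expression and qPCR

TPM matrices are transformed as log2(TPM + 1) (pseudocount
configuration-exposed). Expression bins follow the printed boundaries
exactly: high TPM > 10, medium 1 < TPM ≤ 10, low 0 < TPM ≤ 1, none
TPM = 0. Differential expression per contrast uses a two-sided Welch t-test
on log2(TPM+1) with Benjamini–Hochberg FDR across genes; a gene is a DEG iff
|log2FC| > 1 **and** FDR < 0.05. The published rule "Fold Change > 1" is
read as a threshold on the absolute log2 fold change (two-fold either way):
a literal fold > 1 would flag every upregulated gene regardless of
magnitude, which contradicts the sparse tails of the published volcano
plots. The t-test is a stand-in reproducing the decision rule; the upstream
engine behind public expression portals is unspecified, and count-model
methods (negative-binomial GLMs) are deliberately out of scope because the
input is TPM, not counts. Venn-style DEG intersections report exclusive
region counts; heatmap ordering is average-linkage clustering on
1 − Pearson correlation of log2 rows with rows pre-sorted by id for
determinism.

qPCR analysis uses 2^(−ΔΔCt) with a reference gene (β-actin in the source
workflow): ΔCt per replicate, ΔΔCt = mean treated − mean control *at the
same timepoint* (per-timepoint control rather than time-zero control; the
published normalization is unstated, and the generator plants per-timepoint
folds). Significance is a classical equal-variance one-way ANOVA on
replicate ΔCt values (`stats::oneway.test(var.equal = TRUE)`), starred at
p < 0.05 and p < 0.01; zero within-group variance with equal means is an
error (F undefined), not a silent zero.

## Synthetic data: what it emulates, and what it does not

All generators are deterministic given one integer seed and return their
ground truth.

* `generate_family_genome()` plants homoeologous groups whose A:B:D
  composition follows a configurable ratio mixture; the default mixture
  (85% triads, 2% subgenome duplication, 7% single loss, 4% other, 2%
  orphans) mirrors the high homoeolog retention of the reference family.
  One family ancestor protein carries the motif; group templates diverge
  from it at 20% per residue and members at 1% (duplicated copies placed in
  tandem), so any member detects the whole family by similarity — the way a
  real family shares a domain plus backbone. Background genes are drawn
  from an alphabet without Cys/His, making them motif-free by construction;
  family mutations avoid the eight ligand positions and never introduce
  C/H, so planted motif spans are exact truth for the scanner. Group CDS
  derive from one template CDS with a 3% synonymous swap rate between
  members, giving homoeolog pairs realistic sub-saturation Ks. The group
  order is conserved along homoeologous chromosomes, so cross-subgenome
  anchors are collinear. **Not emulated:** indels (so pipeline "alignments"
  are trivial), transposons/gene structure, isoforms, GC/codon-usage bias,
  and real spacer sequence conservation. Perfect sensitivity/specificity on
  this genome therefore demonstrates the decision logic, not performance on
  diverged real proteomes.
* `evolve_codon_pair()` evolves both lineages from a stop-free ancestor by
  uniform per-site mutation; synonymous changes are accepted with relative
  probability min(1, 1/ω) and nonsynonymous with min(1, ω), stops rejected.
  `branch_length` is the expected number of mutation *attempts* per
  nucleotide site. No transition/transversion bias — consistent with NG86,
  which also ignores it; estimates under a biased process would need a
  different counting method.
* `generate_expression_matrix()` uses a lognormal(meanlog 3, sdlog 1.5)
  TPM baseline — chosen to span all four bin thresholds — with ±`lfc` log2
  shifts for a planted DE fraction and lognormal replicate noise;
  optionally whole samples forced to zero. No mean–variance trend or
  library-size effects.
* `generate_qpcr_table()` plants Ct = baseline − log2(fold) + Gaussian
  noise with triplicate structure and a constant-baseline reference gene,
  so noise-free inversion through 2^(−ΔΔCt) is exact.

## Numerical choices and degenerate inputs

Coordinates are 1-based inclusive end to end (the GFF3/Bioconductor
convention); there is no internal 0-based representation, hence no
conversion point to drift. Readers reject malformed input with line
numbers. pI bisection runs to |charge| < 1e-4 or interval < 1e-8 on
[0, 14]; the charge function is monotone so a root always exists.
NJ Q-ties take the first row-major pair. Bootstrap with 0 replicates
returns the tree without supports. `classify_selection` treats
|ω − 1| ≤ 1e-6 as neutral. All-gap alignment overlap, p ≥ 1, stop codons in
frame, empty sequences, length-1 proteins for the instability index, and
missing reference genes are errors, not silent repairs.

## Problem sizes used in the checks

The shipped tests and the acceptance script exercise: synthetic genomes of
6–12 homoeologous groups over 2–3 chromosomes per subgenome with ~90–130
genes; all 61×61 sense-codon pairs against exhaustive pathway enumeration;
ω recovery over 200 replicate pairs of 500 codons (plus 50-replicate runs
across ω ∈ {0.2, 0.5, 1, 2}); NJ against exhaustive topology search for 5–6
taxa and tree-metric recovery up to 8 taxa; 200 null expression matrices of
60 genes × 6 samples; and bootstrap runs of 10–100 replicates. These sizes
were chosen so each property is measured with comfortable statistical
margin while a full run of the suite stays interactive.

## Known limitations

The E-value model ignores gapped-alignment statistics and composition; the
motif scanner accepts exactly one ligand topology; clade assignment is one
defensible reading of a visual partition; the DEG engine is a decision-rule
stand-in; homoeolog grouping assumes homoeologs keep their chromosome
number; and the pipeline's phylogeny stage requires externally aligned
input for real data. Genome-scale published counts (e.g. full-proteome
family sizes or cross-species pair totals) require the real genomes and
databases and are intentionally outside what the synthetic suite claims to
reproduce.
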