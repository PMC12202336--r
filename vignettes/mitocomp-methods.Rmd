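---
title: "Methods: comparative mitogenomics of intron-rich fungal mitochondria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative mitogenomics of intron-rich fungal mitochondria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

# Scope and model

Fungal mitochondrial genomes in the Hypocreales are circular molecules of
roughly 30–52 kb carrying a fixed core inventory — 15 protein-coding genes
(atp6/8/9, cob, cox1–3, nad1–6, nad4L, rps3), two rRNAs (rns, rnl) and
25–27 tRNAs — under the mold mitochondrial genetic code (table 4, in
which TGA encodes tryptophan and only TAA/TAG terminate). Their striking
size variation is dominated not by the core genes but by mobile group-I
introns, homing-endonuclease ORFs, repeats and intergenic spacers. This
package treats that comparison as a pipeline of testable operations:
composition and skews, codon usage, per-gene evolutionary rates, repeat
landscapes, intron positional-class homology with gain/loss
reconstruction, and a distance-based phylogeny stage.

## Coordinates and data model

Internally every coordinate is 0-based half-open on the forward strand of
the linearized circle; all reports and GenBank output are 1-based
inclusive. Features crossing the origin are stored as two-part joins and
lengths always sum over parts. A minus-strand feature's sequence is the
reverse complement of its ascending-coordinate concatenation. Unknown
bases (N) are excluded from every composition denominator, which keeps
the skew ratios well defined; a skew whose denominator is zero is
reported as NA with a warning rather than silently as NaN.

The GenBank reader accepts both encodings of introns seen in organelle
records — CDS `join()` locations and explicit `intron` features — and
reconciles them: an explicit intron exactly matching a join gap supplies
the subclass label; a gap without one becomes an intron of group
"unknown"; a disagreement is flagged with a warning and the explicit
feature wins, never silently resolved.

## Region partition

Every genome position is assigned exactly one class with precedence
PCG exon > rRNA > tRNA > intron > free ORF > intergenic, so class totals
sum to the genome length as an exact integer identity — the conservation
law each simulated fixture is checked against. Intronic
homing-endonuclease ORFs therefore count as intronic nucleotides, which
is what the published intron-fraction figures assume. Overlapping PCG
exons (annotation errors) warn, and the earlier feature keeps the shared
positions.

## Rates

K2P distances use the closed form d = −½ ln(1−2P−Q) − ¼ ln(1−2Q) on the
exact transition/transversion proportions; saturated pairs
(1−2P−Q ≤ 0 or 1−2Q ≤ 0) are reported as missing and counted, never
imputed. Ka/Ks is Nei–Gojobori (1986) with Jukes–Cantor correction:
per-codon synonymous site fractions averaged over both sequences
(mutations creating a stop count as nonsynonymous), multi-hit codons
averaged over all minimal substitution pathways excluding those passing
through a stop (if every pathway does, all are counted). The choice of
NG86 over a likelihood dN/dS is deliberate: it is deterministic,
closed-form, and testable against an exhaustive pathway-enumeration
oracle, which the test suite does on random codon pairs. The published
analysis used a model-averaging calculator; NG86 is a documented method
substitution, adequate at the low divergences of congeneric
mitochondria.

Codon alignments are protein-guided: CDSs are translated under code 4,
each protein is globally aligned (BLOSUM62, affine gaps) to the first
species in the gene's species set, and only reference codons aligned in
every species are threaded back — a deterministic reference-anchored
filtering that avoids a full MSA dependency while guaranteeing gapless,
frame-true matrices. Columns lost to indels are counted and reported.
Alignment tie-breaking follows the deterministic conventions of the
alignment engine rather than an explicit leftmost-gap rule; on the
low-divergence inputs this pipeline targets the two differ only in
pathological ties.

## Repeats

The three detectors are intentionally transparent re-implementations of
the field's standard tools, at the parameters those tools are
conventionally run with:

* **SSRs** — maximal tandem runs of a primitive 1–6 nt motif at the MISA
  copy thresholds (10/5/4/3/3/3). Motifs are reported as the smallest
  rotation; runs are trimmed leftmost to whole copies so interval length
  = motif × copies; compound/interrupted SSRs are not merged.
* **Dispersed repeats** — maximal repeated pairs under a Hamming budget
  of 3, length 30–5,000, forward and palindromic. Maximality is defined
  per diagonal: a window bounded on both sides by a fourth mismatch (or
  the sequence end) cannot be extended. The scanner streams each
  diagonal in C++ with O(1) memory; the E-value machinery of self-BLAST
  is replaced by these explicit length/mismatch bounds, which detect the
  same repetitive regions deterministically.
* **Tandem arrays** — exact k-mer recurrence seeds extended greedily
  while running identity ≥ 0.85, period 2–100, copies ≥ 1.9, with a
  24-nt minimum array length playing the role of an alignment-score
  cutoff; overlaps resolve to the longest array, then smaller period,
  then leftmost. No probabilistic alignment scoring is attempted.

Circular genomes are scanned on the doubled sequence with calls
constrained to start in the first copy, so origin-spanning repeats are
found; for dispersed repeats, windows truncated by the doubled-sequence
boundary are dropped as their full image is reported elsewhere, making
near-origin maximality approximate — the documented cost of the
doubling strategy.

## Intron positional classes

The core procedure labels each intron by its insertion site in an
intronless reference CDS: the species gene (exons concatenated) is
globally aligned to the reference (match +2, mismatch −3, gap open 5,
gap extend 2), and the position of the last aligned exon nucleotide 5′
of the insertion becomes the label "P&lt;pos&gt;", 1-based. If that
column sits in a reference gap the nearest aligned column 5′ is used and
the assignment is marked unconfident; a confident call also needs at
least 10 aligned columns within 30 nt on each flank. Identity below 0.3
makes a gene unalignable and all its introns undetermined ("*").
Undetermined cells are never counted as presence and never force a
gain/loss event. The absolute ±1 convention of insertion coordinates is
fixed and documented here; published labels whose convention is unstated
may differ by one.

Co-positional introns cluster into ortholog groups by global sequence
identity over the shorter intron (single linkage, threshold 0.7, exposed
as a parameter); a splitting position gets suffixed labels (P100a,
P100b). Dollo reconstruction places the single gain on the branch to the
MRCA of all present tips with the minimal set of losses below it (a loss
is only charged to a subtree containing a confirmed absence); Fitch is
standard two-pass parsimony with root ties resolved toward absence.
Replaying the reconstructed events along the tree reproduces the tip
matrix exactly — a property the suite tests on hundreds of random
matrices.

## Phylogeny stage

The published analyses used ML and Bayesian inference; this package
deliberately ships a desk-scale stand-in — K2P distances on the
14-gene codon-filtered supermatrix (rps3 is excluded from phylogeny but
kept in the rate tables, matching the two published gene lists),
neighbor joining with lexicographic tie-breaks and negative branch
lengths clamped to zero (the deficit moved to the sibling edge), and
nonparametric bootstrap by column resampling. Supports are percentages
of replicates containing each bipartition; saturated replicates are
dropped and counted. Robinson–Foulds distances come from canonical
bipartition sets. Bayesian convergence diagnostics have no analogue here
and are out of scope.

## The simulator and what passing tests mean

`simulate_mitogenomes()` draws an ancestral genome — stop-free PCGs at
the target AT fraction (default 0.74), rRNAs, 71–85 nt tRNAs, geometric
intergenic spacers (mean 200 nt, a free choice surfaced in the config
since no empirical length distribution is available) — and evolves it
down a species tree (given, default seven-species topology, or a Yule
draw with unit-exponential branch lengths). Introns from a positional
catalog follow a planted, Dollo-consistent presence history; about half
carry a ≥300 nt ATG-initiated ORF labeled LAGLIDADG-like or
GIY-YIG-like. Substitutions use a 2:1 transition bias; internal stops
created in coding blocks are repaired by resampling the affected codon,
keeping runtime linear; a synonymous-only mode restricts changes to
silent third positions for invariance tests. Indels are confined to
intergenic spacers. Repeats (SSR motifs, a tandem array, a forward and a
palindromic dispersed pair) are planted into distinct spacers with guard
bases so the planted run is maximal, and every planted coordinate is
recorded in the ground truth.

The default seven-species history plants exactly 84 introns — 64 in
PCGs (76.19%) and 20 in rRNA genes (23.81%), per-species counts 5–15 —
deliberately mirroring the shape of the published *Cordyceps*
comparison, with intron positions and lengths chosen once as plausible
values rather than fitted to any dataset.

What the simulator does **not** emulate: group-I intron secondary
structure and splicing, codon-usage bias fitted to real genomes,
recombination, gene rearrangement, and sequencing/assembly error.
Passing recovery tests therefore demonstrates that the pipeline's
inference is correct when its assumptions hold, not that real annotation
pipelines upstream are error-free.

## Numerical conventions

Percentages in reports are rounded half away from zero to 2 decimals
(matching the style of published tables; note that a table built with
truncation can differ by one final digit — one published intron-fraction
figure does), skews to 4 decimals; all in-memory values keep full double
precision. Correlation p-values use the t approximation with df = n − 2
on both Pearson and mid-rank Spearman coefficients (the published
comparison had n = 7), with an exact permutation p available for n ≤ 8.
Test and acceptance runs use reduced problem sizes — four-gene genomes
of ~20 kb, 20–200 replicates — chosen so each property is exercised at
scales where its brute-force oracle is also computable.

## Known limitations

* NG86 underestimates Ka/Ks at high divergence; the pipeline targets
  congeneric comparisons.
* Reference-anchored codon filtering can discard alignable columns when
  the anchor species carries a private deletion.
* The tandem detector reports no probabilistic score; arrays below 24 nt
  are left to the SSR scanner.
* Horizontal intron transfer is only surfaced as single-species Pcls; no
  cross-dataset search is attempted.
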