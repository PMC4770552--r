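---
title: "Models and methods behind nirkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nirkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirkit)
```

This vignette explains the models and procedures the package implements,
the parameters that matter and their defaults, the numerical choices made
where the design was genuinely open, and what the synthetic-data
generator does and does not emulate.

## Reference-anchored coordinates

All per-sequence features — conserved residues, active-site motifs,
clade-diagnostic indels, terminal extensions — are defined in the residue
numbering of a full-length 375-aa NirK reference. Rather than building a
progressive multiple alignment, every candidate is anchored to the
reference by one optimal global pairwise alignment (star alignment).
This is sufficient because every feature is a *per-sequence* property in
reference coordinates; a multiple alignment for phylogenetics is obtained
afterwards by stacking the anchored rows, padding insertions relative to
the reference as extra columns and trimming terminal overhangs (the
N-/C-terminal extensions), mirroring the usual practice of trimming an
alignment to the region shared by all sequences before tree building.

The aligner is a Gotoh three-state affine-gap DP (compiled code). A gap
run of length $k$ costs $g_o + (k-1)\,g_e$ with defaults $g_o = 11$,
$g_e = 1$ on BLOSUM62. Ties are broken deterministically
(substitution over gap-in-reference over gap-in-target, both for the
final state and each backtrace step), so identical inputs always give
byte-identical outputs. The DP is verified in the tests against
brute-force enumeration of *all* alignments for short pairs.

The bundled reference is a **synthetic surrogate**: its constrained
positions carry the conserved residues and Clade I motif, all other
positions are drawn once from a fixed-seed uniform distribution over the
20 amino acids. Two numerical touches make feature calling unambiguous:

* the residues flanking the two deletion regions are forced to be
  locally distinct, so deleting a region yields a *unique* optimal gap
  placement (otherwise a 7-gap can slide when boundary residues repeat);
* the terminal residues (positions 1 and 375) are forced to differ from
  the extension anchor residues C and M. Without this, the optimal
  alignment can absorb the outermost residue of a terminal extension
  onto the reference terminus, reclassifying the extension as an
  internal insertion and hiding it from the overhang scan.

A real reference of the same numbering can be supplied wherever the
surrogate is accepted.

## Residue rules, motifs, indels, extensions, clades

**Validation.** A candidate is accepted as NirK iff all nine rules pass:
the seven copper-ligand positions (His59, His64, His99, Cys100, His110,
Met115, His298) and the two active-site residues (Asp62, His237).
Deleted positions and `X` fail. The T1Cu/T2Cu partition of the ligands
is descriptive metadata only; validation weighs all rules equally.

**Motifs.** The His237 motif window is fixed to $[-3, +1]$ because the
published motif families (TRPHL, SSFHV/I/P) place the His fourth of
five; the Asp62 window is a symmetric $[-2, +2]$ default (no published
convention exists). Both windows are configurable. A window touching a
deleted position yields a flagged, undefined motif rather than a
truncated string.

**Indels.** The linker (190–196) and tower (258–264) deletion regions
are *configuration values*, shared between the caller and the generator
— published evidence fixes their length (7 aa) and structural identity
but not their absolute coordinates, which depend on the reference. A
deletion is called when at least $\lceil L/2 \rceil + 1$ of the region's
$L$ reference positions are deleted: exact-$L$ matching is brittle when
a stray point indel rags the gap edge, while the majority rule keeps
the call specific. The Bacillaceae extra loop is modelled as an
insertion between positions 310–311 with the same majority rule on the
inserted-residue count.

**Extensions.** The c-type heme template `C-x2-C-H-x50-M` is scanned in
the C-terminal overhang only, the cupredoxin template `C-x4-H-x4-M` in
the N-terminal overhang only — never inside the mapped reference span.
Spacers are matched exactly by default (`spacer_tolerance = 0`) because
the templates specify exact counts; a tolerance is exposed for noisy
real data.

**Clades.** Both diagnostic deletions ⇒ Clade II; neither ⇒ Clade I;
exactly one ⇒ `unclassified`. The literature offers no rule for the
mixed case, and we prefer an explicit fallback over a guess.

## Phylogenetics

Distances are amino-acid difference counts (optionally p-distances).
Complete deletion removes every column containing a gap in *any* row
before counting, so all pairs share one column set; pairwise deletion
drops columns per pair. Neighbour joining uses the standard Q-matrix
agglomeration with a lowest-index tie-break; on additive matrices it
recovers the generating tree exactly (tested to $10^{-9}$ on random
trees). Negative branch lengths arising from non-additive data are
clamped to zero with the deficit transferred to the sibling branch,
preserving the joined pair's path length — the standard display
convention. Bootstrap resamples original columns with replacement and
recomputes the deletion step *per replicate* (resampling first, deletion
second; tools differ here and we fixed one order). Support of an edge is
the percentage of replicate trees containing its bipartition.

## Primer evaluation

A primer position mismatches a template position iff their IUPAC base
sets do not intersect (`N` therefore never mismatches). The best binding
site minimises total mismatches over all offsets on the appropriate
strand, ties to the leftmost. Mismatch profiles report, per clade and
per primer position, the fraction of sequences mismatching at their best
site; the combined profile is exactly the size-weighted mean of the
clade profiles. Whether real surveys counted mismatches at best sites or
at one alignment-anchored site is rarely stated; the package implements
both (best-site scan vs `anchors` in `bindingRegionLogo()`), and the
profile functions report which was used. The 3' window defaults to
$k = 3$ ("the 3' site" is conventionally the terminal few bases).
Sequence logos use nucleotide information content
$\mathrm{IC} = 2 - H$ bits without small-sample correction — at the
dataset sizes involved the correction is negligible against the effects
of interest.

## Pathway inventories and co-occurrence

Genomes are admitted with at least one nitrite reductase (nirK copies
≥ 1 or nirS) — the working definition of a denitrifier *sensu stricto*.
The denitrification category follows from (nor, nosZ); DNRA labels are
**non-exclusive**: a genome with both nrfA and nirB contributes to both
branches, and one with both napA and narG to both pairings. This is the
only reading under which published per-phylum DNRA columns can sum above
the combined percentage, and it is the rule implemented and tested.
NirV is carried and summarised but plays no role in classification.
Percentages are rounded to one decimal, half away from zero; the Total
row is always computed from raw calls, never from rounded per-phylum
values.

Co-occurrence of two genes conditions on the margins: with $N$ genomes,
$N_1, N_2$ presences and $j$ joint presences,
$P(j) = \binom{N_1}{j}\binom{N-N_1}{N_2-j}/\binom{N}{N_2}$, computed via
log-binomial coefficients. `p_lt` and `p_gt` are inclusive tails (they
overlap at $P(j_{\mathrm{obs}})$). The phi coefficient is the Pearson
correlation of the binary vectors, with a $t$-based p-value on $N-2$
degrees of freedom; for $N = 2$ or constant vectors it is flagged
undefined while the tails are still computed. The all-pairs screen
applies Benjamini–Hochberg across pairs to the two-sided
$2\min(p_{lt}, p_{gt})$ — a deliberate choice; single-pair analyses in
the literature typically report uncorrected values.

Calibration note: the discrete hypergeometric tail is conservative and
cannot hold a nominal 5 % level exactly; the package's calibration check
therefore uses the continuous phi p-value, which attains ~5 % type-I
error at $N = 250$, while planted-association detection uses the
one-sided hypergeometric tail.

## The synthetic-data generator

The generator is a pure function of (config, seed) and returns a
ground-truth table alongside the data. Defaults are the conditions used
throughout the tests: 10 sequences per clade, substitution rate 0,
extension fractions 0.15 + 0.15 (matching the ~30 % incidence of
terminal extensions, split between the heme and cupredoxin types), 5 %
multi-copy genomes, Clade II motif SSFHV (one member of the SSFHV/I/P
family; variants via config). Substitution noise is i.i.d. outside
protected positions (rule positions, motif windows, indel regions with
3-residue flanks, the termini), so planted features are recoverable by
construction up to rate 0.10 — the tests verify 100 % recovery of the
truth table at rate 0 and 100 % clade recovery at rate 0.10.

Inventory sampling realises specified gene-pair odds ratios by solving
the exact 2×2 joint for each pair and propagating conditionals over the
association graph, which must be a forest. For marginals strictly inside
(0, 1) every odds ratio > 0 is feasible (the odds ratio sweeps 0 to
infinity as the joint probability runs over its Fréchet interval), so
rejection occurs only for non-positive odds ratios, degenerate marginals
or cyclic constraint graphs.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: there is no tree-structured evolution (no
site-rate heterogeneity, no lineage-specific divergence; noise is i.i.d.
per sequence), no codon-usage realism in back-translation, no
partial/fragmentary sequences, and real alignments of 300–995-aa
proteins are far harder than alignments of surrogate-derived sequences.
Consequences drawn in the tests about statistical recovery (binomial
tolerances, bootstrap supports) hold under these idealised conditions.
In particular, the clade-separation bootstrap check runs at the
zero-noise default, because i.i.d. noise contributes distance without
clade signal — unlike real data, where clade-level divergence dominates.

## Problem sizes and determinism

The test suite and the acceptance script run on deliberately small
problems: 10–24 sequences per set, alignments of ~380 columns, 50–100
bootstrap replicates, inventories of 80–400 genomes, 40–60 Monte-Carlo
seeds — sizes chosen so the whole suite completes in well under a
minute while keeping binomial tolerances meaningful. Every stochastic
step takes an explicit seed; the pipeline writes byte-identical report
bundles for identical configs, and the run manifest (config hash, seed,
package version, artifact list) suffices to re-run any stage in
isolation.

## Known limitations

* The clade call rests entirely on the two diagnostic deletions; real
  sequences with exactly one deletion are reported `unclassified` and
  should be resolved by phylogeny.
* Star alignment to a single reference can misplace insertions in
  regions where the reference is a poor model (e.g. long Actinobacterial
  inserts of variable position).
* Published dataset-level statistics that depend on the original curated
  alignment (overall 10 % mean similarity, per-clade 16 %/66 %, motif
  frequency tables, the count of 39 heme-extended sequences, 61 % NirV
  incidence) are not desk-reproducible without that dataset and are
  deliberately not asserted anywhere in the package.
* Signal peptides, transmembrane domains and spectral (blue/green)
  subclassing are out of scope.
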