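---
title: "Detecting lineage-specific loss of olfactory receptor genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting lineage-specific loss of olfactory receptor genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orloss)
```

## The problem

Olfactory receptor (*OR*) genes are single-exon genes encoding seven-helix
transmembrane receptors; they form one of the largest gene families in
vertebrate genomes, and their loss or retention tracks shifts in sensory
ecology. A recurring question in comparative genomics is whether a focal
lineage — here, penguins against other core waterbirds — has relaxed
selection on olfaction, which leaves a genomic signature: *OR* loci that are
intact in relatives accumulate ORF-disrupting mutations (premature stop
codons, frameshifting insertions/deletions) in the focal lineage, and
disruptions shared across species at homologous positions indicate a single
pseudogenization event in their common ancestor.

`orloss` implements that inference chain end to end:

1. **Intact-gene identification** — six-frame ORF scanning plus length and
   transmembrane-gap filters against an intact reference.
2. **One-to-one ortholog extraction** — maximal well-supported single-copy
   clades from a gene tree.
3. **Pseudogene calling** — codon-aware detection of nonsense mutations and
   frameshifting indels relative to an intact ortholog reference.
4. **Shared disruptions and ancestral loss** — Dollo-style placement of
   shared signatures on the stem branch of their carriers' MRCA.
5. **Contingency statistics** — an exact two-sided test contrasting
   pseudogene fractions between two lineage groups.
6. **A repertoire simulator** — ground truth for every stage.

## The intact filter

A candidate is an intact full-length *OR* when its best ORF is strictly
longer than 250 amino acids (an ORF of exactly 250 aa is rejected) and a
global protein alignment to the intact reference shows no deletion gap of
five or more consecutive amino acids overlapping a transmembrane interval.
Both thresholds are configurable through `filter_criteria()`; the defaults
encode the conventional cutoffs for full-length OR identification.
Transmembrane intervals are supplied with the reference panel rather than
predicted; `default_tm_intervals()` provides canonical seven-helix positions
for a ~310-codon receptor, rescaled to the reference length. The protein
alignment uses BLOSUM62 with gap open 10 / extend 1 — standard defaults,
since no canonical parameter set exists for this step.

Candidate discovery by homology search (TBLASTN/BLASTX against assemblies
and nr) is out of scope: the package accepts candidate sequences directly.
An optional identity prefilter (`min_identity` in `identify_intact()`) can
reject ORFs below a protein-identity floor, off by default.

## Pseudogene calling

`call_disruptions()` aligns the query to the reference CDS globally
(Needleman–Wunsch, affine gaps; match +2, mismatch −3, open −8, extend −2 —
configurable, since published analyses of this kind inspect alignments by
eye) and projects the alignment onto reference codons:

* every indel whose length is not a multiple of 3 is a frameshift;
* premature stops are read in the query's **running frame** — the frame
  implied by the cumulative indel offset — so stops induced downstream of a
  frameshift are reported, matching how first-disruption positions are
  tabulated in comparative studies;
* after compensating indels (net offset ≡ 0 mod 3) downstream codons are
  evaluated in the restored frame and `frame_restored` is set;
* in-frame indels are recorded but never call a pseudogene on their own.

Indels are left-normalized to their 5'-most equivalent placement — the same
convention variant callers use — so coordinates are deterministic wherever
the alignment is ambiguous. The simulator records its planted coordinates
under the same convention, which is what makes exact recovery testable.

Partial gene segments (e.g. 612–964-bp amplicons) are aligned semiglobally
(`partial = TRUE`) so missing flanks are not charged as deletions; the
reading frame of a segment is anchored to the reference codon phase at its
5' aligned end. Queries whose aligned identity (matches over all alignment
columns, gaps counted as differences) falls below `min_identity` (default
0.5) are flagged `low_confidence` with a warning — orthology is suspect —
but the computed report is returned rather than fabricated or suppressed.

For equal-length queries at high identity with no mismatch run longer than
4, the optimal affine-gap alignment under the default scores is provably
gapless (a compensating gap pair costs 20 and repairing *k* mismatches gains
5*k*), so the dynamic program is skipped. This is a pure optimization; any
other scoring goes through the full alignment.

`classify_terminal_position()` labels the first disruption as 5'-terminal
when it falls before a configurable fraction of the reference codon count
(default 0.5); no numeric convention exists for "near the 5' end", so the
threshold is an explicit parameter.

## Ortholog extraction

`extract_ortholog_clades()` applies three criteria: node support strictly
greater than 85 (the conventional bootstrap cutoff; "greater than" is read
strictly), at most one gene per species, and at least four species. Only
**maximal** qualifying clades are returned — when nested clades both
qualify, the outermost wins — because ortholog groups should partition the
tips rather than overlap; groups are numbered by pre-order appearance.
Node labels are interpreted as the support of the clade below the node (the
common newick convention); labels on a 0–1 scale are taken as posterior
probabilities and rescaled ×100, so either ML bootstrap or Bayesian support
can be supplied without claiming the two are equivalent. Rooting uses the
outgroup when given, else midpoint rooting.

`build_gene_tree()` is plumbing for self-contained synthetic runs:
neighbor-joining on p-distances (pairwise deletion of gapped/ambiguous
sites) with site-resampling bootstrap supports. It deliberately does not
replace ML/Bayesian inference on real data — external trees are accepted as
input.

## Shared disruptions and ancestral loss

Two disruptions match when kind, indel length, and reference codon agree
within `tolerance_codons` (default 0: exact coordinates, as is typical when
all queries are projected onto one reference; raise it for noisy
alignments). `infer_ancestral_loss()` places each shared **disruptive**
signature (nonsense or frameshifting indel) on the stem branch of its
carriers' MRCA — the Dollo assumption that a complex loss happens once — and
species-private disruptions on terminal branches.

A shared in-frame deletion never makes a strict ancestral call: it does not
destroy the reading frame. But when such a deletion is at least
`weak_min_deletion_nt` (default 12) long and every carrier is independently
a pseudogene, the locus is flagged *ancestral (weak evidence)* — the
situation where a large shared deletion plus species-private disruptions
jointly suggest pseudogenization before divergence. Weak calls are reported
separately and never enter the strict contingency statistics.

Congener substitutes (sequencing a sister species when the genome species
cannot be amplified) are handled by an alias map applied before tree lookup.
Absence of data (PCR failure, missing assembly regions) is reported as
missing, never treated as evidence of loss.

## The exact test

`contingency_table()` counts sequence observations (species × locus), not
distinct loci, excluding absent entries. `fisher_exact()` enumerates all 2×2
tables with the observed margins in log space and sums the probabilities of
tables no more probable than the observed one (relative tolerance 1e-12) —
the standard minimum-likelihood two-sided rule; two-sided because the claim
under test is a difference between groups. Degenerate tables (a zero margin)
return p = 1 with a warning. The implementation is validated in the test
suite against an independent hypergeometric enumeration and against
`stats::fisher.test`.

## The simulator and what it does (not) show

`simulate_repertoire()` evolves each locus from a random intact CDS (ATG +
sense codons + TAA; 310 codons by default, comfortably above the 250-aa
filter) along a species tree by uniform per-site substitution, with planted
disruptions on named branches and per-species random absence.

Defaults encode the eight-waterbird study design: the `waterbird_tree()`
topology (loon outside; penguins sister to the fulmar; four Pelecaniformes),
29 loci, and a disruption plan with eight penguin-stem loci (a 2-bp deletion
+ 2-bp insertion; single and double nonsense; a 10-bp deletion; a 2-bp
deletion near the 3' end; a 12-bp in-frame deletion with species-private
nonsense ahead of it; a 1-bp insertion) plus three independent non-penguin
terminal events. Absence probabilities are min(5/coverage, 0.25) per
species, mimicking coverage-dependent missingness of draft assemblies (24×
to 105×). The default substitution rate of 0.05/site per unit branch length
on a depth-1 ultrametric tree gives roughly 10% pairwise divergence between
the most distant species, a realistic order of magnitude for orthologous
avian *OR* coding sequences.

Numerical conventions worth knowing:

* substitutions operate in ancestral (root) coordinates; indels are stored
  as events and replayed at the tips, so a stem-branch indel is inherited
  identically by every descendant;
* background substitution never creates an in-frame stop (proposals are
  resampled) and never destroys an existing one, so planted nonsense codons
  survive; the start codon and terminal stop are exempt from substitution;
* planted nonsense codons are placed 5' of any same-lineage frameshifting
  indel — a stop planted in the ancestral frame downstream of a frameshift
  would not be a stop in the derived reading frame, by construction;
* inserted bases and the identity of planted stop codons are drawn once per
  branch, so shared events are byte-identical across carriers;
* everything is deterministic given the seed.

The simulator emulates clade structure, lineage-restricted disruptions and
coverage-dependent missingness. It does **not** emulate realistic OR
composition, codon usage, selection (dN/dS), gene conversion, duplication,
or alignment uncertainty from diverged flanks — so green tests demonstrate
that the inference chain is correct under its stated model, not that every
real-data failure mode is covered.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(sim = sim_config(seed = 42), grouping = "tree")
res <- run_pipeline(cfg)
res
```

The pipeline simulates the repertoire, filters intact genes, reconstructs a
bootstrapped NJ tree over all intact sequences (sequences from different
loci are far apart, so loci resolve as well-supported clades), extracts
ortholog groups, calls disruptions for every sequence of each analyzed
locus against the reference (preferring the northern fulmar, falling back
to the crested ibis — species whose sequences are intact for the planted
design), infers shared and ancestral losses, and tabulates the exact test.
With the default design the ancestral-loss set is the eight planted
penguin-stem loci (seven strict, one weak via the 12-bp in-frame deletion
rule) plus the three non-penguin terminal events.

Problem sizes used in the automated checks — a 310-codon reference, 500
noisy mutants for precision/recall, 100 seeded pipeline replicates, 200
random trees for the ortholog oracle — were chosen so the full suite
completes on a laptop in minutes while keeping every estimate's sampling
error well below the margins being asserted.

## Known limitations

* The family assignment (`assign_family()`) is a best-hit alignment against
  exemplars, a documented non-equivalent simplification of profile-HMM
  scanning; it reproduces the Class I (families 51–56, water-borne) vs
  Class II (1–14, air-borne) mapping but not HMM-based family calls.
* `find_shared_disruptions()` clusters positions by single linkage; with a
  nonzero tolerance, chains of nearby events can merge.
* Dollo placement is parsimony, not probabilistic ancestral-state
  reconstruction, and no dating of loss events is attempted.
* Sequencing error is indistinguishable from a true disruption at the level
  of this package; low-identity queries are flagged, not adjudicated.
* At high substitution divergence (~8–10%) the affine-gap alignment can,
  rarely, prefer a compensating short insertion+deletion pair over a dense
  run of chance mismatches, yielding a spurious frame-restored frameshift
  pair (about 2% of simulated whole-repertoire replicates contain one such
  observation). This is optimal-alignment behavior under the stated scoring,
  not a parsing defect; raising the gap penalties removes it at the cost of
  splitting genuine long indels.
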