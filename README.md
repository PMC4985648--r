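# orloss

Inference of lineage-specific **olfactory receptor (OR) gene loss** from
nucleotide sequences.

Olfactory receptor genes are single-exon genes encoding seven-transmembrane
odorant receptors. When a lineage relaxes its reliance on olfaction, *OR*
loci that stay intact in relatives accumulate ORF-disrupting mutations —
premature stop codons and frameshifting insertions/deletions — and
disruptions shared across species at homologous positions mark a single
pseudogenization event in their common ancestor. `orloss` implements the
complete inference chain for this kind of comparative study (the motivating
case: penguins against other core waterbirds), for users who have candidate
*OR* sequences, gene trees, and a species tree, and want reproducible
pseudogene calls, ancestral-loss placements, and the contingency statistics
that summarize them.

## What it computes

* **Intact-OR identification** — `find_orfs()` scans six frames for every
  maximal ATG-to-stop ORF; `filter_intact()` keeps ORFs strictly longer than
  250 aa with no deletion gap of ≥5 aa overlapping a transmembrane interval
  of the reference (global protein alignment, BLOSUM62).
* **One-to-one ortholog extraction** — `extract_ortholog_clades()` returns
  maximal clades with support > 85, at most one gene per species, and ≥4
  species; `build_gene_tree()` (NJ + site-resampling bootstrap) provides a
  self-contained tree builder for synthetic runs.
* **Pseudogene calling** — `call_disruptions()` globally aligns a query to
  an intact ortholog reference CDS (affine gaps), reports every
  frameshifting indel (left-normalized coordinates) and every premature stop
  read in the query's running frame, and classifies intact vs pseudogene.
  For a 2×2 table with margins fixed, `fisher_exact()` computes the exact
  two-sided p by log-space hypergeometric enumeration:
  p = Σ Pr(X = x) over all x with Pr(X = x) ≤ Pr(X = a), where
  Pr(X = x) = C(r₁, x)·C(r₂, c₁−x) / C(n, c₁).
* **Ancestral-loss inference** — `find_shared_disruptions()` matches
  disruptions across species by kind, length and reference codon;
  `infer_ancestral_loss()` places each shared disruptive signature on the
  stem branch of its carriers' MRCA (Dollo single-origin rule), with a
  separate weak-evidence flag for long shared in-frame deletions.
* **Family assignment** — `assign_family()` assigns an OR protein to a gene
  family by best exemplar alignment; families 51–56 are Class I
  (water-borne ligands), 1–14 Class II (air-borne).
* **Simulation** — `simulate_repertoire()` evolves OR-like repertoires along
  a species tree with planted branch-specific disruptions and known truth
  labels; `run_pipeline()` ties all stages together.

## A worked example

```r
library(orloss)

## the published-style contingency table: 18/54 penguin vs 3/102
## non-penguin pseudogene observations
f <- fisher_exact(c(18, 36, 3, 99))
f$p.value
#> [1] 3.242156e-07
round(100 * f$proportions, 1)
#> [1] 33.3  2.9

## full synthetic pipeline: 8 waterbird species, 29 loci, 8 penguin-stem
## disruptions, coverage-dependent absence
res <- run_pipeline(pipeline_config(sim = sim_config(seed = 42),
                                    grouping = "tree"))
res
#> OR gene-loss pipeline result
#>   sequences: 205 (188 intact); loci analyzed: 27
#>   penguin: 14/53 pseudogene (26.4%); waterbird: 1/147 (0.7%)
#>   Fisher exact p = 2.46e-08
#>   ancestral losses: OR4@penguins, OR13@penguins, OR3@penguins,
#>   OR25@penguins, OR7@penguins, OR19@penguins, OR9@penguins
```

The p-value on the printed table is far below 1e-4: the penguin group's
pseudogene fraction (33.3%) is significantly greater than the non-penguin
fraction (2.9%). In the synthetic run, seven of the eight planted
penguin-stem losses are recovered as ancestral calls (OR19 enters through
the weak-evidence rule for its shared 12-bp in-frame deletion); the eighth,
OR22, drops below the four-species ortholog criterion in this replicate
because simulated low-coverage absence removes three of its non-penguin
sequences — the same reason real surveys lose loci to incomplete draft
assemblies. The exact test still separates the groups decisively.

The methods vignette (`vignettes/or-gene-loss.Rmd`) documents the model,
parameter defaults, numerical conventions, and what the simulator does and
does not emulate.

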