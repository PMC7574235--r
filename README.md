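# famtrace

Charting birth-and-death evolution of a gene family — iterative
homology-based annotation, pseudogene classification, synteny locus
assignment, phylogenetics, and duplication/loss reconciliation, with a
ground-truth synthetic-genome simulator that makes every stage testable.

## What it does

Gene families like perforin-1 evolve by *birth and death*: copies arise by
(often tandem) duplication and die by deletion or pseudogenization —
diagnosable by premature in-frame stop codons and frameshifts.  Automatic
annotators routinely miss the interesting copies.  famtrace implements the
expert-style pipeline as tested components:

* **Translated search** (`translated_search`): seed-and-extend alignment of
  a seed protein against all six reading frames, BLOSUM62 with affine gaps
  (gap of length *L* costs `open + L·extend`); hits never cross in-frame
  stops, so the pseudogene signal survives to later stages.
* **Splice-aware gene models** (`cluster_hits`, `splice_align`): a dynamic
  program over (genome, query, codon-phase/intron state) that opens introns
  only at `GT..AG` (length ≥ `min_intron`, flat penalty, phases 0/1/2 with
  exact split-codon scoring), models frameshifts as penalized 1–2-base
  jumps, and traverses stop codons at a heavy cost so they are recorded,
  not hidden.
* **Classification** (`classify_status`): pseudogene iff the conceptual
  translation has an internal `*`, the parse needed a frameshift, or the
  terminal structure is missing (`truncated`); every cause is listed.
* **Iteration** (`iterate_annotation`): newly found functional paralogs are
  recycled as queries until no new model appears — the mechanism that
  recovers paralogs too diverged for the original seed.
* **Synteny** (`assign_locus`): loci labeled `"UP-DOWN"` by their nearest
  flanking neighbor genes, so conserved loci align across species and
  tandem amplifications group into one locus.
* **Phylogenetics** (`center_star_msa`, `trim_alignment`,
  `neighbor_joining`, `bootstrap_support`, `fitch_parsimony_score`):
  center-star MSA, curation-style trimming (gappy-row deletion, ragged-end
  removal, long internal gap runs → missing), NJ with bootstrap support and
  collapse below a cutoff (default 100 replicates, cutoff 50), Fitch
  parsimony with gaps as a 21st state.
* **Reconciliation** (`lca_reconcile`, `event_report`): classic LCA
  duplication-loss parsimony of a rooted gene tree against a strictly
  binary species tree, with per-branch event attribution.
* **Simulator** (`simulate_genome`, `simulate_family`,
  `plant_gene`, `pseudogenize`): synthetic contigs with planted multi-exon
  genes at controlled divergence, tandem clusters, marker-flanked loci,
  repeat insertions, pseudogenes, split-contig artifacts; and a
  birth-and-death process along a species tree with an exact event log.

`run_pipeline()` ties simulate → annotate → phylo → reconcile together;
`inst/scripts/famtrace.R` exposes the stages as shell subcommands
(`simulate`, `annotate`, `phylo`, `reconcile`, `run`, `report`).

## Worked example

Simulate a 60 kb genome with a tandem cluster of three copies plus one
singleton (identity 0.7–0.9 to the seed, one copy pseudogenized), then
annotate it from the seed protein alone:

```r
library(famtrace)
spec <- genome_spec(contig_lengths = c(chr1 = 60000L), n_singletons = 1L,
                    tandem_clusters = 3L, identity_range = c(0.7, 0.9),
                    pseudogene_fraction = 0.25, seed = 7L)
sim <- simulate_genome(spec)
ann <- iterate_annotation(sim$genome, c(seed = sim$seed_protein),
                          search_params(), model_params(max_intron = 5000L))
ann$iterations
#>   iteration n_queries n_new_models n_models
#> 1         1         1            4        4
#> 2         2         4            0        4
al <- assign_locus(ann$models, sim$neighbors)
```

The four planted genes are recovered with exact coordinates, status and
locus grouping (compare `sim$truth_table`):

```
chr1_m01  -    2882-  4851  5 exons  functional  MARKA-MARKB  score 2181
chr1_m02  +    5348-  7291  5 exons  functional  MARKA-MARKB  score 2159
chr1_m03  -    8064- 10069  5 exons  pseudogene  MARKA-MARKB  score 1954
chr1_m04  -   13345- 14920  2 exons  functional  MARKC-MARKD  score 2027
```

The pseudogene (`chr1_m03`, planted with a premature stop) is flagged with
its defect, and the three tandem copies share the `MARKA-MARKB` synteny
locus while the singleton sits alone at `MARKC-MARKD`:

```
        label upstream downstream n_members                    members
1 MARKA-MARKB    MARKA      MARKB         3 chr1_m01,chr1_m02,chr1_m03
2 MARKC-MARKD    MARKC      MARKD         1                   chr1_m04
```

From here, `center_star_msa()` + `bootstrap_support()` build the family
tree from the functional translations, and `lca_reconcile()` against a
species tree yields the per-branch duplication/loss table (`events.tsv` in
a `run_pipeline()` output directory).  See the methods vignette
(`vignettes/famtrace-methods.Rmd`) for the model, parameter rationale and
limitations.

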