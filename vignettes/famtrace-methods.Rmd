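---
title: "Methods: homology annotation and birth-and-death reconciliation in famtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homology annotation and birth-and-death reconciliation in famtrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Multi-copy gene families such as perforin-1 evolve by a birth-and-death
process: copies arise by (often tandem) duplication, diverge, and die by
deletion or pseudogenization.  Charting this history across genome
assemblies needs more than an off-the-shelf annotator, because the
interesting copies are precisely the ones automatic annotation misses:
diverged paralogs, pseudogenes with premature stops or frameshifts, and
fragments on short contigs.  famtrace implements the full chain as
reusable, tested components:

1. **Translated search** — align a seed protein against all six reading
   frames of each contig (`translated_search()`).
2. **Gene models** — cluster hits into candidate loci and refine each by a
   splice-aware dynamic program into an exon/intron model
   (`cluster_hits()`, `splice_align()`), then classify it as functional or
   pseudogene (`classify_status()`).
3. **Iteration** — recycle newly found functional paralogs as queries
   until no new model appears (`iterate_annotation()`).
4. **Synteny** — label loci by their flanking neighbor genes
   (`assign_locus()`), so conserved loci can be tracked across species.
5. **Phylogenetics** — align the family proteins, build a
   neighbor-joining tree with bootstrap support, optionally score trees by
   Fitch parsimony (`center_star_msa()`, `bootstrap_support()`,
   `fitch_parsimony_score()`).
6. **Reconciliation** — map the rooted gene tree onto the binary species
   tree by LCA mapping and count duplications and losses
   (`lca_reconcile()`, `event_report()`).

Everything is exercised on synthetic genomes with known ground truth
(`simulate_genome()`, `simulate_family()`), so each stage's recovery
behavior is measurable without downloading a single assembly.

## Translated search

The search is seed-and-extend.  Each frame translation is split at its
in-frame stop codons; stops therefore bound every reported hit.  This is a
deliberate choice rather than a limitation: in-frame stops are exactly the
pseudogene signal the downstream classifier must see, so a hit is never
scored "through" a stop.  Within a stop-free segment, any diagonal word of
`word_size` residues scoring at least `seed_threshold` (a neighborhood
seed — the word need not match exactly) triggers a gapped extension.  The
extension is an exact affine-gap local alignment over the segment,
windowed by the X-drop criterion: a gap run longer than
`(x_drop - |gap_open|)/|gap_extend|` columns would fall more than `x_drop`
below the running best, so the DP never needs to run further than
`query_length` plus that bound beyond the outermost seed.  Additional
hits in one segment are found by masking previously reported target
columns and re-running, so same-frame hits never overlap.

Scoring is BLOSUM62 with gap costs `open + L·extend` (defaults −11, −1),
matching common tblastn-style practice.  There are no E-values: candidate
selection downstream is score- and synteny-driven, and the raw-score floor
is configurable (`min_score`, default 50).  Default `seed_threshold` is
14; oracle-style exactness (agreement with full Smith–Waterman) is only
guaranteed when seeding is sensitive enough, so the verification suite
runs with `seed_threshold = 8`.

## Splice-aware gene models

`splice_align()` is the package's core dynamic program.  States are
(genome position, query position) at a codon boundary, plus affine-gap
states in both directions and intron states.  Introns open only at `GT`
and close only at `AG`, must be at least `min_intron` (40) bases long, and
cost a flat `intron_penalty`.  Introns may split codons (phase 1 and 2):
the DP carries one running-maximum channel per donor-side partial codon
(1 + 5 + 25 channels), so the split codon is scored exactly when the
intron closes.  Frameshifts are 1–2-base genomic jumps at
`frameshift_penalty` (−30).  In-frame stop codons are scored by a
`*`-overridden matrix row (`stop_score`, −15) — expensive enough never to
be preferred, cheap enough that a pseudogene parse traverses its stop and
records it.  Ties are broken toward fewer introns (intron transitions are
taken only on strict improvement) and deterministic transition order.

Two post-processing steps make model boundaries comparable with annotated
CDSs: if the optimal local parse stops short of the query ends (local
alignment trims mismatching termini), the outer exons are extended
ungapped codon-by-codon to cover the query, accepted only when the added
score stays above a small slack (25 matrix units) and no stop codon or
window edge intervenes; and a directly following in-frame stop codon is
absorbed into the last exon, as is conventional for CDS annotation.

**Why `intron_penalty = -12` and `min_model_score = 300`.**  These two
defaults balance against each other.  The intron penalty must be well
below the cost of reading through a short intron as a codon gap (a 60-base
intron read through as gaps costs about −31), otherwise chance alignments
inside diverged genes occasionally tip the parse into reading through a
real intron.  But a cheap intron lets the DP stitch unrelated low-scoring
background segments ("junk exons") into arbitrarily long chains: random
local segments in a multi-kilobase window score ~25–40 in matrix units,
more than one intron costs.  The model score floor is therefore the
mechanism that rejects background chains — a genuine family member at
even 60% identity over a few hundred residues scores on the order of a
thousand, two orders of magnitude above what background chains reach in
windows of the default size.  Both values are configuration fields, and
the candidate-locus windows are additionally clipped at the hit spans of
neighboring disjoint loci so a tandem neighbor can never be absorbed into
a parse.

A model is a pseudogene iff its conceptual translation contains a stop,
its parse required a frameshift, or it lacks the expected terminal
structure (no initial methionine or uncovered query start — reported as
`truncated`, which is also how assembly fragments surface).  Every cause
is listed, not just the first.

## Iteration and synteny

Iteration n searches with the seed queries plus the conceptual
translations of every functional model found so far.  Pseudogene products
are never recycled: their stops poison seeding and their inclusion would
let one mis-call cascade.  Convergence is judged after deduplication
(reciprocal CDS overlap > 50%, higher score wins), so rediscovering a
known gene never loops; the iteration cap (4 by default) is a safety
valve and hitting it is flagged.  Search results are cached per query
sequence, so re-running old queries is free.

Locus labels are `"UP-DOWN"` from the nearest non-family neighbor gene on
each side within `locus_max_distance` (1 Mb — conserved loci in this
problem are sub-megabase), `.` when a side is missing.  Tandem copies
share flanks and therefore a label, which groups them into one synteny
locus.

## Phylogenetics

Pairwise global alignment is delegated to Biostrings (Gotoh affine-gap);
the multiple alignment is center-star under "once a gap, always a gap",
with the center chosen to maximize summed pairwise score.  Trimming
mirrors standard manual curation: rows with more than `max_gap_fraction`
(0.5) gaps are deleted; leading/trailing columns with modal-residue
agreement below `end_agreement` (0.3) are removed; internal gap runs
longer than `gap_run` (20) columns become `?` (missing), reflecting
annotation uncertainty rather than true deletion.  The run-length rule is
a mechanical stand-in for what is expert judgment in manual work, and all
three thresholds are exposed.

Distances are p or Poisson (−ln(1−p)) over columns where neither row has
`-` or `?`; a saturated pair is capped just below 1 with a warning.  Trees
come from Saitou–Nei neighbor joining (exact on additive matrices), with
negative branch lengths clamped to zero and the unrooted result resolved
at the final join so it can be re-rooted on an outgroup
(`root_tree()`).  Bootstrap support resamples columns with replacement,
rebuilds the tree per replicate, and reports the percentage of replicates
containing each split of the full-data tree; splits under
`collapse_cutoff` (50, after the common bootstrap-collapse convention,
with 100 replicates by default) are collapsed to polytomies.  Fitch
parsimony treats the gap as a 21st character state and `?`/`X` as fully
ambiguous.  Bayesian or heuristic-search tree inference is deliberately
out of scope: the reconciliation stage consumes any rooted tree, and at
desk scale NJ plus bootstrap provides the topology and a support surface.

## Reconciliation

`lca_reconcile()` is the classic duplication-loss parsimony: each gene
node maps to the LCA of its children's images; a node is a duplication
iff its image equals a child's image; losses are the depth gaps minus the
one-edge discount per speciation child.  Losses are attributed to the
sibling species branches skipped along each path, so the per-branch table
(`event_report()`) sums exactly to the totals.  The species tree must be
strictly binary (`check_binary()` fails loudly on polytomies, which the
caller must resolve — the same constraint the underlying method has
always imposed).  Gene-tree rooting is taken as given; the pipeline roots
via a synthetic outgroup upstream.  Leaf-to-species mapping follows the
`Species_gene` naming convention with an explicit map as override.

## The synthetic-data generator

`simulate_genome()` plants, in i.i.d. background DNA at 42% GC, gene
copies reverse-translated (uniform synonymous codons — codon usage is
irrelevant to protein-level search) from a seed protein at controlled
identity, with 2–5 exons, introns of 60–300 bases (minimum 60 keeps GT/AG
detection unambiguous at desk scale), mixed intron phases (so the aligner
must handle codon-splitting junctions), tandem clusters, flanking marker
genes, repeat insertions (5%-mutated copies of a fixed repeat seed,
standing in for transposon-like elements), pseudogenized copies
(premature stop / frameshift / truncation), and optionally a gene cut at
an intron across two contigs (the assembly-break situation typical of
avian loci).  The default planted identity range is 0.6–0.9 to the seed;
divergence among real paralogs is not quantified in the literature this
emulates, so the range is a free, config-exposed choice.  The seed
protein itself is synthetic (`synthetic_seed_protein()`), a random
sequence carrying the two default screening motifs; it is labeled as
synthetic and is not a real perforin sequence.

What the generator does **not** emulate: indel evolution in background
DNA, codon-model sequence evolution, non-canonical splice sites (GC–AG),
overlapping genes, and assembly errors beyond the contig split.  Passing
recovery tests on these genomes therefore demonstrates algorithmic
correctness of the pipeline — search sensitivity at a given divergence,
exactness of the splice parses, status classification, event counting —
not performance on the full messiness of real assemblies.

`simulate_family()` runs a linear birth-and-death process (rates λ, μ per
lineage per unit branch length) down a binary species tree, logging every
event, and evolves leaf proteins by per-site Poisson substitution.  With
μ = 0 the true duplication count is exactly recoverable from the gene
tree, which the verification suite asserts; with μ > 0 parsimony is a
lower bound on both event counts.

## Problem sizes and determinism

The verification suite runs everything at desk scale, chosen so the whole
chain is measurable in minutes on one core: a 200 kb genome with 8
planted copies (two tandem clusters of three plus two singletons, one
premature-stop and one frameshift pseudogene) for recovery; queries of
20–40 residues against ≤ 2 kb for search-oracle equality over 50
instances; planted genes of ≤ 150 nt CDS with ≤ 2 introns for exhaustive
parse enumeration over 30 instances; 20 chained-paralog scenarios for the
iteration-gain property; 8-leaf additive matrices for NJ; all labeled
gene-tree shapes up to 4 leaves (plus sampled 5-leaf cases) against a
3-species tree for the reconciliation oracle; and 50 replicates per
birth-death setting.  For these runs `max_intron` is set to 5000 — the
simulated introns are two orders of magnitude shorter, and window size is
the dominant cost of the splice DP — while the package default stays at
20000, appropriate for vertebrate-scale introns.

All randomness flows from explicit seeds; generator functions restore the
caller's RNG state, and `run_pipeline()` derives per-stage seeds from a
single root seed, so two runs under one seed are byte-identical (the
suite checks this by hashing every output file).

## Known limitations

* The center-star MSA is O(n²) in sequence count and poorer than
  profile-based aligners on deep families; it is adequate for the family
  sizes this package targets (tens of sequences).
* The splice DP allocates traceback for the full window × query matrix
  (~170 MB at 45 kb × 550 residues); very long windows should be clipped
  via `max_intron`.
* Start-codon choice is "first M in the parse"; alternative starts and
  UTRs are out of scope, as is alternative splicing.
* Reconciliation does not rearrange weakly supported edges; support-aware
  rearrangement would need the collapsed tree plus a resolution search.
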