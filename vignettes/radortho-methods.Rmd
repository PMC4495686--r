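---
title: "Cross-laboratory RAD-seq orthology and phylogenetics: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-laboratory RAD-seq orthology and phylogenetics: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radortho)
```

## Scope and rationale

`radortho` identifies orthologous RAD loci across species from per-species
(optionally per-study) consensus locus sequences and estimates a phylogeny
from the interspecific single-nucleotide variation they contain. Consensus
RAD loci are short (tens of bp), essentially indel-free within the depths
that matter here, and sampled by a shared restriction enzyme — so orthology
inference can be reduced to carefully filtered sequence similarity, and the
dominant noise processes are restriction-site loss along lineages,
paralogy (especially in lineages with ancestral genome duplication), and
per-study technical dropout. Every design choice below follows from one of
those three.

## The simulator and what it emulates

`simulation_config()` + `simulate_dataset()` generate datasets in which the
truth is known, so the clustering and tree stages can be scored exactly.

* **Sequence evolution.** Ancestral loci are uniform random sequences of
  `locus_length` bp (default 60), prefixed by the post-cut remnant of the
  recognition site (`TGCAGG` for SbfI), evolved down the input newick tree
  under JC69 or K2P with branch lengths in expected substitutions/site.
  Substitutions are drawn per site per branch from the exact transition
  probabilities, so closed-form identities (e.g. expected pairwise identity
  $1 - \tfrac{3}{4}(1 - e^{-4d/3})$ under JC69) hold and are tested.
* **Restriction-site loss** is an absorbing per-branch event with
  probability $1 - e^{-\lambda b}$ ($\lambda$ = `site_loss_rate`, $b$ =
  branch length); a locus is absent from every leaf below the loss. Regain
  is not modelled — at realistic rates it is second-order, and loss is the
  process that drives the observed decay of shared loci with divergence.
  No published estimate pins this turnover rate for the data regime we
  emulate, so the default (0.5 per unit branch length) is an explicit free
  parameter: at salmonid-scale tree lengths it removes a few percent of
  loci, at teleost scale tens of percent.
* **Paralogs.** A fraction of ancestral loci (default 0.05) is duplicated
  at the root with `paralog_extra_divergence` (default 0.05) of extra
  distance, then evolved down the tree alongside the parent and emitted in
  the same species under independent ids. This is deliberately the hard
  case for the pipeline: young paralogs that pass alignment thresholds must
  be caught by the uniqueness and multi-cluster filters.
* **Studies.** Each species' surviving locus set is replicated into
  `n_studies_per_species` study files, each independently dropping loci at
  `study_dropout_rate` — the technical component of missingness, as opposed
  to the biological component from site loss.
* **Reproducibility.** Each stage (ancestral draw/evolution, site loss,
  paralog duplication, study replication) runs on its own stream derived
  from the master seed by fixed small offsets, so identical configs produce
  byte-identical FASTA output and individual stages can be varied without
  perturbing the others.

What the simulator does **not** reproduce: coalescent gene-tree/species-tree
discordance, methylation-sensitive digestion, read-level error (inputs are
population consensus sequences), base-composition and rate heterogeneity,
and genomic context (repeats are exercised through explicit fixtures, not
emergent repeat landscapes). Passing tests on synthetic data therefore
demonstrate the correctness of the inference machinery under the stated
generative model, not robustness to every artefact of real libraries.

## Preprocessing

* **Trimming** keeps each locus's first `target_length` bases (default 60)
  so alignment statistics are comparable across studies with different read
  lengths; shorter loci are dropped and counted. Trimming twice is a no-op.
* **Low-complexity masking** is DUST-style: within every sliding window
  (default 12 bp over these short loci) the triplet-count score
  $\sum_t c_t(c_t-1)/2 / (w-3)$ is compared to a threshold (default 2, the
  classic DUST cut-off); every base of any window above threshold is
  masked. Masking annotates — sequence letters never change — and masked
  bases are excluded from alignment *seeding* only, mirroring how masked
  databases suppress spurious seeds without forbidding aligned extension.
  Lowering the threshold can only grow the mask (tested property).
* **Repeat-library masking** marks bases covered by any ≥ 18 bp window of a
  user library matching with ≤ 2 mismatches on either strand. It is a
  deliberately simple exhaustive matcher adequate for compact libraries,
  not a general repeat annotator.
* **Within-species merging** compares loci across studies over the full
  trimmed length on either strand, requiring identity ≥ 0.95 **and**
  mismatches ≤ 2 (both enforced as stated, although at 60 bp the mismatch
  bound is the binding one). Full-length comparison rather than local
  alignment is a deliberate choice: loci are already equal-length and
  near indel-free, so a local aligner would only add free parameters.
  Groups are maximal cliques of the match graph; a locus belonging to two
  incompatible groups (two maximal cliques) is ambiguous and excluded with
  a log entry. A group becomes a common locus when it spans at least
  `min_studies` studies — default a majority of the studies present, since
  no principled universal threshold exists; the representative sequence
  comes from the lexicographically first study (a pure tie-break). The
  sharing percentage is reported relative to the smallest study, the
  convention that makes cross-study overlap comparable.

## Alignment and hit filtering

The cross-species search is a seeded local aligner: candidate pairs must
share at least one exact, unmasked, N-free k-mer (default k = 11, the
classic nucleotide-search word size) on either strand; candidates are then
aligned with affine-gap Smith–Waterman scoring (+1 match, −2 mismatch, gap
of length $g$ costing $5 + 2g$), and hits scoring below 20 are suppressed.
On random 60-mers the best local score between unrelated loci stays well
below 20, so the floor separates signal from noise rather than tuning
sensitivity; the seeded search is verified against an exhaustive
Smith–Waterman oracle in the test suite. Significance ranking uses the raw
score: it is monotone in everything the thresholds filter on and exactly
deterministic, which database-size-dependent statistics are not.

Per query and subject species the best hit is kept (ties: higher identity,
longer alignment, lexicographically smaller subject — all deterministic),
then filtered by the preset thresholds:

| preset | identity | alignment length | mismatches |
|---|---|---|---|
| strict | ≥ 0.95 | ≥ 50 bp | ≤ 2 |
| relaxed | ≥ 0.85 | ≥ 45 bp | ≤ 10 |

Identity is $(\mathrm{len} - \mathrm{mm} - \mathrm{gaps})/\mathrm{len}$;
gap columns count against identity but not against the mismatch count
(mismatch = substitution columns only), a convention the short, near
indel-free loci make essentially consequence-free, and which is recorded
because gapped-hit accounting is otherwise ambiguous. Strict output is
provably nested inside relaxed output (tested). Finally, any subject that
is the best hit of two or more queries within a directed species pair is
removed with all its hits — multi-hit subjects are the signature of repeats
and of paralogous regions in duplicated genomes.

## Cluster inference and filters

Reciprocal unique best hits define an undirected graph. The default reading
of "every member is every other member's unique best match" is **maximal
cliques** (cliques automatically contain at most one locus per species,
because hits never join conspecific loci); connected components are exposed
as an alternative mode for sensitivity analysis, since the two readings
differ exactly on incomplete reciprocity, and the package reports both
rather than declaring one canonical. Filters then run in a fixed order:
clusters sharing any locus with another cluster are removed whole (the
paralogy guard — two cliques overlapping in one locus are both removed,
never arbitrated by score); clusters with two members in one species are
removed; and clusters below `min_species` coverage, or failing a
species-group constraint (e.g. "at least one non-salmonid member", used to
drop lineage-specific clusters), are removed. Cluster counts are monotone
non-increasing in `min_species` (tested), and member orientation is fixed
relative to the lexicographically smallest member by propagating hit
strands.

## Variant supermatrix

Cluster members are re-oriented and multiply aligned by center-star (center
= member minimising summed pairwise distance; ties by id). For equal-length
members the alignment is exactly the columnwise stacking; when an indel is
present the merged alignment's sum-of-pairs cost is checked against the
exact three-sequence dynamic program in tests. Center-star rather than a
progressive heuristic is sufficient *because* the loci are short and
near indel-free — this is the one place the data regime buys real
simplification.

A column is a **variant** iff at least two species have data (gap and N
count as missing) and at least two distinct bases occur among them. A
column with one base and everything else missing carries no between-species
information, hence the ≥ 2 rule; sites with three or four alleles are
retained, since nothing in the analysis requires biallelism. Gap-as-missing
is the default (configurable in principle to gap-as-state, but with ~0
indels the choice is inert). Species absent from a cluster receive `N` at
that cluster's columns — the matrix analogue of padding absent species with
a string of N's. Columns are ordered by (cluster id, column index), with a
provenance map from every matrix column back to its cluster and column, so
the matrix is reproducible and auditable. Export is **relaxed sequential
PHYLIP** (`"<n> <sites>"` header, whitespace-separated name and sequence):
strict 10-character names would force truncation collisions among species
names; the writer round-trips through the bundled reader bit-exactly.

## Tree inference

The internal tree builder is distance-based by design: the package's claim
is pipeline-level topology recovery, and variant-only matrices require
ascertainment-aware likelihoods that belong in dedicated ML software — the
PHYLIP export is the hand-off point. Distances use **pairwise deletion**
(complete-case deletion would throw away exactly the missing-rich rows the
coverage thresholds deliberately retain); p-distance is the default because
variant-only sites are strongly ascertained and the JC69 correction of an
inflated p is not more interpretable (JC69, $d = -\tfrac{3}{4}\ln(1-4p/3)$,
is available and errors loudly at saturation $p \ge 0.75$ or zero shared
columns, naming the offending pair). Neighbor joining (via ape) clamps
negative branch lengths to zero and logs the clamped total. Bootstrap
resamples matrix columns with replacement (default 1,000 replicates,
seeded); support is the percentage of replicate trees containing each
internal bipartition of the point tree, with failed replicates (saturated
or disconnected resamples) excluded from the denominator and counted.
Branch lengths are in substitutions/site on the variant-only scale and are
inflated relative to genome-wide divergence; topology and support are the
outputs to interpret. Robinson–Foulds distance (`compare_topologies()`)
operationalises "same topology" as RF = 0.

## Problem sizes used in validation

The test suite validates on: 500-locus five-taxon zero-divergence datasets
(exact recovery), 2,000-locus two-taxon datasets (closed-form identity
within 3 standard errors), 200 random ≤ 15-node RBH graphs against
brute-force subset enumeration, a 50-locus aligner fixture against
exhaustive Smith–Waterman, 150-locus six-taxon ladder trees over 10 seeds
(dropout monotonicity), and 500-locus ten-taxon trees over 10 seeds
(topology recovery, RF = 0 in ≥ 9/10). The ten-taxon validation tree has
maximum pairwise path length ≈ 0.10 substitutions/site — moderate
divergence where the relaxed thresholds (≤ 10 mismatches over 60 bp ≈ 0.17)
retain most true pairs while site loss and threshold attrition still
produce realistic missingness; the five-taxon tree (max path ≈ 0.025) sits
inside the strict regime the strict preset targets.

## Known limitations

* Orthology is similarity-based; no synteny or tree-aware (reconciliation)
  evidence is used, so deep paralogy that survives the uniqueness and
  multi-cluster filters is undetectable in principle.
* The genic-annotation significance is a Karlin–Altschul-style scaling of
  the raw local score with fixed documented constants (nucleotide
  λ = 1.33, K = 0.621; translated λ = 0.267, K = 0.041 with BLOSUM62).
  It makes a threshold reproducible *within this tool*; it is not
  calibrated against any external search program's E-values.
* The translated search mode compares all 6 × 6 reading-frame pairs with
  4-residue seeds — adequate for flagging conserved coding sequence,
  not a general protein homology search.
* Divergence times are out of scope; branch lengths of the internal tree
  are not calibrated quantities.
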