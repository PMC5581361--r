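---
title: "Methods: DTL reconciliation and the HGT-index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DTL reconciliation and the HGT-index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hgtindex)
```

This vignette documents the model the package implements, the decisions taken
where the design was genuinely open, and what the simulation-based tests do
and do not establish.

## The reconciliation model

A gene family's history is reconstructed by embedding its gene tree *G* into
a rooted reference species tree *S*. Topological conflict between the two is
explained by three event types — duplication (D), horizontal transfer (T) and
loss (L) — and the maximum-parsimony reconciliation minimises the total
weighted event cost. The package implements the *undated* variant: species
nodes carry no absolute times, a transfer may connect any two species
lineages that are **incomparable** (neither an ancestor of the other), and no
global time-consistency constraint is imposed across transfers. This matches
the behaviour of the standard undated DTL reconciliation tools; it can in
principle accept sets of transfers with no consistent joint timing, a known
and accepted property of the undated model.

The dynamic program fills three tables over gene node *g* and species node
*s*:

* `c(g, s)` — cheapest reconciliation of the gene subtree at *g* with *g*
  mapped exactly at *s*. For a gene leaf, 0 at its genome's leaf and infinite
  elsewhere. For an internal *g* with children *g′*, *g″*:
  * speciation (internal *s* with children *s₁*, *s₂* only):
    `min(in(g′,s₁) + in(g″,s₂), in(g′,s₂) + in(g″,s₁))`;
  * duplication: `D + in(g′,s) + in(g″,s)`;
  * transfer: `T + min(in(g′,s) + out(g″,s), in(g″,s) + out(g′,s))`;
  and `c(g,s)` is the minimum of the three.
* `in(g, s) = min(c(g,s), L + in(g,s₁), L + in(g,s₂))` — enter the species
  tree at *s*, map at or below it, paying one loss per step down.
* `out(g, s)` — minimum of `in(g, s′)` over all *s′* incomparable to *s*
  (the transfer recipient is a free choice, so an optimal reconciliation
  never pays losses on the transferred side: it can take the recipient equal
  to the child's own mapping).

The optimum is `min over s of c(root(G), s)`. Backtracking recovers one
optimal event history; the recomputed cost `D·n_dup + T·n_transfer +
L·n_loss` is asserted against the table optimum on every run, and every
reported transfer's donor/recipient pair is asserted incomparable.

Both trees must be rooted and binary. The species tree arrives rooted (or is
rooted with `root_with_outgroup()`, mirroring the usual practice of rooting a
16S rRNA reference tree with a distant outgroup such as a eukaryotic 18S
sequence); unrooted *gene* trees are handled by evaluating the rooted optimum
for every possible root edge — `2n − 3` rootings for *n* leaves — and keeping
the cheapest.

### Per-gene-set reference trees

Each gene set is reconciled against the species tree **restricted to its
member genomes** (`ape::keep.tip`), not the full genome panel. This mirrors
how reference trees are built in practice (one 16S tree per orthologous set,
from the member genomes' sequences) and is required for the statistic to make
sense: reconciling a 10-genome gene tree against a 2,000-genome reference
would charge thousands of spurious losses for genomes where the gene was
never observed, and parsimony would occasionally convert runs of such losses
into fictitious transfers. With the restriction, a gene tree congruent with
the species tree always reconciles at cost zero.

### Determinism and ties

Equally parsimonious reconciliations are common, and the package does not
enumerate them. Instead every choice point has a fixed preference order —
speciation over duplication over transfer, then the smallest species
postorder index for mappings and recipients, the smallest canonical edge
index among tied rootings, and stopping early (fewer losses) along `in()`
chains — so the same input always yields the same output, and the result
carries a `ties` flag recording whether any alternative optimum was
encountered. Cost comparisons use an absolute tolerance of 1e-9 (costs are
user-supplied reals); the backtrack/table consistency assertion uses 1e-6.

### Event costs

Defaults are D = 2, T = 3, L = 1, the long-standing defaults of the
reconciliation tools this stage emulates; no published costs accompany the
corpus this package's statistic comes from, so the costs are exposed as
configuration (`dtl_costs()`) and the optimum is reported with its event
decomposition. The optimal cost is non-decreasing in each cost parameter, a
property the test suite checks on seeded random instances.

## The HGT-index and gene-set bookkeeping

For each gene set, `HGT-index = n_transfers / n_genomes`. The index is kept
at full precision internally and rounded to 3 decimals in reports; summary
percentages are rounded to the nearest integer. For one-gene-per-genome sets
the index is bounded by (n−1)/n < 1.

Exclusion filters run in a fixed order — `single_species`, `zero_distance`,
`min_taxa`, `max_fraction` — and the first failure is reported:

* **single_species** — all member genes map to one genome (or, when genome
  metadata with a `species` column is supplied, one species). No conflict is
  measurable within a single taxon.
* **zero_distance** — every pairwise patristic distance on the gene tree is
  below `zero_distance_epsilon` (default 1e-6): the tree carries no signal.
  The source corpus screened on "near-zero pairwise NJ distances" without
  specifying whether these were alignment or tree distances; patristic
  distances on the gene tree are used here as the closest tree-level
  equivalent, with the threshold configurable. Trees without branch lengths
  skip this screen with a warning (the reconciliation itself is purely
  topological).
* **min_taxa** — fewer than `min_taxa` (default 10) genomes. The source
  descriptions of this threshold are mutually inconsistent (exclusion of
  sets with "<10 genomes" vs retention of sets with ">10"); the inclusive
  reading — keep n ≥ 10 — is adopted because small sets make the index
  incomparable across genes (two transfers among four genomes already give
  0.5). Configurable.
* **max_fraction** — strictly more than `max_genome_fraction` (default 0.5)
  of `total_available_genomes` (default 2,472, the size of the corpus the
  statistic was introduced on; the pipeline resets it to the species tree's
  leaf count). Exactly 50% is kept.

Included sets with at least one inferred transfer are **HGT-genes**; with
zero transfers, **HGT-free**. Excluded sets are `not_applicable`. Summary
percentages use the documented denominators: exclusions as a share of all
sets, HGT-gene/HGT-free as shares of the retained sets.

## Annotation summaries

Pfam families are assigned to a gene set by the 80% majority rule: every
family carried by at least `threshold` (default 0.8) of the member genes is
assigned, so multi-domain sets can receive several families. The denominator
is *all* member genes by default — the rule is stated over the proteins of
the gene set, not over the annotated ones — with `denominator = "annotated"`
available.

GO biological-process keyword counts use case-insensitive substring matching
of each keyword against each term-name occurrence, with one exception:
keywords shorter than 5 characters (e.g. "rRNA") require a whole-token match,
so "rRNA" does not count "tRNA processing". A term occurrence contributes at
most once per keyword but may hit several keywords; duplicate term
occurrences count separately (the published counts are word tallies, and
whether they deduplicated terms is not recoverable — occurrences were
adopted). Absolute keyword counts depend entirely on the annotation snapshot
supplied and are not comparable across annotation sources.

## The synthetic-data generator

The generator stands in for a database-scale corpus of orthologous gene sets
with precomputed reference trees. It emulates the structure of that input —
one rooted reference tree over N genomes, per-set genome subsamples, one gene
per genome, known transfer conflict — not its biology:

* **Species tree**: Yule (pure-birth) topology, built by repeatedly splitting
  a uniformly chosen tip; i.i.d. exponential branch lengths with mean 0.1
  substitutions/site (the scale typical of 16S trees). Deterministic under a
  seed.
* **Transfers**: `k` subtree-prune-and-regraft (SPR) edits on the gene tree;
  an SPR is exactly the topological footprint one transfer leaves, so the
  edit log is exact ground truth with no rate calibration. Edits are
  constrained to be **incomparable** (pruned clade vs regraft target) and
  **independent** — the moved clades and regraft targets of all k edits have
  pairwise disjoint leaf sets. Independence matters: interacting edits (one
  regrafting inside another's moved clade) can compound into topologies
  whose cheapest explanation needs *more* than k transfers, destroying the
  edit count as ground truth. With `deep = TRUE`, both endpoints must also
  lie at least two nodes below their most recent common ancestor, which
  excludes topology-neutral sibling regrafts and makes a single edit
  reliably recoverable. When a tree is too small to host the requested
  number of independent (deep) edits, the generator raises an error rather
  than degrading these guarantees.
* **Leaf duplications/losses** can be implanted at configurable rates
  (default 0); they are logged but deliberately excluded from
  transfer-recovery ground truth.
* **Annotations/metadata**: one synthetic Pfam family per set carried by a
  configurable fraction (default 0.9) of genes; GO terms drawn from a fixed
  vocabulary containing the keyword panel; genomes partitioned into five
  named phyla.

Defaults — 40 genomes, 20 gene sets, per-set sizes uniform on [10, 20], one
deep transfer per set — are chosen so that simulated sets pass the default
filters (sizes at least the min-taxa threshold and at most half the panel)
and each pipeline stage is exercised. What passing tests on this generator
show is that the *inference machinery* is correct: the dynamic program
matches brute-force enumeration, implanted signal is recovered, bookkeeping
is exact. What they do not show is robustness to everything the generator
omits: alignment and tree-inference error, rate heterogeneity, incomplete
orthology, within-species transfer that leaves no topological trace, or
interacting/overlapping transfer histories.

## Numerical and degenerate-input choices

* Newick labels are taken verbatim (no quoting or underscore conventions) so
  they match mapping tables byte-for-byte; square-bracket comments are
  stripped; duplicate labels and negative branch lengths are rejected at
  parse time.
* Rooted multifurcations are resolved deterministically left-to-right into a
  caterpillar with zero-length edges (`binarize()`); `(A,B,C)` becomes
  `((A,B),C)`. Zero-length edges leave patristic distances unchanged, and
  the resolution is logged via a warning in the pipeline.
* A basal trifurcation is flagged unrooted per newick convention; a
  binary-rooted newick can be forced unrooted with `rooted_hint = FALSE`, in
  which case its arbitrary root is discarded before rooting enumeration.
* All-zero event costs are legal and give optimum 0; an untotal gene-genome
  map is an error, not an infinite-cost result.

## Problem sizes used by the test suite

Brute-force oracle comparisons enumerate all species-node assignments for
trees of up to 6 leaves (200 seeded instances). Transfer recovery uses a
40-genome species tree with 100 single-edit replicates and 10 replicates per
k in 0..3. Rooting consistency is checked exhaustively for unrooted gene
trees of up to 8 leaves against an independent re-rooting implementation
(phytools). Pipeline partition/determinism properties run on a 20-set
bundle. These sizes keep the full suite within a couple of minutes on one
CPU while covering every code path; the engine itself handles trees one to
two orders of magnitude larger.

## Known limitations

* One optimal reconciliation is reported, not the (often large) space of
  optima; the `ties` flag only records that alternatives existed.
* The undated model does not check time-consistency across transfers.
* The HGT-index is not normalised for the phylogenetic diversity or tree
  length of the gene set, so indices are most comparable between sets of
  similar breadth; sets spanning few, closely related genomes can understate
  transfer activity that leaves no topological conflict.
* Unrooted gene-tree reconciliation re-runs the full dynamic program per
  rooting (O(n) rootings); for very large unrooted trees this is the
  dominant cost.
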