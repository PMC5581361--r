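# hgtindex

Genome-wide detection of horizontal gene transfer (HGT) by explicit
phylogenetic conflict: orthologous gene trees are reconciled against a rooted
reference species tree under the undated duplication–transfer–loss (DTL)
maximum-parsimony model, and each gene set is summarised by an **HGT-index**

```
HGT-index = n_transfers / n_genomes
```

the number of inferred transfer events on the gene tree divided by the number
of member genomes (taxa). An index of 0 means no detectable gene/species tree
conflict ("HGT-free"); values approach but never reach 1 for one-gene-per-
genome sets, since a gene tree with *n* leaves has at most *n − 1* internal
nodes at which a transfer can be inferred. The package is aimed at
microbiologists and evolutionary genomicists who want a self-contained,
reproducible implementation of this pipeline stage — for ranking genes by
transfer propensity (antibiotic-resistance surveillance, marker-gene
selection for trees of life) — without a database-scale corpus.

## What is inside

* **Reconciliation** (`reconcile_dtl()`): the undated DTL dynamic program
  over cost tables `c(g,s)`, `in(g,s)`, `out(g,s)` with configurable event
  costs (defaults D = 2, T = 3, L = 1), deterministic backtracking of one
  optimal event history, a tie flag, and exhaustive edge-rooting for unrooted
  gene trees (`reconcile_unrooted()`). Results support `tidy()`, `glance()`
  and a TSV report.
* **Tree handling** (`parse_newick()`, `root_with_outgroup()`, `binarize()`,
  `patristic_distances()`): newick I/O via ape with strict validation,
  outgroup rooting of the reference tree, deterministic polytomy resolution,
  and the patristic-distance screen.
* **Statistics and bookkeeping** (`compute_hgt_index()`, `apply_filters()`,
  `classify_hgt()`, `rank_records()`, `summarize_run()`): exclusion filters
  (single species, all-zero distances, fewer than 10 genomes, more than 50%
  of available genomes), HGT-gene / HGT-free classification, top-k tables and
  run summaries.
* **Annotation** (`assign_pfam_majority()`, `count_keywords()`,
  `aggregate_phyla()`): 80% majority-rule Pfam assignment and GO
  biological-process keyword counts over the HGT-gene lists.
* **Simulation** (`simulate_species_tree()`,
  `simulate_gene_tree_with_transfers()`, `simulate_collection()`): Yule
  species trees and gene trees carrying a known number of independent,
  logged transfer edits, so every stage is testable against ground truth.
* **Pipeline** (`run_hgt_pipeline()`): bundle in, per-gene-set records,
  HGT-gene/HGT-free/excluded lists, top-k tables, keyword counts and summary
  out; per-set error quarantine; fully deterministic. A thin CLI wrapper with
  `simulate` / `reconcile` / `index` / `summarize` subcommands is installed
  at `inst/cli/hgtpipe.R`.

## Worked example

```r
library(hgtindex)

cfg <- simulation_config(n_genomes = 40, n_gene_sets = 20,
                         transfers_per_set = rep(c(0, 1, 2, 0, 1), 4), seed = 42)
simulate_collection(cfg, "demo_bundle")
run <- run_hgt_pipeline(bundle_dir = "demo_bundle")
run
#> HGT-index pipeline run
#>   gene sets: 20 (0 excluded [0%], 20 included, 0 errored)
#>   included: 12 HGT-genes (60%), 8 HGT-free (40%)

head(run$top_by_index[, c("gene_set_id", "n_genomes", "n_transfers",
                          "hgt_index", "pfam_ids")], 5)
#>   gene_set_id n_genomes n_transfers hgt_index pfam_ids
#> 1 set013             10           2    0.2    PF12517
#> 2 set018             10           2    0.2    PF32726
#> 3 set008             12           2    0.167  PF48807
#> 4 set003             20           2    0.1    PF39836
#> 5 set005             11           1    0.0909 PF09023
```

Twenty simulated gene sets were reconciled against the 40-genome reference
tree; the 8 sets simulated without transfers all come out HGT-free (zero
reconciliation cost), and no set's inferred transfer count exceeds its
implanted count. The top table ranks gene sets by HGT-index — e.g. `set013`
has 2 inferred transfers among 10 genomes, index 2/10 = 0.2 — with the
synthetic Pfam family assigned to each set by the 80% majority rule.
`run$keyword_counts` tallies GO biological-process keyword occurrences
(metabolic, transport, transcription, ...) over the HGT-genes' annotations.

A single reconciliation:

```r
sp  <- parse_newick("((A,B),C);")
gn  <- parse_newick("((a,c),b);")
rec <- reconcile_dtl(gn, sp, c(a = "A", b = "B", c = "C"))
glance(rec)
#>   cost n_duplication n_transfer n_loss ties  rooting_edge
#> 1    3             0          1      0 FALSE           NA
```

The cheapest explanation of the `((a,c),b)` vs `((A,B),C)` conflict is a
single transfer (cost 3 under the default costs), donor lineage A, recipient
C.

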