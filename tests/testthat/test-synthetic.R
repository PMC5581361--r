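test_that("simulated species trees are rooted, binary, labelled and seeded", {
  tr <- simulate_species_tree(5, seed = 1)
  expect_equal(length(tr$tip.label), 5L)
  expect_equal(tr$Nnode, 4L)
  expect_true(ape::is.binary.phylo(tr))
  expect_true(is_rooted_tree(tr))
  expect_true(all(grepl("^G[0-9]{4}$", tr$tip.label)))
  expect_true(all(tr$edge.length >= 0))

  # determinism: identical seeds give identical newick strings
  expect_identical(write_newick(simulate_species_tree(12, seed = 7)),
                   write_newick(simulate_species_tree(12, seed = 7)))
  expect_false(identical(write_newick(simulate_species_tree(12, seed = 7)),
                         write_newick(simulate_species_tree(12, seed = 8))))

  t3 <- simulate_species_tree(3, seed = 2)
  expect_equal(t3$Nnode, 2L)  # exactly one cherry plus the outer leaf
  expect_error(simulate_species_tree(2), ">= 3")
})

test_that("k = 0 gene trees are congruent restrictions of the species tree", {
  sp <- simulate_species_tree(14, seed = 21)
  sim <- simulate_gene_tree_with_transfers(sp, k = 0, seed = 22)
  ref <- ape::keep.tip(sp, sp$tip.label)
  ref$tip.label <- paste0("g_", ref$tip.label)
  expect_true(isTRUE(ape::all.equal.phylo(sim$tree, ref, use.edge.length = FALSE)))
  rec <- reconcile_dtl(sim$tree, sp,
                       stats::setNames(sim$map$genome_id, sim$map$gene_id))
  expect_equal(rec$cost, 0)
  expect_equal(rec$n_transfer, 0L)

  subs <- sample(sp$tip.label, 8)
  sim2 <- simulate_gene_tree_with_transfers(sp, subs, k = 0, seed = 23)
  expect_setequal(sim2$map$genome_id, subs)
  rec2 <- reconcile_dtl(sim2$tree, ape::keep.tip(sp, subs),
                        stats::setNames(sim2$map$genome_id, sim2$map$gene_id))
  expect_equal(rec2$cost, 0)
})

test_that("implanted transfers are logged and recoverable", {
  sp <- simulate_species_tree(25, seed = 51)
  sim <- simulate_gene_tree_with_transfers(sp, k = 3, seed = 52, deep = TRUE)
  expect_length(sim$truth$events, 3L)
  expect_equal(sim$truth$k_implanted, 3L)
  for (ev in sim$truth$events) {
    # donor and recipient clades are disjoint at application time
    expect_length(intersect(ev$donor_genomes, ev$recipient_genomes), 0)
  }
  # parsimony never infers more transfers than were implanted
  for (k in 0:3) {
    for (s in 1:5) {
      simk <- simulate_gene_tree_with_transfers(sp, k = k, seed = 600 + 10 * k + s,
                                                deep = TRUE)
      rec <- reconcile_dtl(simk$tree, sp,
                           stats::setNames(simk$map$genome_id, simk$map$gene_id))
      expect_lte(rec$n_transfer, k)
    }
  }
  # a single deep transfer is recovered exactly
  hits <- vapply(1:20, function(s) {
    sim1 <- simulate_gene_tree_with_transfers(sp, k = 1, seed = 700 + s, deep = TRUE)
    rec <- reconcile_dtl(sim1$tree, sp,
                         stats::setNames(sim1$map$genome_id, sim1$map$gene_id))
    rec$n_transfer
  }, numeric(1))
  expect_gte(mean(hits == 1), 0.95)
})

test_that("collections are byte-identical under a fixed configuration", {
  cfg <- simulation_config(n_genomes = 15, n_gene_sets = 4,
                           transfers_per_set = c(0, 1, 1, 2), seed = 33,
                           set_size_range = c(8, 12),
                           n_single_genome_sets = 1, n_zero_length_sets = 1)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- simulate_collection(cfg, d1)
  m2 <- simulate_collection(cfg, d2)
  expect_identical(m1, m2)
  files <- c("species.nwk", "manifest.tsv", "mapping.tsv", "annotations.tsv",
             "metadata.tsv", "truth.json",
             file.path("genesets", paste0(m1$gene_set_id, ".nwk")))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  expect_equal(nrow(m1), 6L)  # 4 regular + 2 designed fixture sets
  expect_equal(m1$k_implanted[1:4], c(0L, 1L, 1L, 2L))
})
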