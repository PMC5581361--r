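test_that("HGT-index arithmetic matches published per-gene values", {
  expect_equal(round(compute_hgt_index(153, 191), 3), 0.801)
  expect_equal(round(compute_hgt_index(245, 915), 3), 0.268)
  expect_equal(round(compute_hgt_index(20, 28), 3), 0.714)
  expect_equal(compute_hgt_index(0, 57), 0)
  expect_error(compute_hgt_index(3, 0), "n_genomes")
  expect_error(compute_hgt_index(-1, 5), "n_transfers")
  # vectorised, exact pre-rounding identity
  nt <- c(0L, 5L, 17L); ng <- c(12L, 40L, 33L)
  expect_equal(compute_hgt_index(nt, ng) * ng, as.numeric(nt))
})

test_that("index stays below one for one-gene-per-genome sets", {
  sp <- simulate_species_tree(15, seed = 9)
  for (k in 0:4) {
    sim <- simulate_gene_tree_with_transfers(sp, k = k, seed = 400 + k)
    rec <- reconcile_dtl(sim$tree, sp,
                         stats::setNames(sim$map$genome_id, sim$map$gene_id))
    idx <- compute_hgt_index(rec$n_transfer, length(unique(sim$map$genome_id)))
    expect_lt(idx, 1)
  }
})

make_set <- function(n, single_genome = FALSE, zero_len = FALSE) {
  tr <- ape::rtree(n, tip.label = paste0("g", seq_len(n)))
  if (zero_len) tr$edge.length <- rep(0, length(tr$edge.length))
  genomes <- if (single_genome) rep("G1", n) else paste0("G", seq_len(n))
  list(tree = tr, map = stats::setNames(genomes, tr$tip.label))
}

test_that("filters fire in the documented order with the documented thresholds", {
  cfg <- hgt_filter_config()
  s9 <- make_set(9)
  expect_equal(apply_filters(s9$tree, s9$map, cfg), "excluded:min_taxa")

  s10 <- make_set(10)
  expect_equal(apply_filters(s10$tree, s10$map, cfg), "included")

  big <- make_set(1250)
  expect_equal(apply_filters(big$tree, big$map, cfg), "excluded:max_fraction")
  # exactly 50% of available genomes is kept (strict comparison)
  edge <- make_set(1236)
  expect_equal(apply_filters(edge$tree, edge$map, cfg), "included")

  z12 <- make_set(12, zero_len = TRUE)
  expect_equal(apply_filters(z12$tree, z12$map, cfg), "excluded:zero_distance")

  # single-species precedes min_taxa for a 5-genome single-species set
  s5 <- make_set(5, single_genome = TRUE)
  expect_equal(apply_filters(s5$tree, s5$map, cfg), "excluded:single_species")

  # metadata-driven species collapse
  meta <- tibble::tibble(genome_id = paste0("G", 1:12),
                         species = rep("Escherichia coli", 12))
  s12 <- make_set(12)
  expect_equal(apply_filters(s12$tree, s12$map, cfg, metadata = meta),
               "excluded:single_species")

  # missing branch lengths: screen skipped with a warning, not an error
  nolen <- parse_newick(paste0("(", paste(
    rep("(", 0), collapse = ""), paste0("g", 1:12, collapse = ","), ");"),
    rooted_hint = TRUE)
  expect_warning(
    st <- apply_filters(nolen, stats::setNames(paste0("G", 1:12), paste0("g", 1:12)), cfg),
    "skipped")
  expect_equal(st, "included")
})

test_that("classification separates HGT-genes from HGT-free and excluded sets", {
  expect_equal(
    classify_hgt(c("included", "included", "excluded:min_taxa"),
                 c(153L, 0L, NA)),
    c("hgt_gene", "hgt_free", "not_applicable"))
})

test_that("ranking is a stable descending sort with id tie-break", {
  rec <- tibble::tibble(
    gene_set_id = c("d", "b", "c", "a"),
    hgt_index = c(0.679, 0.714, 0.714, 0.801),
    n_genomes = c(187L, 28L, 28L, 191L))
  top <- rank_records(rec, by = "hgt_index", top_k = 3)
  expect_equal(top$gene_set_id, c("a", "b", "c"))
  expect_equal(top$hgt_index, c(0.801, 0.714, 0.714))
  expect_equal(nrow(rank_records(rec[0, ], top_k = 5)), 0L)
  expect_equal(nrow(rank_records(rec, top_k = 99)), 4L)
})

test_that("run summary computes counts and rounded percentages on the right denominators", {
  rec <- tibble::tibble(
    status = c(rep("excluded:min_taxa", 3), rep("included", 10)),
    hgt_class = c(rep("not_applicable", 3), rep("hgt_gene", 6), rep("hgt_free", 4)))
  s <- summarize_run(rec)
  expect_equal(s$n_total, 13L)
  expect_equal(s$n_excluded + s$n_included, s$n_total)
  expect_equal(s$n_hgt_gene + s$n_hgt_free, s$n_included)
  expect_equal(s$pct_excluded, round(100 * 3 / 13))
  expect_equal(s$pct_hgt_gene, 60)
  expect_equal(s$pct_hgt_free, 40)
  # degenerate: no HGT-free genes
  rec0 <- tibble::tibble(status = rep("included", 10),
                         hgt_class = rep("hgt_gene", 10))
  expect_equal(summarize_run(rec0)$pct_hgt_free, 0)
})
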