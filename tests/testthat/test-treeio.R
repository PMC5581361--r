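test_that("newick parsing reads topology, lengths and rootedness", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C"))
  expect_true(is_rooted_tree(tr))
  expect_equal(sort(tr$edge.length), c(1, 1, 1, 2))

  tri <- parse_newick("(A,B,C);")
  expect_false(is_rooted_tree(tri))
  expect_true(is_rooted_tree(parse_newick("(A,B,C);", rooted_hint = TRUE)))

  # comments stripped, labels verbatim (underscores untouched)
  tc <- parse_newick("((A_x[comment],B):1,C);")
  expect_true("A_x" %in% tc$tip.label)
})

test_that("parse errors name the problem", {
  expect_error(parse_newick("((A,A),B);"), "duplicate leaf labels")
  expect_error(parse_newick("((A,B),C"), "unclosed")
  expect_error(parse_newick("(A,B));"), "position")
})

test_that("write/parse round trip preserves topology, labels and lengths", {
  for (seed in 1:8) {
    set.seed(seed)
    tr <- simulate_species_tree(sample(4:12, 1))
    back <- parse_newick(write_newick(tr))
    expect_true(isTRUE(ape::all.equal.phylo(tr, back, use.edge.length = FALSE)))
    expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-9)
  }
  # no branch lengths -> no ":" fields
  txt <- write_newick(parse_newick("((A,B),C);"))
  expect_false(grepl(":", txt, fixed = TRUE))
  # single-leaf tree
  expect_equal(write_newick(parse_newick("A;")), "A;")
})

test_that("outgroup rooting places the outgroup split at the root", {
  t <- parse_newick("(A,B,(C,OUT));")
  dropped <- root_with_outgroup(t, "OUT", drop_outgroup = TRUE)
  # the OUT-adjacent edge induces split {C} | {A,B}: C sister to (A,B)
  expect_equal(write_newick(dropped), "((A,B),C);")
  kept <- root_with_outgroup(t, "OUT")
  base_kids <- kept$edge[kept$edge[, 1] == length(kept$tip.label) + 1L, 2]
  out_idx <- which(kept$tip.label == "OUT")
  expect_true(out_idx %in% base_kids)  # outgroup is a direct child of the root

  # already-rooted tree with the outgroup already basal: unchanged
  t2 <- parse_newick("((A,B),C);")
  expect_true(isTRUE(ape::all.equal.phylo(
    root_with_outgroup(t2, "C"), t2, use.edge.length = FALSE)))
  expect_error(root_with_outgroup(t2, "X"), "not found")
})

test_that("binarize resolves multifurcations left-to-right with zero lengths", {
  expect_equal(write_newick(binarize(parse_newick("(A,B,C);", rooted_hint = TRUE))),
               "((A,B),C);")
  expect_equal(write_newick(binarize(parse_newick("(A,B,C,D);", rooted_hint = TRUE))),
               "(((A,B),C),D);")
  b <- binarize(parse_newick("((A:1,B:1,C:1):1,D:2);"))
  expect_equal(write_newick(b), "(((A:1,B:1):0,C:1):1,D:2);")
  # identity on binary input; leaf set always unchanged
  t <- parse_newick("((A:1,B:1):1,C:2);")
  expect_equal(write_newick(binarize(t)), write_newick(t))
  expect_setequal(binarize(parse_newick("(A,B,C,D,E);", rooted_hint = TRUE))$tip.label,
                  LETTERS[1:5])
})

test_that("patristic distances sum path lengths and behave like a metric", {
  d <- patristic_distances(parse_newick("((A:1,B:1):1,C:2);"))
  expect_equal(d["A", "B"], 2)
  expect_equal(d["A", "C"], 4)
  expect_equal(d["B", "C"], 4)
  expect_equal(diag(d), c(A = 0, B = 0, C = 0))

  expect_equal(patristic_distances(parse_newick("(A:0.5,B:0.25);"))["A", "B"], 0.75)

  z <- parse_newick("((A:0,B:0):0,C:0);")
  expect_true(all(patristic_distances(z) == 0))

  expect_error(patristic_distances(parse_newick("((A,B),C);")), "branch lengths")

  # symmetry and triangle inequality on simulated trees
  for (seed in 1:5) {
    tr <- simulate_species_tree(8, seed = seed)
    d <- patristic_distances(tr)
    expect_equal(d, t(d))
    labs <- rownames(d)
    for (i in labs) for (j in labs) for (k in labs) {
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
    }
  }
})

test_that("gene-species map IO and validation", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tgenome_id", "a\tA", "b\tB"), tmp)
  m <- read_gene_species_map(tmp)
  expect_equal(m$gene_id, c("a", "b"))
  # headerless variant
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tA", "b\tB"), tmp2)
  expect_equal(read_gene_species_map(tmp2), m)

  gt <- parse_newick("((a,b),c);")
  st <- parse_newick("((A,B),C);")
  expect_error(validate_gene_species_map(gt, st, c(a = "A", b = "B")),
               "not total")
  expect_error(validate_gene_species_map(gt, st, c(a = "A", b = "B", c = "Z")),
               "absent from species tree")
  ok <- validate_gene_species_map(gt, st, c(a = "A", b = "B", c = "C"))
  expect_equal(unname(ok), c("A", "B", "C"))
})
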