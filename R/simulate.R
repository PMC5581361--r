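# Synthetic species/gene tree simulator with implanted, logged transfer
# events. Transfers are implanted as subtree-prune-and-regraft (SPR) edits on
# the gene tree: each edit detaches a clade and reattaches it next to a
# lineage incomparable to it, which is exactly the topological footprint a
# single transfer leaves. This gives exact ground truth (the edit log) with
# no rate calibration, at the price of not modelling sequence- or
# inference-level noise.

#' Simulate a rooted binary species tree
#'
#' Yule (pure-birth) topology: starting from a two-leaf tree, a uniformly
#' chosen extant tip is repeatedly split until `n_genomes` tips exist. Branch
#' lengths are i.i.d. exponential. Tips are labelled `G0001`, `G0002`, ... in
#' left-to-right order. Fully deterministic under `seed`.
#'
#' @param n_genomes Integer >= 3.
#' @param seed Optional integer seed.
#' @param branch_mean Mean of the exponential branch lengths, default 0.1
#'   (substitutions/site, the scale typical of 16S rRNA trees).
#' @return A rooted binary `phylo` with `n_genomes` tips.
#' @export
simulate_species_tree <- function(n_genomes, seed = NULL, branch_mean = 0.1) {
  if (n_genomes < 3) stop("n_genomes must be >= 3", call. = FALSE)
  run <- function() {
    max_nodes <- 2L * n_genomes
    children <- vector("list", max_nodes)
    root <- 1L
    children[[1]] <- c(2L, 3L)
    tips <- c(2L, 3L)
    nxt <- 4L
    while (length(tips) < n_genomes) {
      t <- tips[sample.int(length(tips), 1L)]
      children[[t]] <- c(nxt, nxt + 1L)
      tips <- c(setdiff(tips, t), nxt, nxt + 1L)
      nxt <- nxt + 2L
    }
    lens <- stats::rexp(max_nodes, rate = 1 / branch_mean)
    counter <- 0L
    render <- function(v, is_root) {
      kids <- children[[v]]
      core <- if (is.null(kids)) {
        counter <<- counter + 1L
        sprintf("G%04d", counter)
      } else {
        paste0("(", render(kids[1], FALSE), ",", render(kids[2], FALSE), ")")
      }
      if (is_root) core else paste0(core, ":", format(lens[v], digits = 12, scientific = FALSE))
    }
    parse_newick(paste0(render(root, TRUE), ";"))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a gene tree with implanted transfers
#'
#' Restricts the species tree to the sampled genomes (one gene per genome,
#' gene label = genome label prefixed `g_`), then applies `k` sequential SPR
#' edits. Each edit prunes a clade and regrafts it onto an edge incomparable
#' to it in the current gene tree; with `deep = TRUE`, both the pruned clade
#' and the regraft point must additionally sit at least two nodes below their
#' most recent common ancestor, so the edit is guaranteed to be topologically
#' visible.
#'
#' Successive edits are kept independent: the moved clades and regraft targets
#' of all k edits have pairwise disjoint leaf sets. Interacting edits (one
#' edit regrafting inside another's moved clade) can compound into topologies
#' whose cheapest explanation needs more than k transfers, which would break
#' the edit log as ground truth for transfer counts.
#'
#' @param species_tree A rooted binary `phylo`.
#' @param sampled_genomes Character vector of >= 3 genome labels (default: all
#'   tips).
#' @param k Number of transfer edits to implant (>= 0).
#' @param seed Optional integer seed.
#' @param deep Require topologically deep edits? Default `FALSE`.
#' @return A list with elements `tree` (the edited rooted `phylo`), `map`
#'   (tibble `gene_id`/`genome_id`), and `truth`: a list with
#'   `sampled_genomes`, `k_implanted`, and `events` (per edit: `order`,
#'   `recipient_genomes` = leaves of the moved clade, `donor_genomes` =
#'   leaves below the regraft point).
#' @export
simulate_gene_tree_with_transfers <- function(species_tree, sampled_genomes = NULL,
                                              k = 0L, seed = NULL, deep = FALSE) {
  stopifnot(inherits(species_tree, "phylo"), k >= 0)
  if (is.null(sampled_genomes)) sampled_genomes <- species_tree$tip.label
  if (length(sampled_genomes) < 3L) stop("need >= 3 sampled genomes", call. = FALSE)
  if (!all(sampled_genomes %in% species_tree$tip.label)) {
    stop("sampled genomes absent from species tree", call. = FALSE)
  }
  run <- function() {
    sub <- ape::keep.tip(species_tree, sampled_genomes)
    sub$tip.label <- paste0("g_", sub$tip.label)
    st <- phylo_to_spr(sub)
    events <- list()
    touched <- character(0)
    for (i in seq_len(k)) {
      cand <- spr_candidates(st, deep = deep)
      if (nrow(cand)) {
        untouched <- vapply(seq_len(nrow(cand)), function(j) {
          !any(c(spr_leaves(st, cand$v[j]), spr_leaves(st, cand$y[j])) %in% touched)
        }, logical(1))
        cand <- cand[untouched, , drop = FALSE]
      }
      if (!nrow(cand)) stop("no independent incomparable edge pair available for SPR",
                            call. = FALSE)
      pick <- cand[sample.int(nrow(cand), 1L), ]
      recipient <- spr_leaves(st, pick$v)
      donor <- spr_leaves(st, pick$y)
      touched <- c(touched, recipient, donor)
      st <- spr_apply(st, pick$v, pick$y)
      events[[i]] <- list(
        order = i,
        recipient_genomes = sub("^g_", "", recipient),
        donor_genomes = sub("^g_", "", donor)
      )
    }
    tree <- parse_newick(spr_to_newick(st))
    list(
      tree = tree,
      map = tibble::tibble(
        gene_id = tree$tip.label,
        genome_id = sub("^g_", "", tree$tip.label)
      ),
      truth = list(
        sampled_genomes = sort(sampled_genomes),
        k_implanted = as.integer(k),
        events = events
      )
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulation configuration
#'
#' Defines the study conditions a synthetic input bundle emulates: one rooted
#' reference tree over `n_genomes` genomes and `n_gene_sets` orthologous gene
#' sets, each a subsample of genomes whose gene tree differs from the species
#' tree by a known number of implanted transfers.
#'
#' @param n_genomes Genomes on the species tree, default 40.
#' @param n_gene_sets Number of gene sets, default 20.
#' @param transfers_per_set Integer vector recycled over gene sets, default 1.
#' @param set_size_range Inclusive range the per-set genome counts are drawn
#'   from (uniformly), default `c(10, 20)` (at least the downstream minimum-
#'   taxa threshold, at most half the default genome count), clipped to
#'   `n_genomes`.
#' @param deep Implant only topologically deep transfers? Default `TRUE` (so
#'   the implanted count is recoverable).
#' @param duplication_rate,loss_rate Per-leaf probabilities of implanting a
#'   leaf duplication / leaf loss after the transfer edits, default 0. Logged
#'   in the truth record but not part of transfer-recovery ground truth.
#' @param branch_mean Exponential mean for branch lengths, default 0.1.
#' @param majority_fraction Fraction of each set's genes carrying the set's
#'   Pfam family in the synthetic annotations, default 0.9.
#' @param n_single_genome_sets Extra designed fixture sets whose genes all map
#'   to a single genome (excluded downstream as single-species), default 0.
#' @param n_zero_length_sets Extra designed fixture sets with all-zero branch
#'   lengths (excluded downstream as zero-distance), default 0.
#' @param seed Integer seed; fixes the whole bundle byte-for-byte.
#' @return A list of class `hgt_sim_config`.
#' @export
simulation_config <- function(n_genomes = 40L, n_gene_sets = 20L,
                              transfers_per_set = 1L,
                              set_size_range = c(10L, 20L), deep = TRUE,
                              duplication_rate = 0, loss_rate = 0,
                              branch_mean = 0.1, majority_fraction = 0.9,
                              n_single_genome_sets = 0L,
                              n_zero_length_sets = 0L, seed = 1L) {
  stopifnot(
    n_genomes >= 3, n_gene_sets >= 1, all(transfers_per_set >= 0),
    length(set_size_range) == 2L, set_size_range[1] >= 3,
    duplication_rate >= 0, loss_rate >= 0, branch_mean > 0,
    majority_fraction > 0, majority_fraction <= 1
  )
  structure(
    list(
      n_genomes = as.integer(n_genomes),
      n_gene_sets = as.integer(n_gene_sets),
      transfers_per_set = as.integer(rep_len(transfers_per_set, n_gene_sets)),
      set_size_range = pmin(as.integer(set_size_range), as.integer(n_genomes)),
      deep = isTRUE(deep),
      duplication_rate = duplication_rate,
      loss_rate = loss_rate,
      branch_mean = branch_mean,
      majority_fraction = majority_fraction,
      n_single_genome_sets = as.integer(n_single_genome_sets),
      n_zero_length_sets = as.integer(n_zero_length_sets),
      seed = as.integer(seed)
    ),
    class = "hgt_sim_config"
  )
}

#' Generate a complete synthetic input bundle
#'
#' Writes everything the pipeline consumes to `dir`: `species.nwk`,
#' `genesets/<id>.nwk`, `mapping.tsv` (gene id -> genome id), synthetic
#' `annotations.tsv` (per-set Pfam family at the configured majority
#' fraction; GO terms from a fixed vocabulary), `metadata.tsv` (genome ->
#' phylum/species), `truth.json` (implanted event log) and `manifest.tsv`.
#' Gene ids are set-qualified (`<set>|g_<genome>`) so annotations are unique
#' per gene. Identical configurations produce byte-identical bundles.
#'
#' @param cfg A [simulation_config()].
#' @param dir Output directory (created if needed).
#' @return The manifest tibble (`gene_set_id`, `path`, `n_genomes`,
#'   `k_implanted`), invisibly.
#' @export
simulate_collection <- function(cfg, dir) {
  stopifnot(inherits(cfg, "hgt_sim_config"))
  dir.create(file.path(dir, "genesets"), recursive = TRUE, showWarnings = FALSE)
  withr::with_seed(cfg$seed, {
    species <- simulate_species_tree(cfg$n_genomes, branch_mean = cfg$branch_mean)
    write_newick(species, file.path(dir, "species.nwk"))
    genomes <- species$tip.label

    phyla_pool <- c("Proteobacteria", "Firmicutes", "Actinobacteria",
                    "Bacteroidetes", "Euryarchaeota")
    metadata <- tibble::tibble(
      genome_id = genomes,
      phylum = sample(phyla_pool, length(genomes), replace = TRUE),
      species = paste0("sp_", genomes)
    )
    readr::write_tsv(metadata, file.path(dir, "metadata.tsv"), progress = FALSE)

    go_vocab <- c(
      "carbohydrate metabolic process", "lipid metabolic process",
      "ion transport", "transmembrane transport",
      "transcription, DNA-templated", "regulation of transcription, DNA-templated",
      "signal transduction", "translation", "response to antibiotic",
      "toxin transport", "response to stress", "cellular ion homeostasis",
      "rRNA processing", "transposition, DNA-mediated", "DNA repair",
      "cell wall organization", "protein folding", "phosphorylation"
    )

    manifest <- list(); mapping <- list(); annot <- list(); truth <- list()
    add_annotations <- function(set_id, gene_ids) {
      fam <- sprintf("PF%05d", sample.int(99999L, 1L))
      n <- length(gene_ids)
      n_fam <- ceiling(cfg$majority_fraction * n)
      carriers <- sample(gene_ids, n_fam)
      tibble::tibble(
        gene_id = gene_ids,
        pfam_ids = ifelse(gene_ids %in% carriers, fam, ""),
        go_bp_terms = vapply(gene_ids, function(g) {
          paste(sample(go_vocab, sample.int(3L, 1L)), collapse = "|")
        }, character(1))
      )
    }

    i_set <- 0L
    emit_set <- function(set_id, tree, map, truth_rec) {
      path <- file.path("genesets", paste0(set_id, ".nwk"))
      write_newick(tree, file.path(dir, path))
      manifest[[length(manifest) + 1L]] <<- tibble::tibble(
        gene_set_id = set_id, path = path,
        n_genomes = length(unique(map$genome_id)),
        k_implanted = truth_rec$k_implanted
      )
      mapping[[length(mapping) + 1L]] <<- map
      annot[[length(annot) + 1L]] <<- add_annotations(set_id, map$gene_id)
      truth[[set_id]] <<- truth_rec
    }

    for (j in seq_len(cfg$n_gene_sets)) {
      i_set <- i_set + 1L
      set_id <- sprintf("set%03d", i_set)
      size <- sample(seq(cfg$set_size_range[1], cfg$set_size_range[2]), 1L)
      sampled <- sample(genomes, size)
      k <- cfg$transfers_per_set[j]
      sim <- simulate_gene_tree_with_transfers(species, sampled, k = k, deep = cfg$deep)
      tree <- sim$tree
      # optional leaf duplications / losses (logged, not recovery targets)
      n_dup <- stats::rbinom(1L, length(tree$tip.label), cfg$duplication_rate)
      n_lost <- stats::rbinom(1L, length(tree$tip.label), cfg$loss_rate)
      if (n_dup > 0L) {
        for (d in seq_len(n_dup)) {
          tip <- sample(tree$tip.label, 1L)
          tree <- ape::bind.tree(
            tree,
            structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                           tip.label = paste0(tip, "_dup", d),
                           edge.length = 0, Nnode = 1L),
                      class = "phylo"),
            where = which(tree$tip.label == tip)
          )
        }
      }
      if (n_lost > 0L && length(tree$tip.label) - n_lost >= 3L) {
        drop <- sample(tree$tip.label, n_lost)
        tree <- ape::drop.tip(tree, drop)
      } else {
        n_lost <- 0L
      }
      tree$tip.label <- paste0(set_id, "|", tree$tip.label)
      map <- tibble::tibble(
        gene_id = tree$tip.label,
        genome_id = sub("^.*\\|g_", "", sub("_dup[0-9]+$", "", tree$tip.label))
      )
      tr <- sim$truth
      tr$n_dup_implanted <- as.integer(n_dup)
      tr$n_loss_implanted <- as.integer(n_lost)
      emit_set(set_id, tree, map, tr)
    }

    for (j in seq_len(cfg$n_single_genome_sets)) {
      i_set <- i_set + 1L
      set_id <- sprintf("set%03d", i_set)
      genome <- sample(genomes, 1L)
      n_copies <- 12L
      labs <- sprintf("%s|g_%s_c%02d", set_id, genome, seq_len(n_copies))
      tree <- ape::rtree(n_copies, tip.label = labs, br = stats::rexp, rate = 1 / cfg$branch_mean)
      map <- tibble::tibble(gene_id = labs, genome_id = genome)
      emit_set(set_id, tree, map,
               list(sampled_genomes = genome, k_implanted = 0L, events = list(),
                    fixture = "single_genome"))
    }

    for (j in seq_len(cfg$n_zero_length_sets)) {
      i_set <- i_set + 1L
      set_id <- sprintf("set%03d", i_set)
      size <- max(cfg$set_size_range[1], 10L)
      sampled <- sample(genomes, size)
      sim <- simulate_gene_tree_with_transfers(species, sampled, k = 0L)
      tree <- sim$tree
      tree$edge.length <- rep(0, length(tree$edge.length))
      tree$tip.label <- paste0(set_id, "|", tree$tip.label)
      map <- tibble::tibble(gene_id = tree$tip.label,
                            genome_id = sub("^.*\\|g_", "", tree$tip.label))
      emit_set(set_id, tree, map,
               list(sampled_genomes = sort(sampled), k_implanted = 0L,
                    events = list(), fixture = "zero_length"))
    }

    manifest <- dplyr::bind_rows(manifest)
    readr::write_tsv(manifest, file.path(dir, "manifest.tsv"), progress = FALSE)
    readr::write_tsv(dplyr::bind_rows(mapping), file.path(dir, "mapping.tsv"),
                     progress = FALSE)
    readr::write_tsv(dplyr::bind_rows(annot), file.path(dir, "annotations.tsv"),
                     progress = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(manifest)
  })
}

# --- SPR machinery on a mutable array representation ------------------------
# Nodes: parent (NA for root), children (list), brlen (length of edge above
# node, NA for root), active flag. Built from / rendered to phylo via newick.

phylo_to_spr <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_nodes <- n_tip + tree$Nnode
  children <- vector("list", n_nodes + 2L)  # slack for regraft nodes
  for (v in seq_len(n_nodes + 2L)) children[[v]] <- integer(0)
  parent <- rep(NA_integer_, n_nodes + 2L)
  brlen <- rep(NA_real_, n_nodes + 2L)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    children[[p]] <- c(children[[p]], ch)
    parent[ch] <- p
    brlen[ch] <- if (!is.null(tree$edge.length)) tree$edge.length[i] else 0.1
  }
  labels <- rep(NA_character_, n_nodes + 2L)
  labels[seq_len(n_tip)] <- tree$tip.label
  active <- c(rep(TRUE, n_nodes), FALSE, FALSE)
  list(children = children, parent = parent, brlen = brlen,
       labels = labels, root = n_tip + 1L, active = active,
       free = c(n_nodes + 1L, n_nodes + 2L))
}

spr_descendants <- function(st) {
  n <- length(st$children)
  desc <- matrix(FALSE, n, n)
  walk <- function(v) {
    desc[v, v] <<- TRUE
    for (ch in st$children[[v]]) {
      walk(ch)
      desc[v, ] <<- desc[v, ] | desc[ch, ]
    }
  }
  walk(st$root)
  desc
}

spr_depths <- function(st) {
  n <- length(st$children)
  depth <- rep(NA_integer_, n)
  walk <- function(v, d) {
    depth[v] <<- d
    for (ch in st$children[[v]]) walk(ch, d + 1L)
  }
  walk(st$root, 0L)
  depth
}

spr_leaves <- function(st, v) {
  out <- character(0)
  walk <- function(u) {
    if (!length(st$children[[u]])) {
      out <<- c(out, st$labels[u])
    } else {
      for (ch in st$children[[u]]) walk(ch)
    }
  }
  walk(v)
  sort(out)
}

# Candidate (pruned clade v, regraft-edge child y) pairs: both non-root,
# incomparable in the current tree; optionally "deep" (each >= 2 edges below
# their MRCA, which rules out topology-neutral sibling regrafts).
spr_candidates <- function(st, deep = FALSE) {
  desc <- spr_descendants(st)
  depth <- spr_depths(st)
  nodes <- which(st$active)
  nodes <- setdiff(nodes, st$root)
  pairs <- expand.grid(v = nodes, y = nodes)
  keep <- !mapply(function(v, y) desc[v, y] || desc[y, v], pairs$v, pairs$y)
  pairs <- pairs[keep, , drop = FALSE]
  if (deep && nrow(pairs)) {
    anc_sets <- lapply(seq_along(st$active), function(v) {
      if (!st$active[v]) return(integer(0))
      out <- integer(0); u <- v
      while (!is.na(st$parent[u])) { u <- st$parent[u]; out <- c(out, u) }
      out
    })
    deep_ok <- mapply(function(v, y) {
      common <- intersect(anc_sets[[v]], anc_sets[[y]])
      mrca <- common[which.max(depth[common])]
      (depth[v] - depth[mrca]) >= 2L && (depth[y] - depth[mrca]) >= 2L
    }, pairs$v, pairs$y)
    pairs <- pairs[deep_ok, , drop = FALSE]
  }
  pairs
}

spr_apply <- function(st, v, y) {
  p <- st$parent[v]
  sib <- setdiff(st$children[[p]], v)
  g <- st$parent[p]
  # splice out p
  if (is.na(g)) {
    st$root <- sib
    st$parent[sib] <- NA_integer_
    st$brlen[sib] <- NA_real_
  } else {
    st$children[[g]][st$children[[g]] == p] <- sib
    st$parent[sib] <- g
    st$brlen[sib] <- st$brlen[sib] + st$brlen[p]
  }
  st$children[[p]] <- integer(0)
  st$active[p] <- FALSE
  st$free <- c(st$free, p)
  # regraft v onto the edge above y (y may now be the root)
  w <- st$free[1]
  st$free <- st$free[-1]
  st$active[w] <- TRUE
  x <- st$parent[y]
  if (is.na(x)) {
    st$children[[w]] <- c(y, v)
    st$parent[y] <- w
    st$parent[v] <- w
    st$brlen[y] <- 0.05
    st$parent[w] <- NA_integer_
    st$brlen[w] <- NA_real_
    st$root <- w
  } else {
    st$children[[x]][st$children[[x]] == y] <- w
    st$parent[w] <- x
    st$brlen[w] <- st$brlen[y] / 2
    st$children[[w]] <- c(y, v)
    st$parent[y] <- w
    st$brlen[y] <- st$brlen[y] / 2
    st$parent[v] <- w
  }
  st
}

spr_to_newick <- function(st) {
  render <- function(v, is_root) {
    kids <- st$children[[v]]
    core <- if (!length(kids)) {
      st$labels[v]
    } else {
      paste0("(", paste(vapply(kids, function(k) render(k, FALSE), character(1)),
                        collapse = ","), ")")
    }
    if (is_root) core
    else paste0(core, ":", format(st$brlen[v], digits = 12, scientific = FALSE))
  }
  paste0(render(st$root, TRUE), ";")
}
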