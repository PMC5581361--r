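# Undated duplication-transfer-loss (DTL) maximum-parsimony reconciliation.
#
# The dynamic program fills, for every gene-tree node g and species-tree node
# s, the cheapest cost c(g, s) of reconciling the gene subtree rooted at g
# with its root mapped exactly at s, together with
#   in(g, s)  = cheapest cost of entering the species tree at s and mapping g
#               at s or anywhere below it (each step down costs one loss), and
#   out(g, s) = min over species nodes s' incomparable to s of in(g, s').
# Internal gene nodes are explained by one of three events:
#   speciation   (internal s only): the two gene children enter the two
#                 distinct child subtrees of s;
#   duplication:  both children enter at s itself;
#   transfer:     one child enters at s, the other at some species node
#                 incomparable to s (the recipient).
# The model is undated: no global time-consistency constraint is imposed
# across transfers, only per-transfer donor/recipient incomparability.

#' DTL event costs
#'
#' Non-negative per-event parsimony costs. The defaults (duplication 2,
#' transfer 3, loss 1) are the conventional defaults of DTL reconciliation
#' software; the optimum is reported together with event counts so users can
#' re-run under other regimes.
#'
#' @param duplication,transfer,loss Non-negative numbers.
#' @return A list of class `dtl_costs`.
#' @export
dtl_costs <- function(duplication = 2, transfer = 3, loss = 1) {
  stopifnot(
    is.numeric(duplication), duplication >= 0,
    is.numeric(transfer), transfer >= 0,
    is.numeric(loss), loss >= 0
  )
  structure(
    list(duplication = duplication, transfer = transfer, loss = loss),
    class = "dtl_costs"
  )
}

#' DTL dynamic-programming cost tables
#'
#' Low-level access to the reconciliation tables; most users want
#' [reconcile_dtl()]. Rows are gene-tree nodes, columns species-tree nodes
#' (both in ape numbering: tips first, then internals from the root).
#'
#' @param gene_tree Rooted binary `phylo`.
#' @param species_tree Rooted binary `phylo`.
#' @param map Gene-to-genome map: data frame (`gene_id`, `genome_id`) or named
#'   character vector.
#' @param costs A [dtl_costs()] object.
#' @return A list with matrices `c`, `in_`, `out`, the optimal total cost
#'   `optimum`, and the internal tree indices.
#' @export
dtl_cost_table <- function(gene_tree, species_tree, map, costs = dtl_costs()) {
  stopifnot(inherits(gene_tree, "phylo"), inherits(species_tree, "phylo"))
  if (!is_rooted_tree(species_tree)) {
    stop("species tree must be rooted; use root_with_outgroup() first", call. = FALSE)
  }
  if (!is_rooted_tree(gene_tree)) {
    stop("dtl_cost_table() needs a rooted gene tree; use reconcile_dtl() for unrooted input",
         call. = FALSE)
  }
  gti <- index_rooted_phylo(gene_tree)
  sti <- index_rooted_phylo(species_tree)
  m <- validate_gene_species_map(gene_tree, species_tree, map)
  map_idx <- match(unname(m), species_tree$tip.label)
  names(map_idx) <- names(m)
  tip_map <- map_idx[gti$tip_labels[seq_along(gene_tree$tip.label)]]
  tab <- dtl_dp(gti, sti, tip_map, costs)
  tab$gene_index <- gti
  tab$species_index <- sti
  tab$tip_map <- tip_map
  tab$costs <- costs
  tab
}

#' Reconcile a gene tree against a rooted species tree
#'
#' Runs the undated DTL maximum-parsimony dynamic program and backtracks one
#' optimal reconciliation. Unrooted gene trees are handled by evaluating every
#' edge-rooting and keeping the cheapest (ties broken by the smallest
#' canonical edge index). All remaining ties among equally cheap events are
#' broken deterministically -- speciation over duplication over transfer, then
#' the smallest species postorder index -- and the result records whether any
#' tie was encountered, since equally parsimonious reconciliations are not
#' enumerated.
#'
#' @inheritParams dtl_cost_table
#' @param gene_tree A `phylo`, rooted or unrooted (unrooted trees need at
#'   least 3 leaves).
#' @return An object of class `dtl_reconciliation` with elements `cost`,
#'   `events` (tibble: one row per gene internal node), `transfers` (tibble of
#'   donor/recipient species nodes), `n_duplication`, `n_transfer`, `n_loss`,
#'   `ties`, `rooting_edge` (NA for rooted input), plus label bookkeeping.
#'   Supports [tidy()], [glance()] and `print()`.
#' @examples
#' sp <- parse_newick("((A:1,B:1):1,C:2);")
#' gn <- parse_newick("((a:1,b:1):1,c:2);")
#' map <- c(a = "A", b = "B", c = "C")
#' rec <- reconcile_dtl(gn, sp, map)
#' rec$cost        # 0: congruent trees
#' count_transfers(rec)
#' @export
reconcile_dtl <- function(gene_tree, species_tree, map, costs = dtl_costs()) {
  stopifnot(inherits(gene_tree, "phylo"), inherits(species_tree, "phylo"))
  if (!is_rooted_tree(species_tree)) {
    stop("species tree must be rooted; use root_with_outgroup() first", call. = FALSE)
  }
  if (is_rooted_tree(gene_tree)) {
    tab <- dtl_cost_table(gene_tree, species_tree, map, costs)
    res <- dtl_backtrack(tab)
    res$rooting_edge <- NA_integer_
    return(res)
  }
  reconcile_unrooted(gene_tree, species_tree, map, costs)
}

#' Reconcile an unrooted gene tree by exhaustive edge-rooting
#'
#' Evaluates the rooted DTL optimum for every possible root placement (one per
#' edge of the unrooted gene tree) and returns the reconciliation of the
#' cheapest rooting. Edge indices follow the postorder edge sequence of the
#' input orientation; among equally cheap rootings the smallest index wins.
#'
#' @inheritParams reconcile_dtl
#' @return A `dtl_reconciliation`; `rooting_edge` gives the chosen edge.
#' @export
reconcile_unrooted <- function(gene_tree, species_tree, map, costs = dtl_costs()) {
  stopifnot(inherits(gene_tree, "phylo"))
  if (length(gene_tree$tip.label) < 3L) {
    stop("unrooted reconciliation needs >= 3 leaves", call. = FALSE)
  }
  if (!is_rooted_tree(species_tree)) {
    stop("species tree must be rooted; use root_with_outgroup() first", call. = FALSE)
  }
  sti <- index_rooted_phylo(species_tree)
  m <- validate_gene_species_map(gene_tree, species_tree, map)
  map_idx <- match(unname(m), species_tree$tip.label)
  names(map_idx) <- names(m)
  # a binary-rooted tree flagged unrooted must first lose its arbitrary root,
  # otherwise re-rooting would leave a degree-2 node
  if (ape::is.rooted(gene_tree)) gene_tree <- ape::unroot(gene_tree)
  rootings <- enumerate_rootings(gene_tree)
  best <- NULL
  best_tab <- NULL
  any_tie <- FALSE
  for (gti in rootings) {
    tip_map <- map_idx[gti$tip_labels[seq_along(gene_tree$tip.label)]]
    tab <- dtl_dp(gti, sti, tip_map, costs)
    if (is.null(best) || tab$optimum < best - 1e-9) {
      best <- tab$optimum
      tab$gene_index <- gti
      tab$species_index <- sti
      tab$tip_map <- tip_map
      tab$costs <- costs
      best_tab <- tab
    } else if (abs(tab$optimum - best) <= 1e-9) {
      any_tie <- TRUE
    }
  }
  res <- dtl_backtrack(best_tab)
  res$rooting_edge <- best_tab$gene_index$rooting_edge
  res$ties <- res$ties || any_tie
  res
}

#' Number of transfer events in a reconciliation
#'
#' @param result A `dtl_reconciliation`.
#' @return Non-negative integer count of transfer events.
#' @export
count_transfers <- function(result) {
  stopifnot(inherits(result, "dtl_reconciliation"))
  result$n_transfer
}

#' @export
print.dtl_reconciliation <- function(x, ...) {
  cat("DTL reconciliation (undated maximum parsimony)\n")
  cat(sprintf("  cost: %g  (D=%g, T=%g, L=%g)\n", x$cost,
              x$costs$duplication, x$costs$transfer, x$costs$loss))
  cat(sprintf("  events: %d duplication, %d transfer, %d loss\n",
              x$n_duplication, x$n_transfer, x$n_loss))
  if (!is.na(x$rooting_edge)) cat(sprintf("  rooting edge: %d\n", x$rooting_edge))
  if (x$ties) cat("  note: equally parsimonious alternatives existed (deterministic choice)\n")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-node event table of a reconciliation
#'
#' @param x A `dtl_reconciliation`.
#' @param ... Unused.
#' @return A tibble with one row per gene internal node: `gene_node`, `event`,
#'   `species_node`, `donor`, `recipient`.
#' @method tidy dtl_reconciliation
#' @export
tidy.dtl_reconciliation <- function(x, ...) x$events

#' One-row summary of a reconciliation
#'
#' @param x A `dtl_reconciliation`.
#' @param ... Unused.
#' @return A one-row tibble: cost, event counts, tie flag, rooting edge.
#' @method glance dtl_reconciliation
#' @export
glance.dtl_reconciliation <- function(x, ...) {
  tibble::tibble(
    cost = x$cost,
    n_duplication = x$n_duplication,
    n_transfer = x$n_transfer,
    n_loss = x$n_loss,
    ties = x$ties,
    rooting_edge = x$rooting_edge
  )
}

#' Write a reconciliation report TSV
#'
#' One row per gene internal node (node id, event, mapped species node, donor,
#' recipient) followed by a `#summary` comment line with the total cost, event
#' counts and rooting edge.
#'
#' @param result A `dtl_reconciliation`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reconciliation_report <- function(result, path) {
  stopifnot(inherits(result, "dtl_reconciliation"))
  readr::write_tsv(result$events, path, progress = FALSE)
  summary_line <- sprintf(
    "#summary\tcost=%g\tn_duplication=%d\tn_transfer=%d\tn_loss=%d\trooting_edge=%s\tties=%s",
    result$cost, result$n_duplication, result$n_transfer, result$n_loss,
    ifelse(is.na(result$rooting_edge), "NA", as.character(result$rooting_edge)),
    result$ties
  )
  cat(summary_line, "\n", file = path, append = TRUE, sep = "")
  invisible(path)
}

# --- dynamic program --------------------------------------------------------

dtl_dp <- function(gti, sti, tip_map, costs) {
  if (any(vapply(gti$children, length, 1L) > 2L) ||
      any(vapply(sti$children, length, 1L) > 2L)) {
    stop("reconciliation requires binary trees; call binarize() first", call. = FALSE)
  }
  D <- costs$duplication; Tc <- costs$transfer; L <- costs$loss
  ng <- gti$n; ns <- sti$n
  anc <- ancestry_matrices(sti)
  INC <- anc$inc
  s_internal <- which(!sti$is_tip)
  C <- matrix(Inf, ng, ns)
  IN <- matrix(Inf, ng, ns)
  OUT <- matrix(Inf, ng, ns)
  s_post <- sti$order

  for (gv in gti$order) {
    if (gti$is_tip[gv]) {
      C[gv, tip_map[[gti$tip_labels[gv]]]] <- 0
    } else {
      kids <- gti$children[[gv]]
      in1 <- IN[kids[1], ]; in2 <- IN[kids[2], ]
      out1 <- OUT[kids[1], ]; out2 <- OUT[kids[2], ]
      dup <- D + in1 + in2
      trn <- Tc + pmin(in1 + out2, in2 + out1)
      spe <- rep(Inf, ns)
      for (sv in s_internal) {
        sc <- sti$children[[sv]]
        spe[sv] <- min(in1[sc[1]] + in2[sc[2]], in1[sc[2]] + in2[sc[1]])
      }
      C[gv, ] <- pmin(spe, dup, trn)
    }
    inn <- C[gv, ]
    for (sv in s_post) {
      if (!sti$is_tip[sv]) {
        sc <- sti$children[[sv]]
        inn[sv] <- min(inn[sv], L + inn[sc[1]], L + inn[sc[2]])
      }
    }
    IN[gv, ] <- inn
    OUT[gv, ] <- vapply(seq_len(ns), function(sv) {
      x <- inn[INC[sv, ]]
      if (length(x)) min(x) else Inf
    }, numeric(1))
  }
  optimum <- min(C[gti$root, ])
  list(c = C, in_ = IN, out = OUT, optimum = optimum, species_inc = INC)
}

# --- backtracking -----------------------------------------------------------

dtl_backtrack <- function(tab) {
  eps <- 1e-9
  gti <- tab$gene_index
  sti <- tab$species_index
  costs <- tab$costs
  D <- costs$duplication; Tc <- costs$transfer; L <- costs$loss
  C <- tab$c; IN <- tab$in_; OUT <- tab$out; INC <- tab$species_inc
  ties <- FALSE

  pick_min <- function(values) {
    # smallest species postorder rank among minima; flags ties
    m <- min(values)
    cand <- which(values <= m + eps)
    if (length(cand) > 1L) ties <<- TRUE
    cand[which.min(sti$post_rank[cand])]
  }

  root_row <- C[gti$root, ]
  root_s <- pick_min(root_row)
  if (!is.finite(root_row[root_s])) {
    stop("internal error: no finite reconciliation (is the map total?)", call. = FALSE)
  }

  n_loss <- 0L
  events <- list()
  transfers <- list()

  node_id <- function(ti, v, prefix) {
    if (ti$is_tip[v]) ti$tip_labels[v] else sprintf("%s%d", prefix, ti$post_rank[v])
  }

  # Follow the in()-chain from entry point sv down to the node where the gene
  # node maps exactly; each step down is one loss. Prefers stopping (fewer
  # losses) when tied.
  descend <- function(gv, sv) {
    repeat {
      if (C[gv, sv] <= IN[gv, sv] + eps) {
        if (!sti$is_tip[sv]) {
          sc <- sti$children[[sv]]
          if (min(L + IN[gv, sc[1]], L + IN[gv, sc[2]]) <= IN[gv, sv] + eps) ties <<- TRUE
        }
        return(sv)
      }
      sc <- sti$children[[sv]]
      opts <- c(L + IN[gv, sc[1]], L + IN[gv, sc[2]])
      j <- if (opts[1] <= IN[gv, sv] + eps && opts[2] <= IN[gv, sv] + eps) {
        ties <<- TRUE
        if (sti$post_rank[sc[1]] < sti$post_rank[sc[2]]) 1L else 2L
      } else if (opts[1] <= IN[gv, sv] + eps) 1L else 2L
      n_loss <<- n_loss + 1L
      sv <- sc[j]
    }
  }

  assign_node <- function(gv, sv) {
    if (gti$is_tip[gv]) return(invisible(NULL))
    kids <- gti$children[[gv]]
    g1 <- kids[1]; g2 <- kids[2]
    best <- C[gv, sv]

    spe <- Inf; spe_orient <- NA_integer_
    if (!sti$is_tip[sv]) {
      sc <- sti$children[[sv]]
      o1 <- IN[g1, sc[1]] + IN[g2, sc[2]]
      o2 <- IN[g1, sc[2]] + IN[g2, sc[1]]
      spe <- min(o1, o2)
      if (abs(o1 - o2) <= eps && is.finite(o1)) ties <<- TRUE
      spe_orient <- if (o1 <= o2 + eps) 1L else 2L
    }
    dup <- D + IN[g1, sv] + IN[g2, sv]
    trA <- Tc + IN[g1, sv] + OUT[g2, sv]  # g2 transferred
    trB <- Tc + IN[g2, sv] + OUT[g1, sv]  # g1 transferred
    trn <- min(trA, trB)

    hits <- sum(c(spe, dup, trn) <= best + eps)
    if (hits > 1L) ties <<- TRUE

    if (spe <= best + eps) {
      sc <- sti$children[[sv]]
      e1 <- if (spe_orient == 1L) sc[1] else sc[2]
      e2 <- if (spe_orient == 1L) sc[2] else sc[1]
      events[[length(events) + 1L]] <<- list(
        gene_node = node_id(gti, gv, "g"), event = "speciation",
        species_node = node_id(sti, sv, "s"),
        donor = NA_character_, recipient = NA_character_
      )
      s1 <- descend(g1, e1)
      s2 <- descend(g2, e2)
      assign_node(g1, s1)
      assign_node(g2, s2)
    } else if (dup <= best + eps) {
      events[[length(events) + 1L]] <<- list(
        gene_node = node_id(gti, gv, "g"), event = "duplication",
        species_node = node_id(sti, sv, "s"),
        donor = NA_character_, recipient = NA_character_
      )
      s1 <- descend(g1, sv)
      s2 <- descend(g2, sv)
      assign_node(g1, s1)
      assign_node(g2, s2)
    } else {
      if (trA <= trn + eps && trB <= trn + eps) ties <<- TRUE
      transferred_first <- trB <= trn + eps && trA > trn + eps
      g_stay <- if (transferred_first) g2 else g1
      g_move <- if (transferred_first) g1 else g2
      rec_vals <- ifelse(INC[sv, ], IN[g_move, ], Inf)
      r <- pick_min(rec_vals)
      events[[length(events) + 1L]] <<- list(
        gene_node = node_id(gti, gv, "g"), event = "transfer",
        species_node = node_id(sti, sv, "s"),
        donor = node_id(sti, sv, "s"), recipient = node_id(sti, r, "s")
      )
      transfers[[length(transfers) + 1L]] <<- list(
        donor = sv, recipient = r,
        donor_id = node_id(sti, sv, "s"), recipient_id = node_id(sti, r, "s")
      )
      s_stay <- descend(g_stay, sv)
      s_move <- descend(g_move, r)
      assign_node(g_stay, s_stay)
      assign_node(g_move, s_move)
    }
    invisible(NULL)
  }

  assign_node(gti$root, root_s)

  ev <- if (length(events)) {
    tibble::as_tibble(do.call(rbind, lapply(events, function(e) {
      data.frame(gene_node = e$gene_node, event = e$event,
                 species_node = e$species_node, donor = e$donor,
                 recipient = e$recipient, stringsAsFactors = FALSE)
    })))
  } else {
    tibble::tibble(gene_node = character(), event = character(),
                   species_node = character(), donor = character(),
                   recipient = character())
  }
  tr <- if (length(transfers)) {
    tibble::tibble(
      donor = vapply(transfers, function(t) t$donor_id, character(1)),
      recipient = vapply(transfers, function(t) t$recipient_id, character(1)),
      donor_node = vapply(transfers, function(t) t$donor, integer(1)),
      recipient_node = vapply(transfers, function(t) t$recipient, integer(1))
    )
  } else {
    tibble::tibble(donor = character(), recipient = character(),
                   donor_node = integer(), recipient_node = integer())
  }

  # transfer validity: donor and recipient must be incomparable
  if (nrow(tr)) {
    ok <- mapply(function(d, r) INC[d, r], tr$donor_node, tr$recipient_node)
    if (!all(ok)) stop("internal error: comparable transfer donor/recipient", call. = FALSE)
  }

  n_dup <- sum(ev$event == "duplication")
  n_trn <- sum(ev$event == "transfer")
  recomputed <- D * n_dup + Tc * n_trn + L * n_loss
  if (abs(recomputed - tab$optimum) > 1e-6) {
    stop(sprintf("internal error: backtracked cost %g != table optimum %g",
                 recomputed, tab$optimum), call. = FALSE)
  }

  structure(
    list(
      cost = tab$optimum,
      events = ev,
      transfers = tr[, c("donor", "recipient")],
      n_duplication = as.integer(n_dup),
      n_transfer = as.integer(n_trn),
      n_loss = as.integer(n_loss),
      ties = ties,
      rooting_edge = NA_integer_,
      root_species = root_s,
      costs = costs
    ),
    class = "dtl_reconciliation"
  )
}
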