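# Independent brute-force DTL oracle.
#
# Enumerates every assignment of species nodes to gene internal nodes and
# takes, per node, the cheapest valid event:
#   speciation at internal s: children map into the two distinct child
#     subtrees of s; losses = steps from each child subtree root down to the
#     child's node.
#   duplication at s: both children map inside the subtree of s; losses =
#     steps down from s.
#   transfer at s: one child maps inside the subtree of s, the other maps at
#     a node incomparable to s (the reconciliation may choose the recipient
#     equal to that node, so the transferred side incurs no losses).
# Total cost = sum over gene internal nodes; oracle optimum = min over all
# assignments. Shares nothing with the package's dynamic program except basic
# tree traversal.

oracle_tree_idx <- function(tree) {
  n_tip <- length(tree$tip.label)
  n <- n_tip + tree$Nnode
  kids <- vector("list", n)
  parent <- rep(NA_integer_, n)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    kids[[p]] <- c(kids[[p]], ch)
    parent[ch] <- p
  }
  root <- n_tip + 1L
  depth <- rep(0L, n)
  ord <- integer(0)
  stack <- root
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    ord <- c(ord, v)
    for (ch in kids[[v]]) {
      depth[ch] <- depth[v] + 1L
      stack <- c(stack, ch)
    }
  }
  desc <- matrix(FALSE, n, n)
  for (v in rev(ord)) {
    desc[v, v] <- TRUE
    for (ch in kids[[v]]) desc[v, ] <- desc[v, ] | desc[ch, ]
  }
  list(n = n, n_tip = n_tip, kids = kids, parent = parent, root = root,
       depth = depth, desc = desc, preorder = ord)
}

oracle_dtl <- function(gene_tree, species_tree, map, costs = list(duplication = 2, transfer = 3, loss = 1)) {
  gi <- oracle_tree_idx(gene_tree)
  si <- oracle_tree_idx(species_tree)
  D <- costs$duplication; Tc <- costs$transfer; L <- costs$loss
  ns <- si$n
  inc <- !(si$desc | t(si$desc))   # incomparability relation
  sdepth <- si$depth
  ch1 <- rep(NA_integer_, ns); ch2 <- rep(NA_integer_, ns)
  for (s in seq_len(ns)) {
    if (length(si$kids[[s]]) == 2L) { ch1[s] <- si$kids[[s]][1]; ch2[s] <- si$kids[[s]][2] }
  }
  tip_map <- match(map[gene_tree$tip.label], species_tree$tip.label)

  gint <- rev(gi$preorder)            # postorder
  gint <- gint[gint > gi$n_tip]       # internal gene nodes
  k <- length(gint)
  M <- as.matrix(do.call(expand.grid, rep(list(seq_len(ns)), k)))
  R <- nrow(M)
  col_of <- function(g) which(gint == g)
  mapped <- function(g) {
    if (g <= gi$n_tip) rep(tip_map[g], R) else M[, col_of(g)]
  }

  inf_if <- function(valid, cost) ifelse(!is.na(valid) & valid, cost, Inf)
  spe_cost_of <- function(sv, m1, m2) {
    s1 <- ch1[sv]; s2 <- ch2[sv]
    v1 <- si$desc[cbind(s1, m1)] & si$desc[cbind(s2, m2)]
    c1 <- L * ((sdepth[m1] - sdepth[s1]) + (sdepth[m2] - sdepth[s2]))
    v2 <- si$desc[cbind(s2, m1)] & si$desc[cbind(s1, m2)]
    c2 <- L * ((sdepth[m1] - sdepth[s2]) + (sdepth[m2] - sdepth[s1]))
    pmin(inf_if(v1, c1), inf_if(v2, c2))
  }
  dup_cost_of <- function(sv, m1, m2) {
    v <- si$desc[cbind(sv, m1)] & si$desc[cbind(sv, m2)]
    inf_if(v, D + L * (sdepth[m1] + sdepth[m2] - 2 * sdepth[sv]))
  }
  trn_cost_of <- function(sv, m1, m2) {
    v1 <- si$desc[cbind(sv, m1)] & inc[cbind(m2, sv)]
    c1 <- Tc + L * (sdepth[m1] - sdepth[sv])
    v2 <- si$desc[cbind(sv, m2)] & inc[cbind(m1, sv)]
    c2 <- Tc + L * (sdepth[m2] - sdepth[sv])
    pmin(inf_if(v1, c1), inf_if(v2, c2))
  }

  total <- rep(0, R)
  for (g in gint) {
    kidg <- gi$kids[[g]]
    m1 <- mapped(kidg[1]); m2 <- mapped(kidg[2]); sv <- M[, col_of(g)]
    total <- total + pmin(spe_cost_of(sv, m1, m2),
                          dup_cost_of(sv, m1, m2),
                          trn_cost_of(sv, m1, m2))
  }
  best <- min(total)

  # event-count multisets at the optimum (preference speciation < duplication
  # < transfer within each node, as documented for the implementation)
  triples <- unique(t(vapply(which(total <= best + 1e-9), function(r) {
    nd <- 0L; nt <- 0L; nl <- 0
    for (g in gint) {
      kidg <- gi$kids[[g]]
      m1 <- mapped(kidg[1])[r]; m2 <- mapped(kidg[2])[r]; sv <- M[r, col_of(g)]
      spe <- spe_cost_of(sv, m1, m2); dup <- dup_cost_of(sv, m1, m2)
      trn <- trn_cost_of(sv, m1, m2)
      node <- min(spe, dup, trn)
      if (spe <= node + 1e-9) {
        nl <- nl + spe / max(L, 1e-12)
      } else if (dup <= node + 1e-9) {
        nd <- nd + 1L; nl <- nl + (dup - D) / max(L, 1e-12)
      } else {
        nt <- nt + 1L; nl <- nl + (trn - Tc) / max(L, 1e-12)
      }
    }
    c(n_duplication = nd, n_transfer = nt, n_loss = round(nl))
  }, numeric(3))))

  list(cost = best, event_counts = triples)
}

# Random small reconciliation instance, independent of the package simulator.
random_instance <- function(seed, max_leaves = 6L) {
  set.seed(seed)
  ng <- sample(3:max_leaves, 1L)
  ns <- sample(3:max_leaves, 1L)
  gt <- ape::rtree(ng, tip.label = paste0("g", seq_len(ng)), br = NULL)
  st <- ape::rtree(ns, tip.label = paste0("S", seq_len(ns)), br = NULL)
  map <- stats::setNames(sample(st$tip.label, ng, replace = TRUE), gt$tip.label)
  list(gene_tree = gt, species_tree = st, map = map)
}
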