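# Internal indexed tree structure consumed by the reconciliation dynamic
# program and the simulator. Nodes are integers; for structures derived from a
# phylo object the ape numbering is kept (tips 1..n, root n+1).

tree_index <- function(children, root, tip_labels, n_nodes) {
  parent <- rep(NA_integer_, n_nodes)
  for (v in seq_len(n_nodes)) {
    for (ch in children[[v]]) parent[ch] <- v
  }
  is_tip <- vapply(children, function(x) length(x) == 0L, logical(1))
  # iterative postorder
  post <- integer(n_nodes)
  stack <- c(root)
  seen <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    seen <- c(seen, v)
    stack <- c(stack, children[[v]])
  }
  post <- rev(seen)
  depth <- rep(NA_integer_, n_nodes)
  depth[root] <- 0L
  for (v in seen) {
    if (v != root) depth[v] <- depth[parent[v]] + 1L
  }
  post_rank <- integer(n_nodes)
  post_rank[post] <- seq_along(post)
  structure(
    list(
      n = n_nodes, root = root, children = children, parent = parent,
      is_tip = is_tip, order = post, post_rank = post_rank, depth = depth,
      tip_labels = tip_labels
    ),
    class = "hgt_tree_index"
  )
}

# Build a tree_index from a rooted binary phylo.
index_rooted_phylo <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_nodes <- n_tip + tree$Nnode
  children <- vector("list", n_nodes)
  for (v in seq_len(n_nodes)) children[[v]] <- integer(0)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    children[[p]] <- c(children[[p]], tree$edge[i, 2])
  }
  bad <- which(vapply(children, length, 1L) > 2L)
  if (length(bad)) {
    stop("tree is not binary; call binarize() first", call. = FALSE)
  }
  if (any(vapply(children, length, 1L) == 1L)) {
    stop("tree contains unifurcations; resolve before reconciling", call. = FALSE)
  }
  labs <- rep(NA_character_, n_nodes)
  labs[seq_len(n_tip)] <- tree$tip.label
  tree_index(children, n_tip + 1L, labs, n_nodes)
}

# descendant-or-self and incomparability relations as logical matrices
ancestry_matrices <- function(ti) {
  n <- ti$n
  desc <- matrix(FALSE, n, n)
  for (v in ti$order) {
    desc[v, v] <- TRUE
    for (ch in ti$children[[v]]) desc[v, ] <- desc[v, ] | desc[ch, ]
  }
  inc <- !(desc | t(desc))
  list(desc = desc, inc = inc)
}

# All edge-rootings of an unrooted phylo (basal multifurcation). Edges are
# numbered canonically by the postorder edge sequence of the input
# orientation. Returns a list of tree_index objects plus the tip relabelling
# (tip ids 1..n keep their ape identity).
enumerate_rootings <- function(tree) {
  n_tip <- length(tree$tip.label)
  if (n_tip < 3L) stop("unrooted reconciliation needs >= 3 leaves", call. = FALSE)
  tp <- ape::reorder.phylo(tree, "postorder")
  edges <- tp$edge  # canonical order
  n_nodes_in <- n_tip + tree$Nnode
  adj <- vector("list", n_nodes_in)
  for (v in seq_len(n_nodes_in)) adj[[v]] <- integer(0)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  root_id <- n_nodes_in + 1L
  labs <- rep(NA_character_, root_id)
  labs[seq_len(n_tip)] <- tree$tip.label
  lapply(seq_len(nrow(edges)), function(i) {
    a <- edges[i, 1]; b <- edges[i, 2]
    children <- vector("list", root_id)
    for (v in seq_len(root_id)) children[[v]] <- integer(0)
    orient <- function(v, from) {
      for (w in adj[[v]]) {
        if (w != from) {
          children[[v]] <<- c(children[[v]], w)
          orient(w, v)
        }
      }
    }
    children[[root_id]] <- c(a, b)
    orient(a, b)
    orient(b, a)
    ti <- tree_index(children, root_id, labs, root_id)
    ti$rooting_edge <- i
    ti
  })
}
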