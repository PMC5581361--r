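# Tree input/output and basic manipulation.
#
# Trees are carried as ape "phylo" objects throughout the package. Newick
# reading/writing is delegated to ape; this layer adds the validation the
# reconciliation pipeline depends on (unique leaf labels, non-negative branch
# lengths, rooted/unrooted flagging) plus deterministic multifurcation
# resolution and outgroup rooting.

#' Parse a newick string into a phylogenetic tree
#'
#' Labels are taken verbatim: quoting and underscore-to-space conventions are
#' deliberately not interpreted, so labels match gene/genome mapping tables
#' byte for byte. Square-bracket comments are stripped before parsing. A tree
#' whose basal node has three or more children is flagged unrooted, following
#' the usual newick convention.
#'
#' @param text A single newick string (terminated by `;`).
#' @param rooted_hint Optional logical. Overrides the structural rooted flag,
#'   e.g. `FALSE` to force a binary-rooted newick to be treated as unrooted
#'   (its root placement then carries no meaning for reconciliation).
#' @return An object of class `phylo`. Query its rootedness with
#'   [is_rooted_tree()].
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' is_rooted_tree(tr)
#' @export
parse_newick <- function(text, rooted_hint = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- strip_newick_comments(text)
  check_newick_syntax(txt)
  txt <- trimws(txt)

  # ape cannot represent a single-leaf tree parsed from "A;".
  if (grepl("^[^();,:]+;$", txt)) {
    lab <- sub(";$", "", txt)
    tree <- structure(
      list(
        edge = matrix(c(2L, 1L), 1L, 2L),
        tip.label = lab,
        Nnode = 1L
      ),
      class = "phylo", order = "cladewise"
    )
    return(validate_tree(tree, rooted_hint))
  }

  tree <- tryCatch(
    ape::read.tree(text = txt),
    error = function(e) stop("malformed newick: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree)) stop("malformed newick: parser returned no tree", call. = FALSE)
  validate_tree(tree, rooted_hint)
}

#' Read a newick tree from a file
#'
#' @param path Path to a file containing one newick tree.
#' @inheritParams parse_newick
#' @return A `phylo` object.
#' @export
read_newick <- function(path, rooted_hint = NULL) {
  if (!file.exists(path)) stop("tree file not found: ", path, call. = FALSE)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  parse_newick(txt, rooted_hint = rooted_hint)
}

#' Write a tree as a newick string
#'
#' Round-trip stable with [parse_newick()]: topology and labels are preserved
#' exactly, branch lengths to better than 12 significant digits.
#'
#' @param tree A `phylo` object.
#' @param path Optional file path; when supplied the string is also written
#'   there.
#' @return The newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) == 1L) {
    txt <- paste0(tree$tip.label, ";")
  } else {
    txt <- ape::write.tree(tree, digits = 12)
  }
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Is a tree rooted?
#'
#' Structural rootedness (binary basal node) unless the tree carries an
#' explicit flag set via `rooted_hint` at parse time.
#'
#' @param tree A `phylo` object.
#' @return Logical scalar.
#' @export
is_rooted_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  flag <- attr(tree, "rooted")
  if (!is.null(flag)) return(isTRUE(flag))
  if (length(tree$tip.label) <= 2L) return(TRUE)
  ape::is.rooted(tree)
}

#' Root a tree with an outgroup leaf
#'
#' Places the root on the edge subtending the outgroup, so the root bipartition
#' separates the outgroup from every other leaf -- the standard way a reference
#' species tree is rooted with a distant outgroup sequence. Optionally removes
#' the outgroup afterwards (the usual next step, since the outgroup is not part
#' of the genome set under study).
#'
#' @param tree A `phylo` object (rooted or unrooted).
#' @param outgroup_label Leaf label to use as outgroup.
#' @param drop_outgroup Remove the outgroup leaf (and the resulting
#'   unifurcation) after rooting? Default `FALSE`.
#' @return A rooted `phylo` object.
#' @export
root_with_outgroup <- function(tree, outgroup_label, drop_outgroup = FALSE) {
  stopifnot(inherits(tree, "phylo"), is.character(outgroup_label), length(outgroup_label) == 1L)
  if (!outgroup_label %in% tree$tip.label) {
    stop("outgroup label not found in tree: ", outgroup_label, call. = FALSE)
  }
  attr(tree, "rooted") <- NULL
  rooted <- ape::root(tree, outgroup = outgroup_label, resolve.root = TRUE)
  if (drop_outgroup) {
    rooted <- ape::drop.tip(rooted, outgroup_label, collapse.singles = TRUE)
  }
  rooted
}

#' Resolve multifurcations deterministically
#'
#' Every node with more than two children is resolved into a caterpillar by
#' combining children left to right in their input order; introduced edges get
#' branch length zero (when the tree has branch lengths). `(A,B,C)` becomes
#' `((A,B),C)` and `(A,B,C,D)` becomes `(((A,B),C),D)`. Already-binary trees
#' are returned unchanged. The resolution is purely a bookkeeping device so the
#' reconciliation dynamic program, which requires binary trees, is defined;
#' zero-length edges leave patristic distances untouched.
#'
#' @param tree A rooted `phylo` object.
#' @return A rooted binary `phylo` object over the same leaf set.
#' @export
binarize <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) <= 2L) return(tree)
  if (!is_rooted_tree(tree)) stop("binarize() requires a rooted tree", call. = FALSE)
  if (ape::is.binary.phylo(tree) && ape::is.rooted(tree)) return(tree)
  has_len <- !is.null(tree$edge.length)
  nested <- phylo_to_nested(tree)
  resolve <- function(node) {
    if (is.null(node$children)) return(node)
    node$children <- lapply(node$children, resolve)
    while (length(node$children) > 2L) {
      pair <- list(
        label = NA_character_,
        length = if (has_len) 0 else NA_real_,
        children = node$children[1:2]
      )
      node$children <- c(list(pair), node$children[-(1:2)])
    }
    node
  }
  out <- parse_newick(nested_to_newick(resolve(nested)))
  attr(out, "rooted") <- NULL
  out
}

#' Patristic distance matrix
#'
#' Sum of branch lengths along the path between every pair of leaves. Used by
#' the gene-set filters as a screen for trees whose leaves are all essentially
#' identical (near-zero pairwise distances).
#'
#' @param tree A `phylo` object with branch lengths on all edges.
#' @return A symmetric numeric matrix with zero diagonal, rows/columns named by
#'   leaf label in the tree's tip order.
#' @export
patristic_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  if (n == 1L) {
    return(matrix(0, 1L, 1L, dimnames = list(tree$tip.label, tree$tip.label)))
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("patristic_distances() requires branch lengths on all edges", call. = FALSE)
  }
  d <- ape::dist.nodes(tree)[seq_len(n), seq_len(n), drop = FALSE]
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}

#' Read a gene-to-genome mapping table
#'
#' Two tab-separated columns, `gene_id` and `genome_id`; a header row is
#' detected and skipped if present.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `gene_id`, `genome_id`.
#' @export
read_gene_species_map <- function(path) {
  if (!file.exists(path)) stop("mapping file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  has_header <- grepl("^gene_id\t", first)
  tab <- readr::read_tsv(
    path,
    col_names = if (has_header) TRUE else c("gene_id", "genome_id"),
    col_types = readr::cols(.default = readr::col_character()),
    skip = 0L, progress = FALSE
  )
  if (ncol(tab) < 2L) stop("mapping TSV must have two columns", call. = FALSE)
  tibble::tibble(gene_id = tab[[1]], genome_id = tab[[2]])
}

#' Read a gene-set manifest
#'
#' @param path Path to a TSV with columns `gene_set_id` and `path` (tree file
#'   per gene set, relative to the manifest's directory unless absolute).
#' @return A tibble with columns `gene_set_id`, `path` (absolute paths).
#' @export
read_tree_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  stopifnot(all(c("gene_set_id", "path") %in% names(tab)))
  base <- dirname(normalizePath(path))
  tab$path <- ifelse(grepl("^/", tab$path), tab$path, file.path(base, tab$path))
  tibble::as_tibble(tab[, c("gene_set_id", "path")])
}

#' Check a gene-to-genome map against a gene tree and species tree
#'
#' The map must be total on the gene tree's leaves, and every image genome must
#' be a leaf of the species tree.
#'
#' @param gene_tree,species_tree `phylo` objects.
#' @param map A data frame with columns `gene_id`, `genome_id`, or a named
#'   character vector (names = gene ids).
#' @return A named character vector gene id -> genome id, invisibly checked.
#' @export
validate_gene_species_map <- function(gene_tree, species_tree, map) {
  m <- as_map_vector(map)
  missing <- setdiff(gene_tree$tip.label, names(m))
  if (length(missing)) {
    stop("mapping is not total on gene leaves; missing: ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  m <- m[gene_tree$tip.label]
  bad <- setdiff(unname(m), species_tree$tip.label)
  if (length(bad)) {
    stop("mapped genomes absent from species tree: ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  m
}

# --- internal helpers -------------------------------------------------------

as_map_vector <- function(map) {
  if (is.data.frame(map)) {
    stopifnot(all(c("gene_id", "genome_id") %in% names(map)))
    if (anyDuplicated(map$gene_id)) {
      # A global mapping table may carry rows for genes outside this tree;
      # duplicates among them are fine, duplicates for one gene id are not.
      dup <- unique(map$gene_id[duplicated(map$gene_id)])
      sub <- map[map$gene_id %in% dup, , drop = FALSE]
      if (nrow(unique(sub)) != length(dup)) {
        stop("conflicting genome assignments for gene ids: ",
             paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
      }
      map <- unique(map)
    }
    stats::setNames(as.character(map$genome_id), as.character(map$gene_id))
  } else if (is.character(map) && !is.null(names(map))) {
    map
  } else {
    stop("map must be a data frame with gene_id/genome_id or a named character vector",
         call. = FALSE)
  }
}

strip_newick_comments <- function(text) gsub("\\[[^]]*\\]", "", text)

check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("malformed newick: unmatched ')' at position ", i, call. = FALSE)
      }
    }
  }
  if (depth > 0L) {
    stop("malformed newick: ", depth, " unclosed '(' at end of string", call. = FALSE)
  }
  if (!grepl(";", text, fixed = TRUE)) {
    stop("malformed newick: missing terminating ';' at position ",
         nchar(text), call. = FALSE)
  }
  invisible(TRUE)
}

validate_tree <- function(tree, rooted_hint = NULL) {
  labs <- tree$tip.label
  if (any(!nzchar(labs)) || anyNA(labs)) {
    stop("invalid newick: empty leaf label", call. = FALSE)
  }
  if (anyDuplicated(labs)) {
    stop("duplicate leaf labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "), call. = FALSE)
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0, na.rm = TRUE)) {
    stop("negative branch lengths are not allowed", call. = FALSE)
  }
  if (!is.null(rooted_hint)) {
    stopifnot(is.logical(rooted_hint), length(rooted_hint) == 1L)
    attr(tree, "rooted") <- rooted_hint
  }
  tree
}

# Nested-list view of a rooted phylo: list(label, length, children). Child
# order follows the edge matrix, which preserves input order for trees read
# with ape.
phylo_to_nested <- function(tree) {
  n_tip <- length(tree$tip.label)
  has_len <- !is.null(tree$edge.length)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  build <- function(node, edge_idx) {
    len <- if (!is.null(edge_idx) && has_len) tree$edge.length[edge_idx] else NA_real_
    if (node <= n_tip) {
      return(list(label = tree$tip.label[node], length = len, children = NULL))
    }
    kid_edges <- children[[as.character(node)]]
    kid_edges <- kid_edges[order(kid_edges)]  # input order
    list(
      label = NA_character_,
      length = len,
      children = lapply(kid_edges, function(e) build(tree$edge[e, 2], e))
    )
  }
  build(n_tip + 1L, NULL)
}

nested_to_newick <- function(node) {
  render <- function(nd) {
    core <- if (is.null(nd$children)) {
      nd$label
    } else {
      paste0("(", paste(vapply(nd$children, render, character(1)), collapse = ","), ")")
    }
    if (!is.na(nd$length)) {
      core <- paste0(core, ":", format(nd$length, digits = 12, scientific = FALSE))
    }
    core
  }
  paste0(render(node), ";")
}
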