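# End-to-end pipeline: bundle in, per-gene-set records and summaries out.

#' Run the HGT-index pipeline on an input bundle
#'
#' For every gene set in the manifest: parse the tree, apply the exclusion
#' filters, reconcile included sets against the species tree under undated DTL
#' parsimony, compute the HGT-index, classify as HGT-gene or HGT-free, and
#' attach Pfam/phylum annotations. One malformed gene set does not abort the
#' run: it is quarantined with status `"errored"` and the error message.
#'
#' Every gene set ends up in exactly one of: excluded (with its reason), the
#' HGT-gene list, the HGT-free list, or the errored quarantine. Given fixed
#' inputs and configuration the output is fully deterministic.
#'
#' @param bundle_dir Directory holding `species.nwk`, `manifest.tsv`,
#'   `mapping.tsv` and optionally `annotations.tsv`, `metadata.tsv` (the
#'   layout written by [simulate_collection()]). Individual paths may be
#'   overridden.
#' @param species_tree,manifest,mapping,annotations,metadata Optional explicit
#'   paths overriding the bundle layout (`annotations`/`metadata` may be
#'   `NA` to skip).
#' @param out_dir Optional output directory; when given, records, the
#'   HGT-gene/HGT-free/excluded lists, both top-k tables, keyword counts and
#'   the run summary are written as TSV (summary also as JSON).
#' @param costs A [dtl_costs()].
#' @param filters An [hgt_filter_config()]; by default
#'   `total_available_genomes` is set to the species tree's leaf count.
#' @param outgroup Optional leaf label used to root the species tree (the
#'   outgroup is dropped after rooting). Required if the species tree arrives
#'   unrooted.
#' @param top_k Rows in the top tables, default 20.
#' @param keywords GO keyword panel, default [hgt_keywords()].
#' @return An object of class `hgt_run`: a list with `records` (tibble, one
#'   row per gene set), `summary` (one-row tibble), `top_by_index`,
#'   `top_by_genomes`, `keyword_counts`, and `n_errored`.
#' @export
run_hgt_pipeline <- function(bundle_dir = NULL,
                             species_tree = NULL, manifest = NULL,
                             mapping = NULL, annotations = NULL,
                             metadata = NULL, out_dir = NULL,
                             costs = dtl_costs(), filters = NULL,
                             outgroup = NULL, top_k = 20L,
                             keywords = hgt_keywords()) {
  path_or <- function(explicit, name, required = TRUE) {
    if (!is.null(explicit)) return(explicit)
    if (is.null(bundle_dir)) {
      if (required) stop("supply bundle_dir or an explicit path for ", name, call. = FALSE)
      return(NA_character_)
    }
    p <- file.path(bundle_dir, name)
    if (!file.exists(p)) {
      if (required) stop("input not found: ", p, call. = FALSE)
      return(NA_character_)
    }
    p
  }
  sp_path <- path_or(species_tree, "species.nwk")
  mf_path <- path_or(manifest, "manifest.tsv")
  map_path <- path_or(mapping, "mapping.tsv")
  ann_path <- path_or(annotations, "annotations.tsv", required = FALSE)
  meta_path <- path_or(metadata, "metadata.tsv", required = FALSE)

  sp <- read_newick(sp_path)
  if (!is.null(outgroup)) {
    sp <- root_with_outgroup(sp, outgroup, drop_outgroup = TRUE)
  }
  if (!is_rooted_tree(sp)) {
    stop("species tree is unrooted; supply `outgroup`", call. = FALSE)
  }
  if (!ape::is.binary.phylo(sp)) {
    warning("species tree has multifurcations; resolving deterministically",
            call. = FALSE)
    sp <- binarize(sp)
  }
  mf <- read_tree_manifest(mf_path)
  map_tab <- read_gene_species_map(map_path)
  ann_tab <- if (!is.na(ann_path)) read_annotations(ann_path) else NULL
  meta_tab <- if (!is.na(meta_path)) read_genome_metadata(meta_path) else NULL
  if (is.null(filters)) {
    filters <- hgt_filter_config(total_available_genomes = length(sp$tip.label))
  }

  rows <- purrr::map(seq_len(nrow(mf)), function(i) {
    set_id <- mf$gene_set_id[i]
    tryCatch(
      process_gene_set(set_id, mf$path[i], sp, map_tab, ann_tab, meta_tab,
                       costs, filters),
      error = function(e) {
        tibble::tibble(
          gene_set_id = set_id, n_genes = NA_integer_, n_genomes = NA_integer_,
          n_transfers = NA_integer_, hgt_index = NA_real_,
          status = "errored", hgt_class = "not_applicable",
          cost = NA_real_, n_duplication = NA_integer_, n_loss = NA_integer_,
          ties = NA, pfam_ids = NA_character_, phyla = NA_character_,
          error = conditionMessage(e)
        )
      }
    )
  })
  records <- dplyr::bind_rows(rows)
  run_summary <- summarize_run(records)
  top_idx <- rank_records(dplyr::filter(records, .data$hgt_class == "hgt_gene"),
                          by = "hgt_index", top_k = top_k)
  top_gen <- rank_records(dplyr::filter(records, .data$hgt_class == "hgt_gene"),
                          by = "n_genomes", top_k = top_k)
  kw <- if (!is.null(ann_tab)) {
    hgt_sets <- records$gene_set_id[records$hgt_class == "hgt_gene"]
    set_of <- sub("\\|.*$", "", ann_tab$gene_id)
    terms <- unlist(ann_tab$go_bp_terms[set_of %in% hgt_sets])
    count_keywords(terms, keywords)
  } else {
    tibble::tibble(keyword = character(), count = integer())
  }

  res <- structure(
    list(records = records, summary = run_summary,
         top_by_index = top_idx, top_by_genomes = top_gen,
         keyword_counts = kw,
         n_errored = sum(records$status == "errored")),
    class = "hgt_run"
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    w <- function(x, f) readr::write_tsv(x, file.path(out_dir, f), progress = FALSE)
    w(records, "records.tsv")
    w(dplyr::filter(records, .data$hgt_class == "hgt_gene"), "hgt_genes.tsv")
    w(dplyr::filter(records, .data$hgt_class == "hgt_free"), "hgt_free.tsv")
    w(dplyr::filter(records, startsWith(.data$status, "excluded:")), "excluded.tsv")
    w(top_idx, "top_by_index.tsv")
    w(top_gen, "top_by_genomes.tsv")
    w(kw, "keyword_counts.tsv")
    w(run_summary, "summary.tsv")
    jsonlite::write_json(as.list(run_summary), file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

process_gene_set <- function(set_id, tree_path, species_tree, map_tab,
                             ann_tab, meta_tab, costs, filters) {
  gt <- read_newick(tree_path)
  sub_map <- map_tab[map_tab$gene_id %in% gt$tip.label, , drop = FALSE]
  m <- validate_gene_species_map(gt, species_tree, sub_map)
  genomes <- unique(unname(m))
  status <- apply_filters(gt, m, filters, metadata = meta_tab)
  # the reference tree for a gene set spans exactly its member genomes (a
  # pruned copy of the global species tree), so absent genomes are not
  # charged as losses
  sp_set <- if (length(genomes) < length(species_tree$tip.label)) {
    ape::keep.tip(species_tree, genomes)
  } else {
    species_tree
  }

  n_transfers <- NA_integer_
  idx <- NA_real_
  cost <- NA_real_
  n_dup <- NA_integer_
  n_loss <- NA_integer_
  ties <- NA
  if (status == "included") {
    gt_bin <- if (is_rooted_tree(gt) && !ape::is.binary.phylo(gt)) {
      warning("gene set ", set_id, ": multifurcations resolved deterministically",
              call. = FALSE)
      binarize(gt)
    } else gt
    rec <- reconcile_dtl(gt_bin, sp_set, m, costs)
    n_transfers <- rec$n_transfer
    idx <- compute_hgt_index(n_transfers, length(genomes))
    cost <- rec$cost
    n_dup <- rec$n_duplication
    n_loss <- rec$n_loss
    ties <- rec$ties
  }

  pfams <- if (!is.null(ann_tab)) {
    sub_ann <- ann_tab[ann_tab$gene_id %in% gt$tip.label, , drop = FALSE]
    if (nrow(sub_ann)) paste(assign_pfam_majority(sub_ann), collapse = ",") else ""
  } else ""
  phyla <- if (!is.null(meta_tab)) {
    paste(aggregate_phyla(genomes, meta_tab), collapse = ",")
  } else ""

  tibble::tibble(
    gene_set_id = set_id,
    n_genes = length(gt$tip.label),
    n_genomes = length(genomes),
    n_transfers = n_transfers,
    hgt_index = idx,
    status = status,
    hgt_class = classify_hgt(status, n_transfers),
    cost = cost, n_duplication = n_dup, n_loss = n_loss, ties = ties,
    pfam_ids = pfams, phyla = phyla,
    error = NA_character_
  )
}

#' @export
print.hgt_run <- function(x, ...) {
  s <- x$summary
  cat("HGT-index pipeline run\n")
  cat(sprintf("  gene sets: %d (%d excluded [%d%%], %d included, %d errored)\n",
              s$n_total, s$n_excluded, s$pct_excluded, s$n_included, s$n_errored))
  cat(sprintf("  included: %d HGT-genes (%d%%), %d HGT-free (%d%%)\n",
              s$n_hgt_gene, s$pct_hgt_gene, s$n_hgt_free, s$pct_hgt_free))
  invisible(x)
}

#' Re-derive a run summary from a records table
#'
#' @param records A records tibble (as produced by [run_hgt_pipeline()]) or a
#'   path to a written `records.tsv`.
#' @return A one-row summary tibble, identical to the pipeline's own summary
#'   for the same records.
#' @export
summarize_records <- function(records) {
  if (is.character(records)) {
    records <- readr::read_tsv(records, show_col_types = FALSE, progress = FALSE)
  }
  summarize_run(records)
}
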