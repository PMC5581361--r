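# Per-gene-set HGT statistic, exclusion filters, classification and run
# summaries. All functions are tibble-in / tibble-out where the input is
# naturally tabular.

#' HGT-index of a gene set
#'
#' The number of inferred transfer events on a gene tree divided by the number
#' of member genomes (taxa). With one gene per genome the index is bounded by
#' (n - 1) / n and therefore always below 1. Values are returned at full
#' precision; the reporting layer rounds to 3 decimals.
#'
#' @param n_transfers Non-negative integer vector of transfer-event counts.
#' @param n_genomes Positive integer vector of genome counts (recycled).
#' @return Numeric vector `n_transfers / n_genomes`.
#' @examples
#' compute_hgt_index(153, 191)  # 0.801 at 3 decimals
#' @export
compute_hgt_index <- function(n_transfers, n_genomes) {
  stopifnot(is.numeric(n_transfers), is.numeric(n_genomes))
  if (any(n_genomes < 1)) stop("n_genomes must be >= 1", call. = FALSE)
  if (any(n_transfers < 0)) stop("n_transfers must be >= 0", call. = FALSE)
  n_transfers / n_genomes
}

#' Gene-set filter configuration
#'
#' Thresholds for the exclusion screens applied before reconciliation results
#' are interpreted:
#' * `min_taxa`: sets with fewer genomes are excluded (inclusive keep at
#'   `n >= min_taxa`); small sets make the index incomparable across genes
#'   (two transfers among four genomes already yield 0.5).
#' * `max_genome_fraction`: sets covering strictly more than this fraction of
#'   all available genomes are excluded.
#' * `total_available_genomes`: denominator for the fraction screen; defaults
#'   to the 2,472 completely sequenced prokaryotic genomes of the reference
#'   corpus, and is normally set to the species tree's leaf count.
#' * `zero_distance_epsilon`: a set is excluded when every pairwise patristic
#'   distance on its gene tree is below this value (no signal to reconcile).
#'
#' @param min_taxa Integer >= 2, default 10.
#' @param max_genome_fraction Fraction in (0, 1], default 0.5 (strict
#'   comparison: exactly 50% is kept).
#' @param total_available_genomes Positive integer, default 2472.
#' @param zero_distance_epsilon Non-negative number, default 1e-6.
#' @return A list of class `hgt_filter_config`.
#' @export
hgt_filter_config <- function(min_taxa = 10L, max_genome_fraction = 0.5,
                              total_available_genomes = 2472L,
                              zero_distance_epsilon = 1e-6) {
  stopifnot(
    min_taxa >= 2,
    max_genome_fraction > 0, max_genome_fraction <= 1,
    total_available_genomes >= 1,
    zero_distance_epsilon >= 0
  )
  structure(
    list(
      min_taxa = as.integer(min_taxa),
      max_genome_fraction = max_genome_fraction,
      total_available_genomes = as.integer(total_available_genomes),
      zero_distance_epsilon = zero_distance_epsilon
    ),
    class = "hgt_filter_config"
  )
}

#' Apply the gene-set exclusion filters
#'
#' Screens are applied in a fixed, documented order and the first failure is
#' reported: `single_species`, then `zero_distance`, then `min_taxa`, then
#' `max_fraction`. A 5-genome single-species set is therefore reported as
#' `excluded:single_species`, not `excluded:min_taxa`.
#'
#' The single-species screen uses genome labels unless `metadata` supplies a
#' `species` column, in which case genomes are collapsed to species first.
#' The zero-distance screen needs branch lengths; when they are absent it is
#' skipped with a warning.
#'
#' @param gene_tree The gene set's `phylo` tree.
#' @param map Gene-to-genome map (data frame or named character vector) for
#'   this gene set.
#' @param cfg An [hgt_filter_config()].
#' @param metadata Optional tibble with columns `genome_id` and `species`.
#' @return A status string: `"included"` or one of
#'   `"excluded:single_species"`, `"excluded:zero_distance"`,
#'   `"excluded:min_taxa"`, `"excluded:max_fraction"`.
#' @export
apply_filters <- function(gene_tree, map, cfg = hgt_filter_config(),
                          metadata = NULL) {
  stopifnot(inherits(gene_tree, "phylo"), inherits(cfg, "hgt_filter_config"))
  m <- as_map_vector(map)
  genomes <- unique(unname(m[gene_tree$tip.label]))

  units <- genomes
  if (!is.null(metadata) && "species" %in% names(metadata)) {
    sp <- metadata$species[match(genomes, metadata$genome_id)]
    if (!anyNA(sp)) units <- unique(sp)
  }
  if (length(units) == 1L) return("excluded:single_species")

  if (is.null(gene_tree$edge.length) || anyNA(gene_tree$edge.length)) {
    warning("gene tree has no branch lengths; zero-distance screen skipped",
            call. = FALSE)
  } else if (length(gene_tree$tip.label) >= 2L) {
    d <- patristic_distances(gene_tree)
    if (max(d) < cfg$zero_distance_epsilon) return("excluded:zero_distance")
  }

  if (length(genomes) < cfg$min_taxa) return("excluded:min_taxa")
  if (length(genomes) > cfg$max_genome_fraction * cfg$total_available_genomes) {
    return("excluded:max_fraction")
  }
  "included"
}

#' Classify gene sets as HGT-genes or HGT-free
#'
#' An included gene set with at least one inferred transfer shows detectable
#' gene/species tree conflict and is an HGT-gene; an included set with zero
#' transfers is (tentatively) HGT-free. Excluded sets are `not_applicable`.
#'
#' @param status Character vector of filter statuses (see [apply_filters()]).
#' @param n_transfers Integer vector of transfer counts (NA allowed for
#'   excluded or errored sets).
#' @return Character vector in `{"hgt_gene", "hgt_free", "not_applicable"}`.
#' @export
classify_hgt <- function(status, n_transfers) {
  stopifnot(length(status) == length(n_transfers))
  dplyr::case_when(
    status != "included" ~ "not_applicable",
    n_transfers >= 1 ~ "hgt_gene",
    TRUE ~ "hgt_free"
  )
}

#' Rank gene-set records
#'
#' Stable descending sort on `hgt_index` or `n_genomes`, ties broken by
#' `gene_set_id` in lexicographic order; used for the "top-k highest index"
#' and "top-k largest sets" tables.
#'
#' @param records Tibble with at least `gene_set_id` and the ranking column.
#' @param by `"hgt_index"` (default) or `"n_genomes"`.
#' @param top_k Number of rows to return, default 20.
#' @return The first `top_k` rows of the sorted tibble.
#' @export
rank_records <- function(records, by = c("hgt_index", "n_genomes"), top_k = 20L) {
  by <- match.arg(by)
  stopifnot(is.data.frame(records))
  if (!nrow(records)) return(tibble::as_tibble(records))
  records |>
    dplyr::arrange(dplyr::desc(.data[[by]]), .data$gene_set_id) |>
    dplyr::slice_head(n = top_k)
}

#' Summarise a pipeline run
#'
#' Counts and percentages over a records table: exclusions (by reason) as a
#' percentage of all gene sets, HGT-gene and HGT-free as percentages of the
#' retained (included) sets. Percentages are rounded to the nearest integer;
#' raw fractions are reported alongside.
#'
#' @param records Tibble with columns `status` and `hgt_class` (one row per
#'   gene set).
#' @return A one-row tibble with counts (`n_total`, `n_excluded`,
#'   `n_excluded_*`, `n_included`, `n_hgt_gene`, `n_hgt_free`, `n_errored`)
#'   and percentages (`pct_excluded`, `pct_hgt_gene`, `pct_hgt_free`).
#' @export
summarize_run <- function(records) {
  stopifnot(is.data.frame(records), all(c("status", "hgt_class") %in% names(records)))
  st <- records$status
  n_total <- length(st)
  n_errored <- sum(st == "errored")
  n_excluded <- sum(startsWith(st, "excluded:"))
  n_included <- sum(st == "included")
  n_hgt <- sum(records$hgt_class == "hgt_gene", na.rm = TRUE)
  n_free <- sum(records$hgt_class == "hgt_free", na.rm = TRUE)
  pct <- function(num, den) if (den > 0) round(100 * num / den) else 0
  tibble::tibble(
    n_total = n_total,
    n_excluded = n_excluded,
    n_excluded_single_species = sum(st == "excluded:single_species"),
    n_excluded_zero_distance = sum(st == "excluded:zero_distance"),
    n_excluded_min_taxa = sum(st == "excluded:min_taxa"),
    n_excluded_max_fraction = sum(st == "excluded:max_fraction"),
    n_included = n_included,
    n_hgt_gene = n_hgt,
    n_hgt_free = n_free,
    n_errored = n_errored,
    frac_excluded = if (n_total > 0) n_excluded / n_total else 0,
    frac_hgt_gene = if (n_included > 0) n_hgt / n_included else 0,
    frac_hgt_free = if (n_included > 0) n_free / n_included else 0,
    pct_excluded = pct(n_excluded, n_total),
    pct_hgt_gene = pct(n_hgt, n_included),
    pct_hgt_free = pct(n_free, n_included)
  )
}
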