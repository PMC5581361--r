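# Pfam majority-rule assignment, GO biological-process keyword counts and
# phylum aggregation over gene sets.

#' Default GO biological-process keywords
#'
#' The keyword panel used to summarise the functions of HGT-genes: broad
#' process words (metabolic, transport, transcription, transduction,
#' translation) plus clinically and mechanistically interesting ones
#' (antibiotic, toxin, stress, homeostasis, rRNA, transposition).
#'
#' @return Character vector of keywords.
#' @export
hgt_keywords <- function() {
  c("metabolic", "transport", "transcription", "transduction", "translation",
    "antibiotic", "toxin", "stress", "homeostasis", "rRNA", "transposition")
}

#' Read a gene annotation table
#'
#' Tab-separated columns `gene_id`, `pfam_ids` (comma-joined, may be empty)
#' and `go_bp_terms` (pipe-joined, may be empty); a header row is detected by
#' the first field.
#'
#' @param path Path to the TSV file.
#' @return A tibble with `gene_id` (character) and list-columns `pfam_ids`,
#'   `go_bp_terms`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  has_header <- grepl("^gene_id\t", first)
  tab <- readr::read_tsv(
    path,
    col_names = if (has_header) TRUE else c("gene_id", "pfam_ids", "go_bp_terms"),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (ncol(tab) < 3L) stop("annotation TSV must have three columns", call. = FALSE)
  split_field <- function(x, sep) {
    lapply(x, function(v) {
      if (is.na(v) || !nzchar(v)) character(0) else strsplit(v, sep, fixed = TRUE)[[1]]
    })
  }
  out <- tibble::tibble(
    gene_id = tab[[1]],
    pfam_ids = split_field(tab[[2]], ","),
    go_bp_terms = split_field(tab[[3]], "|")
  )
  if (anyDuplicated(out$gene_id)) {
    stop("duplicate gene_id in annotation table", call. = FALSE)
  }
  out
}

#' Majority-rule Pfam assignment for a gene set
#'
#' A Pfam family is assigned to a gene set when at least `threshold` of its
#' member genes carry that family (80% by default). Several families can pass
#' simultaneously (multi-domain gene sets). By default the denominator is all
#' member genes, unannotated ones included; set `denominator = "annotated"` to
#' count only genes with at least one Pfam hit.
#'
#' @param annotations Tibble of the gene set's members with a `pfam_ids`
#'   list-column (as from [read_annotations()]), or a list of character
#'   vectors (one per gene).
#' @param threshold Fraction in (0, 1], default 0.8.
#' @param denominator `"all"` (default) or `"annotated"`.
#' @return Character vector of assigned Pfam ids, lexicographically sorted;
#'   empty when none pass.
#' @export
assign_pfam_majority <- function(annotations, threshold = 0.8,
                                 denominator = c("all", "annotated")) {
  denominator <- match.arg(denominator)
  stopifnot(threshold > 0, threshold <= 1)
  sets <- if (is.data.frame(annotations)) {
    stopifnot("pfam_ids" %in% names(annotations))
    annotations$pfam_ids
  } else {
    annotations
  }
  if (!length(sets)) stop("empty annotation list", call. = FALSE)
  sets <- lapply(sets, function(x) unique(as.character(x)))
  n <- if (denominator == "all") {
    length(sets)
  } else {
    sum(vapply(sets, length, 1L) > 0L)
  }
  if (n == 0L) return(character(0))
  counts <- table(unlist(sets))
  sort(names(counts)[counts / n >= threshold])
}

#' Count keyword occurrences in GO term names
#'
#' Case-insensitive substring match of each keyword against each term name;
#' keywords shorter than 5 characters (e.g. "rRNA") require a whole-token
#' match so that "rRNA" does not count "tRNA processing". Each term occurrence
#' contributes at most once per keyword but may contribute to several
#' keywords. Duplicate terms in the input count as separate occurrences.
#'
#' @param terms Character vector of GO biological-process term names.
#' @param keywords Non-empty character vector; default [hgt_keywords()].
#' @return A tibble with columns `keyword` and `count`, in keyword order.
#' @export
count_keywords <- function(terms, keywords = hgt_keywords()) {
  stopifnot(is.character(keywords), length(keywords) > 0)
  terms <- as.character(terms)
  lower_terms <- tolower(terms)
  token_lists <- strsplit(lower_terms, "[^a-z0-9]+")
  counts <- vapply(keywords, function(kw) {
    kl <- tolower(kw)
    if (nchar(kw) >= 5L) {
      sum(stringr::str_detect(lower_terms, stringr::fixed(kl)))
    } else {
      sum(vapply(token_lists, function(tok) kl %in% tok, logical(1)))
    }
  }, numeric(1))
  tibble::tibble(keyword = keywords, count = as.integer(counts))
}

#' Read a genome metadata table
#'
#' Tab-separated columns `genome_id`, `phylum` and optionally `species`.
#'
#' @param path Path to the TSV file.
#' @return A tibble with `genome_id`, `phylum` and, when present, `species`.
#' @export
read_genome_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L, warn = FALSE)
  has_header <- grepl("^genome_id\t", first)
  tab <- readr::read_tsv(
    path,
    col_names = if (has_header) TRUE else c("genome_id", "phylum", "species")[
      seq_len(length(strsplit(first, "\t", fixed = TRUE)[[1]]))],
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  tibble::as_tibble(tab)
}

#' Phyla represented in a gene set
#'
#' @param genomes Character vector of member genome ids.
#' @param metadata Tibble with columns `genome_id`, `phylum`; genomes without
#'   metadata are recorded as `"unknown"`.
#' @return Deduplicated, lexicographically sorted character vector of phyla.
#' @export
aggregate_phyla <- function(genomes, metadata = NULL) {
  genomes <- unique(as.character(genomes))
  if (is.null(metadata) || !nrow(metadata)) {
    return(if (length(genomes)) "unknown" else character(0))
  }
  stopifnot(all(c("genome_id", "phylum") %in% names(metadata)))
  ph <- metadata$phylum[match(genomes, metadata$genome_id)]
  ph[is.na(ph)] <- "unknown"
  sort(unique(ph))
}
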