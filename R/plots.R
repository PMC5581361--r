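# ggplot2 helpers for pipeline results.

#' Histogram of HGT-indices by class
#'
#' @param records Records tibble from [run_hgt_pipeline()].
#' @param binwidth Histogram bin width, default 0.05.
#' @return A ggplot object.
#' @export
plot_hgt_index <- function(records, binwidth = 0.05) {
  stopifnot(is.data.frame(records))
  dat <- dplyr::filter(records, .data$hgt_class %in% c("hgt_gene", "hgt_free"))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$hgt_index, fill = .data$hgt_class)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0, position = "stack") +
    ggplot2::labs(x = "HGT-index (transfers / genomes)", y = "gene sets",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of GO keyword counts
#'
#' @param keyword_counts Tibble with `keyword`, `count` (see
#'   [count_keywords()]).
#' @return A ggplot object.
#' @export
plot_keyword_counts <- function(keyword_counts) {
  stopifnot(is.data.frame(keyword_counts))
  ggplot2::ggplot(keyword_counts,
                  ggplot2::aes(x = stats::reorder(.data$keyword, .data$count),
                               y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "GO term occurrences") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a pipeline run
#'
#' Composition of the run: gene sets by status/class.
#'
#' @param object An `hgt_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hgt_run
#' @export
autoplot.hgt_run <- function(object, ...) {
  rec <- object$records
  lab <- ifelse(rec$hgt_class %in% c("hgt_gene", "hgt_free"),
                rec$hgt_class, rec$status)
  dat <- dplyr::count(tibble::tibble(outcome = lab), .data$outcome)
  ggplot2::ggplot(dat, ggplot2::aes(x = stats::reorder(.data$outcome, .data$n),
                                    y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "gene sets") +
    ggplot2::theme_minimal()
}
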