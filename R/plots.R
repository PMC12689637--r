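# ggplot2 views of the main result types.

#' Plot the link-weight distribution of a wTO network
#'
#' Histogram of signed wTO weights with the hard-threshold cutoffs marked,
#' the usual diagnostic for choosing/justifying a weight cutoff.
#'
#' @param object a `wto_network`.
#' @param cutoff cutoff to mark (dashed lines at +/- cutoff), default 0.5.
#' @param ... unused.
#' @return A ggplot.
#' @export
#' @method autoplot wto_network
autoplot.wto_network <- function(object, cutoff = 0.5, ...) {
  ggplot(as_tibble(object), aes(x = .data$wto)) +
    geom_histogram(bins = 60, fill = "grey35") +
    geom_vline(xintercept = c(-cutoff, cutoff), linetype = "dashed", colour = "red") +
    labs(x = "signed wTO weight", y = "links") +
    theme_minimal()
}

#' Plot differential link category composition
#'
#' Stacked relative-abundance bars of conserved / condition-specific /
#' reversed links, overall or per group when a grouping is supplied.
#'
#' @param object a `diff_links` table from [classify_links()].
#' @param grouping optional node grouping (see [category_abundance()]);
#'   when given, one bar per group.
#' @param ... unused.
#' @return A ggplot.
#' @export
#' @method autoplot diff_links
autoplot.diff_links <- function(object, grouping = NULL, ...) {
  if (is.null(grouping)) {
    df <- as_tibble(object) |>
      dplyr::filter(.data$category != "none") |>
      dplyr::count(.data$category, name = "n_links") |>
      dplyr::mutate(group = "all", fraction = .data$n_links / sum(.data$n_links))
  } else {
    df <- category_abundance(object, grouping)
  }
  ggplot(df, aes(x = factor(.data$group), y = .data$fraction, fill = .data$category)) +
    geom_col(position = "stack") +
    scale_fill_manual(values = c(
      conserved = "#4477AA", specific_A = "#EE6677",
      specific_B = "#228833", reversed = "#CCBB44", none = "grey80"
    ), drop = TRUE) +
    labs(x = "group", y = "relative abundance", fill = "link category") +
    theme_minimal()
}

#' Dot plot of cluster enrichment results
#'
#' Clusters against terms; dot size is the number of hits, colour the
#' BH-adjusted p-value. Only tested (cluster, term) pairs appear.
#'
#' @param object an `enrichment_table` from [cluster_enrichment()].
#' @param max_padj hide pairs with adjusted p above this (default 1: show
#'   all).
#' @param ... unused.
#' @return A ggplot.
#' @export
#' @method autoplot enrichment_table
autoplot.enrichment_table <- function(object, max_padj = 1, ...) {
  df <- dplyr::filter(as_tibble(object), .data$padj <= max_padj)
  ggplot(df, aes(x = factor(.data$cluster), y = .data$term)) +
    geom_point(aes(size = .data$k, colour = .data$padj)) +
    scale_colour_gradient(low = "#B2182B", high = "#2166AC") +
    labs(x = "cluster", y = NULL, size = "genes", colour = "adj. p") +
    theme_minimal()
}

#' Plot the filtering / integration bookkeeping
#'
#' Link counts per network across the pipeline stages (before filtering,
#' after filtering, consensus), one line per network.
#'
#' @param bookkeeping the `bookkeeping` tibble of a `consenet_result`.
#' @return A ggplot.
#' @export
plot_network_sizes <- function(bookkeeping) {
  df <- bookkeeping |>
    dplyr::mutate(stage = factor(.data$stage, levels = c("before", "after", "consensus")))
  ggplot(df, aes(x = .data$stage, y = .data$links, group = .data$network,
                 colour = .data$network)) +
    geom_line() +
    geom_point() +
    scale_y_log10() +
    labs(x = NULL, y = "links (log scale)") +
    theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
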