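#' Classify links between two condition networks
#'
#' Compares the consensus networks of two conditions link by link. Genes
#' absent from one network are added with zero-weight links (so a gene
#' dropping out of one condition is read as losing its correlations there,
#' not as missing data). A link is *present* in a network when its
#' absolute weight is at least `cutoff` (boundary included). Categories:
#' * `conserved` — present in both conditions with the same sign,
#' * `specific_A` / `specific_B` — present in exactly one condition,
#' * `reversed` — present in both with opposite signs,
#' * `none` — present in neither (possible when inputs carry sub-cutoff
#'   weights).
#'
#' @param net_a,net_b `consensus_network` (or `wto_network`) objects for
#'   conditions A and B.
#' @param cutoff minimum absolute weight for a link to count as present,
#'   default 0.33.
#' @return A `diff_links` tibble: `node1`, `node2`, `omega_a`, `omega_b`,
#'   `category` (factor).
#' @export
classify_links <- function(net_a, net_b, cutoff = 0.33) {
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= 1) abort("`cutoff` must be in (0, 1)")
  ea <- extract_edges(net_a, "omega_a")
  eb <- extract_edges(net_b, "omega_b")
  merged <- dplyr::full_join(ea, eb, by = c("node1", "node2"))
  merged$omega_a[is.na(merged$omega_a)] <- 0
  merged$omega_b[is.na(merged$omega_b)] <- 0
  in_a <- abs(merged$omega_a) >= cutoff
  in_b <- abs(merged$omega_b) >= cutoff
  same <- sign(merged$omega_a) == sign(merged$omega_b)
  category <- dplyr::case_when(
    in_a & in_b & same ~ "conserved",
    in_a & in_b & !same ~ "reversed",
    in_a & !in_b ~ "specific_A",
    !in_a & in_b ~ "specific_B",
    .default = "none"
  )
  out <- tibble(
    node1 = merged$node1, node2 = merged$node2,
    omega_a = merged$omega_a, omega_b = merged$omega_b,
    category = factor(category, levels = diff_link_levels())
  ) |>
    dplyr::arrange(.data$node1, .data$node2)
  class(out) <- c("diff_links", setdiff(class(out), "diff_links"))
  attr(out, "cutoff") <- cutoff
  attr(out, "nodes") <- sort(unique(c(out$node1, out$node2)))
  out
}

diff_link_levels <- function() c("conserved", "specific_A", "specific_B", "reversed", "none")

extract_edges <- function(net, weight_name) {
  t <- as_tibble(net)
  wcol <- intersect(c("omega", "wto"), names(t))[1]
  if (is.na(wcol)) abort("network must carry an `omega` or `wto` weight column")
  t <- t[, c("node1", "node2", wcol)]
  names(t)[3] <- weight_name
  t
}

#' Per-group relative abundance of link categories
#'
#' For each group of nodes (e.g. a cluster), computes the fraction of each
#' link category among links whose *both* endpoints belong to the group —
#' the "relative abundance normalized to cluster size" summary.
#'
#' @param links a `diff_links` table from [classify_links()].
#' @param grouping named vector (node -> group id) or a tibble with columns
#'   `node` and `cluster`/`group`.
#' @param drop_none drop `none` links before computing fractions
#'   (default TRUE).
#' @return A tibble with `group`, `category`, `n_links`, `fraction`
#'   (fractions sum to 1 within each group). Groups without internal links
#'   are omitted with a warning.
#' @export
category_abundance <- function(links, grouping, drop_none = TRUE) {
  if (!inherits(links, "diff_links")) abort("`links` must come from classify_links()")
  if (is.data.frame(grouping)) {
    gcol <- intersect(c("cluster", "group"), names(grouping))[1]
    if (is.na(gcol) || !"node" %in% names(grouping)) {
      abort("`grouping` data frame needs columns `node` and `cluster`/`group`")
    }
    grouping <- setNames(grouping[[gcol]], grouping$node)
  }
  tab <- as_tibble(links)
  if (drop_none) tab <- dplyr::filter(tab, .data$category != "none")
  g1 <- grouping[tab$node1]
  g2 <- grouping[tab$node2]
  internal <- !is.na(g1) & !is.na(g2) & g1 == g2
  tab <- tab[internal, , drop = FALSE]
  tab$group <- unname(g1[internal])
  empty <- setdiff(unique(grouping), tab$group)
  if (length(empty)) {
    warn(sprintf("omitting %d group(s) without internal links", length(empty)))
  }
  tab |>
    dplyr::count(.data$group, .data$category, name = "n_links", .drop = FALSE) |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(fraction = .data$n_links / sum(.data$n_links)) |>
    dplyr::ungroup() |>
    dplyr::filter(!(.data$category == "none" & drop_none))
}

#' @export
#' @method glance diff_links
glance.diff_links <- function(x, ...) {
  counts <- table(x$category)
  total <- sum(counts[diff_link_levels() != "none"])
  tibble(
    n_links = nrow(x),
    n_conserved = as.integer(counts[["conserved"]]),
    n_specific_A = as.integer(counts[["specific_A"]]),
    n_specific_B = as.integer(counts[["specific_B"]]),
    n_reversed = as.integer(counts[["reversed"]]),
    n_none = as.integer(counts[["none"]]),
    frac_conserved = counts[["conserved"]] / total,
    frac_specific_A = counts[["specific_A"]] / total,
    frac_specific_B = counts[["specific_B"]] / total,
    frac_reversed = counts[["reversed"]] / total,
    cutoff = attr(x, "cutoff")
  )
}
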