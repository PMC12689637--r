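#' Pearson correlation adjacency from an expression matrix
#'
#' Computes the full signed Pearson correlation matrix between genes.
#' Zero-variance genes cannot be correlated and are dropped with a warning.
#'
#' @param expr genes x samples numeric matrix (typically log2-scale
#'   normalized expression) with gene ids as rownames; needs >= 3 samples.
#' @return A symmetric correlation matrix with unit diagonal, of class
#'   `cor_adjacency`.
#' @export
pearson_adjacency <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) abort("`expr` must be a numeric matrix")
  if (ncol(expr) < 3) abort("at least 3 samples are required to estimate correlations")
  if (is.null(rownames(expr))) abort("`expr` must have gene ids as rownames")
  v <- apply(expr, 1, var)
  if (any(v == 0)) {
    warn(sprintf("dropping %d zero-variance gene(s)", sum(v == 0)))
    expr <- expr[v > 0, , drop = FALSE]
  }
  a <- cor(t(expr))
  class(a) <- c("cor_adjacency", class(a))
  a
}

#' Signed weighted topological overlap network
#'
#' Converts a signed correlation matrix into a signed weighted topological
#' overlap (wTO) network. For genes *i*, *j* with correlations `a`, the link
#' weight is
#' \deqn{\omega_{ij} = \frac{\sum_{u \ne i,j} a_{iu} a_{uj} + a_{ij}}
#'                          {\min(k_i, k_j) + 1 - |a_{ij}|},\qquad
#'       k_i = \sum_{u \ne i} |a_{iu}|,}
#' so a pair's direct correlation is reinforced (or contradicted) by the
#' agreement of their correlations to every shared neighbour, and the sign
#' of the net overlap is retained. With `method = "abs"` the numerator uses
#' `|a_iu| |a_uj|` (unsigned neighbourhood agreement) while the direct term
#' keeps its sign.
#'
#' @param a a correlation matrix from [pearson_adjacency()] (symmetric,
#'   unit diagonal, entries in `[-1, 1]`).
#' @param method `"sign"` (default) or `"abs"`.
#' @param max_genes guard against accidental huge dense computations;
#'   increase deliberately for larger gene sets.
#' @return A `wto_network`: tibble with columns `node1 < node2`, `wto`, one
#'   row per unordered gene pair; the full node set is kept in
#'   `attr(, "nodes")`.
#' @export
signed_wto <- function(a, method = c("sign", "abs"), max_genes = 5000) {
  method <- match.arg(method)
  if (!is.matrix(a) || nrow(a) != ncol(a)) abort("`a` must be a square matrix")
  if (nrow(a) > max_genes) {
    abort(sprintf(
      "%d genes exceeds the dense-computation guard (max_genes = %d)",
      nrow(a), max_genes
    ))
  }
  if (max(abs(a)) > 1 + 1e-8) abort("correlations must lie in [-1, 1]")
  if (is.null(rownames(a))) abort("`a` must have gene ids as dimnames")
  a0 <- a
  diag(a0) <- 0
  k <- rowSums(abs(a0))
  cross <- if (method == "sign") a0 %*% a0 else abs(a0) %*% abs(a0)
  num <- cross + a0
  den <- outer(k, k, pmin) + 1 - abs(a0)
  w <- num / den
  ut <- upper.tri(w)
  ij <- which(ut, arr.ind = TRUE)
  edges <- tibble(
    node1 = rownames(a)[ij[, 1]],
    node2 = rownames(a)[ij[, 2]],
    wto = w[ut]
  )
  edges <- canonicalize_edges(edges) |> dplyr::arrange(.data$node1, .data$node2)
  new_wto_network(edges, nodes = rownames(a))
}

new_wto_network <- function(edges, nodes, counts = NULL) {
  class(edges) <- c("wto_network", setdiff(class(edges), "wto_network"))
  attr(edges, "nodes") <- nodes
  attr(edges, "filter_counts") <- counts
  edges
}

#' Hard-threshold a wTO network
#'
#' Discards links with absolute weight below `cutoff` (a link exactly at
#' the cutoff is retained) and then drops nodes left without any link.
#' The before/after link and node counts are kept in
#' `attr(, "filter_counts")` for bookkeeping.
#'
#' @param net a `wto_network` from [signed_wto()].
#' @param cutoff absolute-weight cutoff in (0, 1), default 0.5.
#' @return The filtered `wto_network`.
#' @export
hard_threshold <- function(net, cutoff = 0.5) {
  if (!inherits(net, "wto_network")) abort("`net` must be a `wto_network`")
  if (!is.numeric(cutoff) || cutoff <= 0 || cutoff >= 1) abort("`cutoff` must be in (0, 1)")
  before <- c(links = nrow(net), nodes = length(attr(net, "nodes")))
  kept <- dplyr::filter(as_tibble(net), abs(.data$wto) >= cutoff)
  nodes_after <- sort(unique(c(kept$node1, kept$node2)))
  counts <- tibble(
    stage = c("before", "after"),
    links = c(before[["links"]], nrow(kept)),
    nodes = c(before[["nodes"]], length(nodes_after)),
    cutoff = cutoff
  )
  new_wto_network(kept, nodes = nodes_after, counts = counts)
}

#' @export
print.wto_network <- function(x, ...) {
  cat(sprintf("<wto_network> %d links over %d nodes\n", nrow(x), length(attr(x, "nodes"))))
  NextMethod()
}

#' @export
#' @method glance wto_network
glance.wto_network <- function(x, ...) {
  tibble(
    n_links = nrow(x),
    n_nodes = length(attr(x, "nodes")),
    n_negative = sum(x$wto < 0),
    mean_abs_weight = if (nrow(x)) mean(abs(x$wto)) else NA_real_
  )
}
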