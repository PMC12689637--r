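# Graph topology: k-core hubs and Louvain clusters.
# Graph algorithms are delegated to igraph; weights are never used here
# (hub and cluster detection operate on the simple unweighted graph).

as_unweighted_igraph <- function(net) {
  if (inherits(net, "igraph")) return(net)
  t <- as_tibble(net)
  if (!all(c("node1", "node2") %in% names(t))) {
    abort("`net` must be an edge table with `node1`, `node2` columns")
  }
  g <- igraph::graph_from_data_frame(t[, c("node1", "node2")], directed = FALSE,
                                     vertices = attr(net, "nodes"))
  igraph::simplify(g)
}

#' K-core decomposition and core hub genes
#'
#' Computes each node's coreness (the largest k such that the node belongs
#' to the k-core, the maximal subgraph where every node has degree >= k) by
#' iterative peeling, and flags the innermost shell — the nodes of maximum
#' coreness — as the network's core hub genes.
#'
#' @param net an edge table (`wto_network`, `consensus_network`, tibble
#'   with `node1`/`node2`) or an igraph object; weights are ignored.
#' @return A `coreness_map` tibble: `node`, `coreness`, `is_core`, ordered
#'   by decreasing coreness. The core set is in `attr(, "core_set")`.
#' @export
kcore_decomposition <- function(net) {
  g <- as_unweighted_igraph(net)
  if (igraph::vcount(g) == 0) {
    out <- tibble(node = character(0), coreness = integer(0), is_core = logical(0))
  } else {
    k <- igraph::coreness(g)
    out <- tibble(
      node = names(k),
      coreness = as.integer(k),
      is_core = k == max(k)
    ) |> dplyr::arrange(dplyr::desc(.data$coreness), .data$node)
  }
  class(out) <- c("coreness_map", setdiff(class(out), "coreness_map"))
  attr(out, "core_set") <- out$node[out$is_core]
  out
}

#' Overlap between two core gene sets
#'
#' @param core_a,core_b `coreness_map` objects (or character vectors of
#'   core genes).
#' @return A list with `shared`, `only_a`, `only_b` (character vectors) and
#'   `counts` (named integer vector).
#' @export
core_overlap <- function(core_a, core_b) {
  a <- if (inherits(core_a, "coreness_map")) attr(core_a, "core_set") else as.character(core_a)
  b <- if (inherits(core_b, "coreness_map")) attr(core_b, "core_set") else as.character(core_b)
  shared <- intersect(a, b)
  only_a <- setdiff(a, b)
  only_b <- setdiff(b, a)
  list(
    shared = shared, only_a = only_a, only_b = only_b,
    counts = c(shared = length(shared), only_a = length(only_a), only_b = length(only_b))
  )
}

#' Louvain modularity clusters with a minimum-size filter
#'
#' Runs Louvain community detection on the unweighted simple graph (link
#' signs and weights are deliberately ignored) at the given resolution, and
#' drops clusters with fewer than `min_links` internal links. Louvain is
#' order-dependent, so the partition is made reproducible by seeding the
#' RNG; clusters are renumbered by decreasing node count.
#'
#' @inheritParams kcore_decomposition
#' @param resolution modularity resolution parameter, default 1 (the
#'   original modularity definition).
#' @param min_links minimum internal links for a cluster to be retained,
#'   default 20.
#' @param seed RNG seed for the (order-dependent) Louvain heuristic.
#' @return A `partition` tibble: `node`, `cluster` (integer), containing
#'   only nodes of retained clusters. `attr(, "summary")` holds per-cluster
#'   node/link counts (including dropped clusters, flagged by `retained`);
#'   `attr(, "modularity")` the modularity of the full partition.
#' @export
louvain_clusters <- function(net, resolution = 1, min_links = 20, seed = 1L) {
  g <- as_unweighted_igraph(net)
  if (igraph::vcount(g) == 0) abort("cannot cluster an empty graph")
  comm <- with_seed(seed, igraph::cluster_louvain(g, weights = NA, resolution = resolution))
  member <- igraph::membership(comm)
  full <- tibble(node = names(member), cluster_raw = as.integer(member))
  intra <- vapply(sort(unique(full$cluster_raw)), function(cl) {
    sub <- igraph::induced_subgraph(g, full$node[full$cluster_raw == cl])
    igraph::ecount(sub)
  }, numeric(1))
  summary <- tibble(
    cluster_raw = sort(unique(full$cluster_raw)),
    n_nodes = as.integer(table(full$cluster_raw)),
    n_links = as.integer(intra),
    retained = intra >= min_links
  ) |> dplyr::arrange(dplyr::desc(.data$n_nodes))
  # renumber retained clusters 1..K by decreasing size (dropped -> NA)
  summary$cluster <- NA_integer_
  summary$cluster[summary$retained] <- seq_len(sum(summary$retained))
  full <- dplyr::left_join(full, summary[, c("cluster_raw", "cluster")], by = "cluster_raw")
  out <- full |>
    dplyr::filter(!is.na(.data$cluster)) |>
    dplyr::select("node", "cluster") |>
    dplyr::arrange(.data$cluster, .data$node)
  class(out) <- c("partition", setdiff(class(out), "partition"))
  attr(out, "summary") <- summary[, c("cluster", "n_nodes", "n_links", "retained")]
  attr(out, "modularity") <- igraph::modularity(comm)
  attr(out, "resolution") <- resolution
  attr(out, "min_links") <- min_links
  out
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' @export
#' @method glance partition
glance.partition <- function(x, ...) {
  s <- attr(x, "summary")
  tibble(
    n_clusters = sum(s$retained),
    n_dropped = sum(!s$retained),
    n_nodes = nrow(x),
    modularity = attr(x, "modularity"),
    resolution = attr(x, "resolution")
  )
}
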