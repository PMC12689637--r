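#' Over-representation of functional categories in gene clusters
#'
#' One-sided hypergeometric over-representation test of each category gene
#' set in each cluster, restricted to protein-coding genes and a fixed
#' background. P-values are BH-adjusted across terms *within* each cluster;
#' terms with fewer than `min_term_size` background genes are excluded.
#'
#' @param partition a `partition` from [louvain_clusters()].
#' @param catalog tibble with `gene_id`, `biotype`; only `protein_coding`
#'   genes are tested.
#' @param category_sets named list of gene-id vectors (term -> genes).
#' @param background character vector of background gene ids (must contain
#'   every tested gene); typically all protein-coding genes that entered
#'   network construction.
#' @param alpha adjusted-p significance threshold, default 0.05.
#' @param min_term_size minimum background genes per term, default 5.
#' @return An `enrichment_table` tibble: `cluster`, `term`, `k` (hits),
#'   `K` (term size in background), `n` (cluster size in background),
#'   `N` (background size), `p`, `padj`, `significant`.
#' @export
cluster_enrichment <- function(partition, catalog, category_sets, background,
                               alpha = 0.05, min_term_size = 5) {
  if (!all(c("gene_id", "biotype") %in% names(catalog))) {
    abort("`catalog` needs columns `gene_id` and `biotype`")
  }
  background <- unique(as.character(background))
  pc <- catalog$gene_id[catalog$biotype == "protein_coding"]
  bg <- intersect(background, pc)
  N <- length(bg)
  if (N == 0) abort("empty protein-coding background")
  sets <- lapply(category_sets, function(s) intersect(unique(s), bg))
  small <- vapply(sets, length, integer(1)) < min_term_size
  if (any(small)) {
    inform(sprintf("excluding %d term(s) with fewer than %d background genes",
                   sum(small), min_term_size))
    sets <- sets[!small]
  }
  if (!length(sets)) abort("no testable terms left")
  part <- as_tibble(partition)
  rows <- purrr::map_dfr(sort(unique(part$cluster)), function(cl) {
    members <- intersect(part$node[part$cluster == cl], bg)
    n <- length(members)
    res <- purrr::map_dfr(names(sets), function(term) {
      K <- length(sets[[term]])
      k <- length(intersect(members, sets[[term]]))
      tibble(
        cluster = cl, term = term, k = k, K = K, n = n, N = N,
        p = phyper(k - 1, K, N - K, n, lower.tail = FALSE)
      )
    })
    res$padj <- p.adjust(res$p, method = "BH")
    res
  })
  rows$significant <- rows$padj < alpha
  class(rows) <- c("enrichment_table", setdiff(class(rows), "enrichment_table"))
  attr(rows, "alpha") <- alpha
  rows
}

#' Random walk with restart on an unweighted cluster subgraph
#'
#' Iterates `p <- (1 - r) W p + r p0` to its fixed point, where `W` is the
#' column-normalized binary adjacency of the (unweighted, sign-stripped)
#' graph and `p0` is uniform over the seed genes. Columns of isolated
#' nodes are dangling; their probability mass is teleported to `p0`, which
#' keeps the iteration stochastic. Scores are steady-state visiting
#' probabilities: proximity of every node to the seed set.
#'
#' @param net edge table or igraph for one cluster's subgraph.
#' @param seeds character vector of seed gene ids (must be nodes).
#' @param r restart probability, default 0.7.
#' @param tol L1 convergence tolerance, default 1e-10.
#' @param max_iter iteration cap; exceeding it is an error.
#' @return An `rwr_result` tibble: `node`, `score`, `is_seed`, sorted by
#'   decreasing score; attributes `residual`, `iterations`, `r`, `seeds`.
#' @export
rwr_scores <- function(net, seeds, r = 0.7, tol = 1e-10, max_iter = 1e5) {
  g <- as_unweighted_igraph(net)
  nodes <- igraph::V(g)$name
  seeds <- unique(as.character(seeds))
  if (!length(seeds)) abort("`seeds` must be non-empty")
  missing <- setdiff(seeds, nodes)
  if (length(missing)) {
    abort(sprintf("seed(s) not in the subgraph: %s", paste(head(missing, 5), collapse = ", ")))
  }
  if (!is.numeric(r) || r < 0 || r > 1) abort("`r` must be in [0, 1]")
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  deg <- colSums(A)
  W <- sweep(A, 2, pmax(deg, 1), `/`)
  dangling <- deg == 0
  p0 <- setNames(rep(0, length(nodes)), nodes)
  p0[seeds] <- 1 / length(seeds)
  p <- p0
  iter <- 0L
  repeat {
    iter <- iter + 1L
    p_new <- (1 - r) * (drop(W %*% p) + sum(p[dangling]) * p0) + r * p0
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < tol) break
    if (iter >= max_iter) {
      abort(sprintf("RWR did not converge in %d iterations (L1 residual %.3g)", iter, delta))
    }
  }
  out <- tibble(node = nodes, score = unname(p), is_seed = nodes %in% seeds) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$node)
  class(out) <- c("rwr_result", setdiff(class(out), "rwr_result"))
  attr(out, "residual") <- delta
  attr(out, "iterations") <- iter
  attr(out, "r") <- r
  attr(out, "seeds") <- seeds
  out
}

#' Leave-one-out RWR acceptance floor for a category
#'
#' For every gene of a category, seeds the walk with the *other* category
#' genes and records the held-out gene's score; the minimum over held-out
#' genes is the acceptance floor used by [assign_lncrnas()]. Category genes
#' absent from the subgraph are dropped with a warning (a disconnected
#' category gene that is present scores 0 and drags the floor to 0).
#'
#' @inheritParams rwr_scores
#' @param category_genes character vector of the category's (seed) genes;
#'   at least 2 must be present in the subgraph.
#' @return A list with `loo_min` (the floor), and `scores` (tibble
#'   `gene`, `loo_score`).
#' @export
loo_threshold <- function(net, category_genes, r = 0.7, tol = 1e-10, max_iter = 1e5) {
  g <- as_unweighted_igraph(net)
  nodes <- igraph::V(g)$name
  category_genes <- unique(as.character(category_genes))
  absent <- setdiff(category_genes, nodes)
  if (length(absent)) {
    warn(sprintf("dropping %d category gene(s) absent from the subgraph", length(absent)))
    category_genes <- setdiff(category_genes, absent)
  }
  if (length(category_genes) < 2) {
    abort("leave-one-out needs at least 2 category genes in the subgraph")
  }
  loo <- vapply(category_genes, function(gene) {
    res <- rwr_scores(g, setdiff(category_genes, gene), r = r, tol = tol, max_iter = max_iter)
    res$score[res$node == gene]
  }, numeric(1))
  list(
    loo_min = min(loo),
    scores = tibble(gene = category_genes, loo_score = unname(loo))
  )
}

#' Assign lncRNAs to a functional category from RWR scores
#'
#' Ranks the cluster's lncRNAs by their RWR score for a category's seed
#' genes; lncRNAs at or above the `percentile`-th percentile of the
#' cluster's lncRNA scores are *eligible* (ties included), and an eligible
#' lncRNA is *accepted* only if its score is not below the leave-one-out
#' floor `loo_min`.
#'
#' @param scores an `rwr_result` from [rwr_scores()].
#' @param lncrnas character vector of lncRNA gene ids scored in `scores`.
#' @param loo_min leave-one-out acceptance floor (see [loo_threshold()]).
#' @param percentile percentile (0-100) defining the top tier, default 90
#'   (the top decile).
#' @return An `assignment_table` tibble: `gene`, `score`,
#'   `percentile_rank`, `eligible`, `accepted`, `loo_min`.
#' @export
assign_lncrnas <- function(scores, lncrnas, loo_min, percentile = 90) {
  if (!inherits(scores, "rwr_result")) abort("`scores` must come from rwr_scores()")
  lncrnas <- unique(as.character(lncrnas))
  missing <- setdiff(lncrnas, scores$node)
  if (length(missing)) {
    abort(sprintf("lncRNA(s) not scored: %s", paste(head(missing, 5), collapse = ", ")))
  }
  if (!length(lncrnas)) {
    out <- tibble(gene = character(0), score = numeric(0), percentile_rank = numeric(0),
                  eligible = logical(0), accepted = logical(0), loo_min = numeric(0))
    class(out) <- c("assignment_table", setdiff(class(out), "assignment_table"))
    return(out)
  }
  s <- setNames(scores$score, scores$node)[lncrnas]
  thr <- quantile(s, percentile / 100, names = FALSE)
  eligible <- s >= thr
  out <- tibble(
    gene = lncrnas,
    score = unname(s),
    percentile_rank = 100 * (rank(s, ties.method = "average") - 1) / max(length(s) - 1, 1),
    eligible = unname(eligible),
    accepted = unname(eligible & s >= loo_min),
    loo_min = loo_min
  ) |> dplyr::arrange(dplyr::desc(.data$score), .data$gene)
  class(out) <- c("assignment_table", setdiff(class(out), "assignment_table"))
  attr(out, "percentile") <- percentile
  out
}

#' Cluster-wise lncRNA annotation by RWR with leave-one-out validation
#'
#' The full annotation loop: for each cluster and each of its significantly
#' enriched categories, build the cluster's induced subgraph, seed a random
#' walk with the category's protein-coding genes present in the cluster,
#' compute the leave-one-out floor, and accept the top-decile lncRNAs whose
#' score clears the floor.
#'
#' @param net the condition's `consensus_network` (or any edge table).
#' @param partition a `partition` over that network's nodes.
#' @param enrichment an `enrichment_table` for the partition; only rows
#'   with `significant == TRUE` are used.
#' @param catalog tibble with `gene_id`, `biotype`.
#' @param category_sets named list of category gene sets.
#' @inheritParams assign_lncrnas
#' @inheritParams rwr_scores
#' @return A tibble with one row per (lncRNA, cluster, category):
#'   `gene`, `cluster`, `category`, `score`, `percentile_rank`, `loo_min`,
#'   `eligible`, `accepted`.
#' @export
annotate_lncrnas <- function(net, partition, enrichment, catalog, category_sets,
                             r = 0.7, percentile = 90, tol = 1e-10, max_iter = 1e5) {
  part <- as_tibble(partition)
  lnc_all <- catalog$gene_id[catalog$biotype == "lncRNA"]
  sig <- dplyr::filter(as_tibble(enrichment), .data$significant)
  g <- as_unweighted_igraph(net)
  purrr::map_dfr(sort(unique(sig$cluster)), function(cl) {
    members <- part$node[part$cluster == cl]
    sub <- igraph::induced_subgraph(g, intersect(members, igraph::V(g)$name))
    lnc <- intersect(members, lnc_all)
    if (!length(lnc)) return(tibble())
    purrr::map_dfr(sig$term[sig$cluster == cl], function(term) {
      seeds <- intersect(category_sets[[term]], igraph::V(sub)$name)
      if (length(seeds) < 2) return(tibble())
      sc <- rwr_scores(sub, seeds, r = r, tol = tol, max_iter = max_iter)
      floor <- loo_threshold(sub, seeds, r = r, tol = tol, max_iter = max_iter)$loo_min
      asg <- assign_lncrnas(sc, intersect(lnc, sc$node), floor, percentile = percentile)
      dplyr::mutate(as_tibble(asg), cluster = cl, category = term, .after = "gene")
    })
  })
}
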