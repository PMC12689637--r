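# Independent oracles used to cross-check the implementation. These are
# deliberately naive (double loops, explicit peeling, dense solves,
# exhaustive enumeration) and share no code with the package internals.

# signed wTO by explicit double loop over shared neighbours
brute_wto <- function(a, method = "sign") {
  g <- nrow(a)
  ids <- rownames(a)
  out <- NULL
  for (i in seq_len(g - 1)) {
    for (j in (i + 1):g) {
      num <- 0
      for (u in seq_len(g)) {
        if (u == i || u == j) next
        num <- num + if (method == "sign") a[i, u] * a[u, j] else abs(a[i, u]) * abs(a[u, j])
      }
      num <- num + a[i, j]
      ki <- sum(abs(a[i, -i]))
      kj <- sum(abs(a[j, -j]))
      den <- min(ki, kj) + 1 - abs(a[i, j])
      out <- rbind(out, data.frame(node1 = ids[i], node2 = ids[j], wto = num / den))
    }
  }
  out
}

# coreness by literal repeated deletion: for each k remove nodes of degree
# < k until stable; a node's coreness is the largest k at which it survives
brute_coreness <- function(edges, nodes) {
  deg_of <- function(nds, eds) {
    d <- setNames(rep(0L, length(nds)), nds)
    keep <- eds$node1 %in% nds & eds$node2 %in% nds
    for (x in c(eds$node1[keep], eds$node2[keep])) d[[x]] <- d[[x]] + 1L
    d
  }
  core <- setNames(rep(0L, length(nodes)), nodes)
  k <- 1L
  alive <- nodes
  repeat {
    repeat {
      d <- deg_of(alive, edges)
      drop <- names(d)[d < k]
      if (!length(drop) || !length(alive)) break
      alive <- setdiff(alive, drop)
    }
    if (!length(alive)) break
    core[alive] <- k
    k <- k + 1L
  }
  core
}

# RWR steady state by dense linear solve: p = r (I - (1-r) M)^{-1} p0,
# with M the column-normalized adjacency and dangling columns teleporting
# to p0
rwr_solve <- function(edges, nodes, seeds, r) {
  n <- length(nodes)
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (row in seq_len(nrow(edges))) {
    A[edges$node1[row], edges$node2[row]] <- 1
    A[edges$node2[row], edges$node1[row]] <- 1
  }
  deg <- colSums(A)
  M <- sweep(A, 2, pmax(deg, 1), `/`)
  p0 <- setNames(rep(0, n), nodes)
  p0[seeds] <- 1 / length(seeds)
  M[, deg == 0] <- p0
  p <- solve(diag(n) - (1 - r) * M, r * p0)
  setNames(as.numeric(p), nodes)
}

# exact permutation distribution of the overlap coefficient by full
# enumeration over all draws from both pools
enumerate_overlap_p <- function(a, b, pool_a, pool_b) {
  obs <- length(intersect(a, b)) / min(length(a), length(b))
  da <- combn(pool_a, length(a), simplify = FALSE)
  db <- combn(pool_b, length(b), simplify = FALSE)
  tot <- 0L
  ge <- 0L
  for (x in da) {
    for (y in db) {
      tot <- tot + 1L
      coef <- length(intersect(x, y)) / min(length(x), length(y))
      if (coef >= obs) ge <- ge + 1L
    }
  }
  ge / tot
}

# random correlation matrix from random data (guaranteed valid)
random_cor <- function(n_genes, n_samples = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- matrix(rnorm(n_genes * n_samples), n_genes)
  rownames(x) <- sprintf("g%02d", seq_len(n_genes))
  cor(t(x))
}

# random simple graph as a canonical edge tibble
random_graph <- function(n_nodes, p_edge = 0.15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- t(combn(ids, 2))
  keep <- runif(nrow(pairs)) < p_edge
  tibble::tibble(node1 = pairs[keep, 1], node2 = pairs[keep, 2])
}

make_counts <- function(m, dataset = "ds1", condition = "A") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("s%03d", seq_len(ncol(m)))
  count_matrix(m, dataset_id = dataset, condition = condition)
}

# small wto_network from an explicit edge data frame (tests only)
edges_as_wto <- function(df) {
  net <- tibble::as_tibble(df)
  class(net) <- c("wto_network", class(net))
  attr(net, "nodes") <- sort(unique(c(net$node1, net$node2)))
  net
}
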