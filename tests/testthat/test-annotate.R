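mk_partition <- function(nodes, cluster = 1L) {
  p <- tibble::tibble(node = nodes, cluster = cluster)
  class(p) <- c("partition", class(p))
  p
}

test_that("hypergeometric enrichment matches closed forms and enumeration", {
  bg <- sprintf("g%03d", 1:100)
  catalog <- tibble::tibble(gene_id = bg, biotype = "protein_coding")

  # cluster identical to a 10-gene term: p = 1 / choose(100, 10)
  term10 <- bg[1:10]
  part <- mk_partition(term10)
  et <- cluster_enrichment(part, catalog, list(T10 = term10), bg)
  expect_equal(et$p, 1 / choose(100, 10), tolerance = 1e-12)
  expect_equal(et$k, 10)

  # toy N=50, K=10, n=10, k=5 against explicit tail enumeration
  bg50 <- bg[1:50]
  term <- bg50[1:10]
  cluster <- c(bg50[1:5], bg50[26:30])
  et2 <- cluster_enrichment(mk_partition(cluster),
                            tibble::tibble(gene_id = bg50, biotype = "protein_coding"),
                            list(T = term), bg50)
  tail_sum <- sum(vapply(5:10, function(x) {
    choose(10, x) * choose(40, 10 - x) / choose(50, 10)
  }, numeric(1)))
  expect_equal(et2$p, tail_sum, tolerance = 1e-12)
  expect_gte(et2$padj, et2$p)
})

test_that("tiny terms are excluded and only protein-coding genes are tested", {
  bg <- sprintf("g%03d", 1:40)
  catalog <- tibble::tibble(
    gene_id = bg,
    biotype = rep(c("protein_coding", "lncRNA"), each = 20)
  )
  part <- mk_partition(bg[c(1:5, 21:25)]) # 5 pc + 5 lnc members
  expect_message(
    et <- cluster_enrichment(part, catalog, list(T1 = bg[1:10], tiny = bg[1:3]), bg),
    "excluding 1 term"
  )
  expect_false("tiny" %in% et$term)
  expect_equal(unique(et$n), 5)      # lncRNA members never count
  expect_equal(unique(et$N), 20)     # background restricted to protein-coding
})

test_that("enrichment p-values are calibrated under a random-cluster null", {
  set.seed(60)
  bg <- sprintf("g%03d", 1:200)
  catalog <- tibble::tibble(gene_id = bg, biotype = "protein_coding")
  term <- list(T = bg[1:40])
  p <- vapply(1:200, function(i) {
    part <- mk_partition(sample(bg, 30))
    cluster_enrichment(part, catalog, term, bg)$p
  }, numeric(1))
  expect_lte(mean(p < 0.05), 0.08)       # no anti-conservative excess
  expect_gt(mean(p), 0.45)               # discrete p-values are >= uniform on average
})

test_that("RWR reproduces the two-node closed form and the r = 1 limit", {
  edge <- tibble::tibble(node1 = "a", node2 = "b")
  res <- rwr_scores(edge, seeds = "a", r = 0.7)
  # fixed point of p_a = 0.3 p_b + 0.7, p_b = 0.3 p_a
  expect_equal(res$score[res$node == "a"], 0.7 / 0.91, tolerance = 1e-8)
  expect_equal(res$score[res$node == "b"], 0.21 / 0.91, tolerance = 1e-8)

  unit <- rwr_scores(edge, seeds = "a", r = 1)
  expect_equal(setNames(unit$score, unit$node)[c("a", "b")], c(a = 1, b = 0))

  expect_error(rwr_scores(edge, seeds = character(0)), "non-empty")
  expect_error(rwr_scores(edge, seeds = "zz"), "not in the subgraph")
  expect_error(rwr_scores(edge, seeds = "a", max_iter = 1), "did not converge")
})

test_that("RWR scores are a probability vector and respect symmetry", {
  # 4-cycle with seeds at opposite corners: the two free nodes tie
  cyc <- tibble::tibble(node1 = c("a", "b", "c", "a"), node2 = c("b", "c", "d", "d"))
  res <- rwr_scores(cyc, seeds = c("a", "c"), r = 0.7)
  expect_equal(sum(res$score), 1, tolerance = 1e-9)
  s <- setNames(res$score, res$node)
  expect_equal(s[["b"]], s[["d"]], tolerance = 1e-10)
  expect_equal(s[["a"]], s[["c"]], tolerance = 1e-10)
})

test_that("a seed's direct neighbour outscores an equivalent non-neighbour", {
  # s - x - y chain: x touches the seed, y is one step further
  chain <- tibble::tibble(node1 = c("s", "x"), node2 = c("x", "y"))
  res <- rwr_scores(chain, seeds = "s", r = 0.7)
  s <- setNames(res$score, res$node)
  expect_gt(s[["x"]], s[["y"]])
})

test_that("power iteration agrees with the direct linear solve", {
  for (seed in c(11, 12)) {
    g <- random_graph(sample(20:50, 1), p_edge = 0.1, seed = seed)
    nodes <- sort(unique(c(g$node1, g$node2)))
    seeds <- sample(nodes, 3)
    got <- rwr_scores(g, seeds, r = 0.7, tol = 1e-12)
    want <- rwr_solve(g, nodes, seeds, r = 0.7)
    expect_equal(setNames(got$score, got$node)[nodes], want[nodes], tolerance = 1e-8)
  }
})

test_that("dangling nodes teleport their mass back to the seeds", {
  # isolated node z: column of zeros in the adjacency
  g <- tibble::tibble(node1 = "a", node2 = "b")
  gi <- igraph::graph_from_data_frame(g, directed = FALSE,
                                      vertices = c("a", "b", "z"))
  res <- rwr_scores(gi, seeds = "a", r = 0.7)
  expect_equal(sum(res$score), 1, tolerance = 1e-9)
  expect_equal(res$score[res$node == "z"], 0, tolerance = 1e-9)
  want <- rwr_solve(g, c("a", "b", "z"), "a", r = 0.7)
  expect_equal(setNames(res$score, res$node)[c("a", "b", "z")], want, tolerance = 1e-8)
})

test_that("leave-one-out floor matches the brute-force loop", {
  # chain of two category genes reuses the two-node closed form
  edge <- tibble::tibble(node1 = "a", node2 = "b")
  lo <- loo_threshold(edge, c("a", "b"), r = 0.7)
  expect_equal(lo$loo_min, 0.21 / 0.91, tolerance = 1e-8)

  # disconnected category gene drags the floor to zero
  gi <- igraph::graph_from_data_frame(edge, directed = FALSE,
                                      vertices = c("a", "b", "iso"))
  lo0 <- loo_threshold(gi, c("a", "b", "iso"), r = 0.7)
  expect_equal(lo0$loo_min, 0, tolerance = 1e-9)

  # 5-gene toy cluster against an explicit leave-out loop over the solver
  g5 <- random_graph(5, p_edge = 0.8, seed = 21)
  nodes <- sort(unique(c(g5$node1, g5$node2)))
  cat_genes <- nodes[1:4]
  lo5 <- loo_threshold(g5, cat_genes, r = 0.7, tol = 1e-12)
  want <- min(vapply(cat_genes, function(g) {
    rwr_solve(g5, nodes, setdiff(cat_genes, g), r = 0.7)[[g]]
  }, numeric(1)))
  expect_equal(lo5$loo_min, want, tolerance = 1e-8)

  expect_error(loo_threshold(edge, "a"), "at least 2")
})

test_that("assignment applies the top-decile rule with ties and the LOO floor", {
  nodes <- sprintf("n%03d", 1:100)
  scores <- tibble::tibble(node = nodes, score = seq(0.001, 0.1, length.out = 100),
                           is_seed = FALSE)
  class(scores) <- c("rwr_result", class(scores))
  asg <- assign_lncrnas(scores, nodes, loo_min = 0, percentile = 90)
  expect_equal(sum(asg$eligible), 10) # exactly the top decile of 100 distinct scores
  expect_setequal(asg$gene[asg$eligible], nodes[91:100])

  # a floor above some eligible scores rejects them
  floor <- scores$score[97]
  asg2 <- assign_lncrnas(scores, nodes, loo_min = floor, percentile = 90)
  expect_equal(sum(asg2$accepted), 4)
  expect_true(all(asg2$score[asg2$accepted] >= floor))

  empty <- assign_lncrnas(scores, character(0), loo_min = 0)
  expect_equal(nrow(empty), 0)
})

test_that("cluster-wise annotation accepts planted lncRNAs", {
  # one tight cluster: category genes fully connected, lncRNAs attached
  pc <- sprintf("p%d", 1:6)
  lnc <- c("l1", "l2")
  cl <- t(combn(pc, 2))
  edges <- tibble::tibble(
    node1 = c(cl[, 1], rep("l1", 4), "l2"),
    node2 = c(cl[, 2], pc[1:4], pc[1])
  )
  extra <- sprintf("q%d", 1:20) # background genes outside the cluster
  part <- mk_partition(c(pc, lnc))
  catalog <- tibble::tibble(gene_id = c(pc, lnc, extra),
                            biotype = rep(c("protein_coding", "lncRNA", "protein_coding"),
                                          c(6, 2, 20)))
  et <- cluster_enrichment(part, catalog, list(T = pc), background = c(pc, extra))
  expect_true(all(et$significant))
  asg <- annotate_lncrnas(edges, part, et, catalog, list(T = pc), percentile = 50)
  expect_true(all(c("l1", "l2") %in% asg$gene))
  # the better-connected lncRNA scores higher and clears the top tier
  expect_gt(asg$score[asg$gene == "l1"], asg$score[asg$gene == "l2"])
  expect_true(asg$eligible[asg$gene == "l1"])
  expect_type(asg$accepted, "logical")
})
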