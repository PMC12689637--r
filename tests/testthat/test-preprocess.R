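test_that("cpm_filter keeps genes at the boundary and drops silent genes", {
  m <- rbind(
    boundary = c(rep(1, 7), rep(0, 3)),   # 1 cpm in exactly 70% of samples
    silent   = rep(0, 10),
    strong   = rep(50, 10)
  )
  # pad library sizes to 1e6 with a filler gene so cpm == count
  m <- rbind(m, filler = 1e6 - colSums(m))
  colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  cm <- make_counts(m)
  kept <- cpm_filter(cm, min_cpm = 1, min_frac = 0.7)
  expect_true("boundary" %in% rownames(kept$counts))
  expect_true("strong" %in% rownames(kept$counts))
  expect_false("silent" %in% rownames(kept$counts))
  expect_identical(colnames(kept$counts), colnames(m))
})

test_that("cpm_filter matches the per-gene brute-force rule and is idempotent", {
  set.seed(14)
  m <- matrix(rpois(50 * 8, lambda = 3), 50, 8,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:8)))
  m[1, ] <- 1e5 # keep libraries positive
  cm <- make_counts(m)
  kept <- cpm_filter(cm, min_cpm = 1, min_frac = 0.7)
  lib <- colSums(m)
  manual <- vapply(seq_len(nrow(m)), function(g) {
    mean(m[g, ] / lib * 1e6 >= 1) >= 0.7
  }, logical(1))
  expect_identical(rownames(kept$counts), rownames(m)[manual])
  twice <- cpm_filter(kept, min_cpm = 1, min_frac = 0.7)
  expect_identical(twice$counts, kept$counts)
})

test_that("median-of-ratios size factors behave on constructed cases", {
  m <- matrix(rpois(40, 30) + 1, 10, 4)
  m[, 2] <- m[, 1] * 2
  same <- matrix(rep(m[, 1], 4), 10, 4)
  rownames(same) <- rownames(m) <- sprintf("g%02d", 1:10)

  res_same <- median_of_ratios_normalize(same)
  expect_equal(unname(res_same$size_factors), rep(1, 4))

  res <- median_of_ratios_normalize(m)
  expect_equal(unname(res$size_factors[2] / res$size_factors[1]), 2)

  # normalization preserves within-sample rank order
  expect_identical(order(m[, 3]), order(res$normalized[, 3]))

  expect_error(median_of_ratios_normalize(diag(0:3)), "nonzero")
})

test_that("size factors agree with the DESeq2 estimator on a toy matrix", {
  set.seed(8)
  m <- matrix(rnbinom(25 * 6, mu = 100, size = 10) + 1, 25, 6)
  rownames(m) <- sprintf("g%02d", 1:25)
  ours <- median_of_ratios_normalize(m)$size_factors
  ref <- suppressMessages(DESeq2::estimateSizeFactorsForMatrix(m))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("differential expression applies both significance thresholds", {
  cfg <- synth_config(seed = 51, n_genes = 100, n_modules = 1, module_sizes = 1L,
                      n_samples = 150, n_datasets_per_condition = 1,
                      latent_sd = 0.25, nb_dispersion = 0.03)
  st <- generate_study(cfg)
  set.seed(4)
  b <- plant_differential_expression(
    st$counts$ds1_B,
    c(g0010 = 1, g0020 = 0.2) # strong effect vs sub-threshold fold change
  )
  de <- differential_expression(st$counts$ds1_A, b)
  expect_identical(de$direction[de$gene == "g0010"], "up")
  # g0020: highly significant at n=150 but |log2FC| ~ 0.2 < 0.3 -> ns
  row20 <- de[de$gene == "g0020", ]
  expect_lt(row20$fdr, 0.05)
  expect_lt(abs(row20$log2fc), 0.3)
  expect_identical(row20$direction, "ns")
})

test_that("degenerate variance yields p = 1 and a flag", {
  m <- matrix(5, 4, 6, dimnames = list(sprintf("g%d", 1:4), sprintf("s%d", 1:6)))
  m[1, ] <- c(10, 20, 30, 10, 20, 30) # one varying gene so sf exist
  a <- make_counts(m[, 1:3], condition = "A")
  b <- make_counts(m[, 4:6], condition = "B")
  de <- differential_expression(a, b)
  expect_true(all(de$degenerate[de$gene != "g1"]))
  expect_true(all(de$pvalue[de$gene != "g1"] == 1))
})

test_that("consensus DEGs follow the all-datasets same-direction rule", {
  mk <- function(dirs) {
    t <- tibble::tibble(
      gene = sprintf("g%d", seq_along(dirs)),
      log2fc = ifelse(dirs == "up", 1, ifelse(dirs == "down", -1, 0)),
      pvalue = 0.001, fdr = ifelse(dirs == "ns", 0.9, 0.001),
      direction = dirs, degenerate = FALSE, dataset_id = "x"
    )
    class(t) <- c("de_table", class(t))
    t
  }
  t1 <- mk(c("down", "down", "up"))
  t2 <- mk(c("down", "ns", "down"))
  t3 <- mk(c("down", "down", "down"))
  cons <- consensus_degs(list(t1, t2, t3))
  expect_identical(cons$gene, "g1")          # g2 misses one table, g3 flips
  expect_identical(cons$direction, "down")

  single <- consensus_degs(list(t1))
  expect_setequal(single$gene, c("g1", "g2", "g3"))

  expect_error(consensus_degs(list()), "non-empty")
})

test_that("null data give calibrated DE p-values", {
  cfg <- synth_config(seed = 77, n_genes = 1000, n_modules = 1, module_sizes = 1L,
                      n_samples = 40, n_datasets_per_condition = 1,
                      latent_sd = 0.5, nb_dispersion = 0.05,
                      rewired_module_fraction = 0)
  st <- generate_study(cfg)
  de <- differential_expression(st$counts$ds1_A, st$counts$ds1_B)
  expect_lte(mean(de$pvalue < 0.05), 0.06)
  expect_identical(unique(de$direction), "ns")
})
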