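test_that("generate_study is byte-identical under a fixed seed and config", {
  cfg <- synth_config(seed = 101, n_genes = 60, module_sizes = rep(15L, 3),
                      n_modules = 3, n_samples = 10, n_datasets_per_condition = 2)
  s1 <- generate_study(cfg)
  s2 <- generate_study(cfg)
  expect_identical(lapply(s1$counts, `[[`, "counts"), lapply(s2$counts, `[[`, "counts"))
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$catalog, s2$catalog)
})

test_that("generated counts respect the basic contract", {
  cfg <- synth_config(seed = 5, n_genes = 50, n_modules = 2, module_sizes = c(20L, 20L),
                      n_samples = 12, n_datasets_per_condition = 2, libsize_range = 1.5)
  st <- generate_study(cfg)
  expect_length(st$counts, 4) # 2 datasets x 2 conditions
  for (cm in st$counts) {
    expect_true(all(cm$counts >= 0))
    expect_true(all(cm$counts == round(cm$counts)))
    sf <- cm$sim$libsize_factors
    expect_lte(max(sf) / min(sf), 1.5)
  }
  # category sets contain only protein-coding module members
  pc <- st$catalog$gene_id[st$catalog$biotype == "protein_coding"]
  for (m in 1:2) {
    set <- st$category_sets[[sprintf("CAT_%d", m)]]
    expect_true(all(set %in% pc))
    expect_true(all(st$truth$module_of[set] == m))
  }
  # every lncRNA with a category sits in the module carrying that category
  for (g in names(st$truth$lncrna_category_of)) {
    cats <- st$truth$lncrna_category_of[[g]]
    if (length(cats)) {
      expect_identical(cats, sprintf("CAT_%d", st$truth$module_of[[g]]))
    }
  }
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(n_genes = 10, n_modules = 2, module_sizes = c(8L, 8L)),
               "module_sizes")
  expect_error(synth_config(frac_lncrna = 1.4), "frac_lncrna")
  expect_error(synth_config(n_samples = 0), "n_samples")
  expect_error(synth_config(rewire_probs = c(1, 1)), "rewire_probs")
})

test_that("same-module genes are strongly correlated when noise vanishes", {
  # Monte-Carlo over replicate studies: near-deterministic counts and high
  # latent correlation must yield empirical correlation > 0.8 nearly always
  hits <- vapply(seq_len(200), function(i) {
    cfg <- synth_config(
      seed = 1000 + i, n_genes = 10, n_modules = 1, module_sizes = 10L,
      n_samples = 50, n_datasets_per_condition = 1,
      within_module_cor = 0.95, nb_dispersion = 0, frac_negative_loadings = 0,
      rewired_module_fraction = 0, frac_lncrna = 0
    )
    st <- generate_study(cfg)
    x <- log2(st$counts$ds1_A$counts + 1)
    cor(x[1, ], x[2, ]) > 0.8
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("no rewiring means identical latent structure in both conditions", {
  cfg <- synth_config(seed = 3, rewired_module_fraction = 0, n_genes = 60,
                      n_modules = 2, module_sizes = c(25L, 25L), n_samples = 8)
  st <- generate_study(cfg)
  expect_identical(st$truth$loadings_A, st$truth$loadings_B)
  expect_identical(st$truth$module_of, st$truth$module_of_B)
  expect_length(st$truth$rewired_modules, 0)
})

test_that("rewired modules plant all three differential link categories", {
  cfg <- synth_config(seed = 9, rewired_module_fraction = 0.5, n_modules = 2,
                      n_genes = 120, module_sizes = c(50L, 50L), n_samples = 8)
  st <- generate_study(cfg)
  act <- st$truth$rewire_action
  expect_setequal(unique(unname(act)), c("keep", "flip", "drop"))
  expect_gt(length(st$truth$recruits), 0)
  # flipped genes reverse their loading, dropped genes detach
  flipped <- names(act)[act == "flip"]
  dropped <- names(act)[act == "drop"]
  expect_true(all(st$truth$loadings_B[flipped] == -st$truth$loadings_A[flipped]))
  expect_true(all(st$truth$loadings_B[dropped] == 0))
})

test_that("planted differential expression shifts means by 2^effect", {
  cfg <- synth_config(seed = 21, n_genes = 40, n_modules = 1, module_sizes = 1L,
                      n_samples = 250, n_datasets_per_condition = 1,
                      latent_sd = 0.4, nb_dispersion = 0.05)
  st <- generate_study(cfg)
  a <- st$counts$ds1_A
  b <- st$counts$ds1_B
  expect_error(plant_differential_expression(b, c(nope = 1)), "unknown gene")

  # zero effect leaves counts untouched
  b0 <- plant_differential_expression(b, setNames(0, rownames(b$counts)[1]))
  expect_identical(b0$counts, b$counts)

  set.seed(42)
  b1 <- plant_differential_expression(b, setNames(1, "g0005"))
  de <- differential_expression(a, b1)
  expect_equal(de$log2fc[de$gene == "g0005"], 1, tolerance = 0.2)
  expect_identical(de$direction[de$gene == "g0005"], "up")
})

test_that("planted DEGs are recovered with power > 0.8 and few false calls", {
  cfg <- synth_config(seed = 33, n_genes = 200, n_modules = 1, module_sizes = 1L,
                      n_samples = 100, n_datasets_per_condition = 1,
                      latent_sd = 0.3, nb_dispersion = 0.05)
  st <- generate_study(cfg)
  planted <- sprintf("g%04d", 11:20)
  set.seed(7)
  b <- plant_differential_expression(st$counts$ds1_B, setNames(rep(-0.5, 10), planted))
  de <- differential_expression(st$counts$ds1_A, b)
  called <- de$gene[de$direction != "ns"]
  expect_gt(mean(planted %in% called), 0.8)            # power
  expect_gte(mean(called %in% planted), 0.8)           # precision
  expect_true(all(de$direction[de$gene %in% intersect(called, planted)] == "down"))
})
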