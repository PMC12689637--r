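#' Configuration for the synthetic two-condition co-expression study
#'
#' Defines the generative model used by [generate_study()]: a multi-dataset,
#' two-condition bulk RNA-seq design with planted co-expression modules,
#' planted condition-specific rewiring, and known lncRNA category truth.
#' Genes in a module share a per-sample latent module eigengene; counts are
#' drawn negative-binomially from the exponentiated latent mean.
#'
#' The defaults emulate a multi-cohort brain study: three datasets per
#' condition from one region, 40 samples per dataset per condition, four
#' planted modules of 50 genes (plus 20 unassigned background genes), a
#' quarter of modules rewired between conditions, and a quarter of module
#' genes being lncRNAs.
#'
#' @param n_genes total number of genes.
#' @param frac_lncrna fraction of genes (within modules and background) that
#'   are lncRNAs; the rest are protein-coding.
#' @param n_modules number of planted co-expression modules.
#' @param module_sizes integer vector of length `n_modules`; must sum to at
#'   most `n_genes`. Remaining genes are unassigned background noise genes.
#' @param n_datasets_per_condition independent datasets simulated per
#'   condition (each dataset yields one count matrix per condition).
#' @param n_samples samples per dataset per condition.
#' @param rewired_module_fraction fraction of modules whose correlation
#'   structure differs between conditions A and B.
#' @param within_module_cor target latent correlation between two genes of
#'   the same module (before count noise), in `[0, 1]`.
#' @param nb_dispersion negative-binomial dispersion (`size = 1/dispersion`);
#'   `0` gives Poisson counts.
#' @param mean_log_expression baseline natural-log mean expression.
#' @param latent_sd standard deviation (natural-log scale) of the latent
#'   expression signal; controls biological signal strength.
#' @param frac_negative_loadings fraction of module members whose loading on
#'   the module eigengene is negative, planting negative links.
#' @param libsize_range library-size factors are drawn uniformly on the log
#'   scale such that the ratio of the largest to the smallest factor is at
#'   most this value.
#' @param rewire_probs length-3 probabilities (keep, flip, drop) applied
#'   independently to each gene of a rewired module in condition B. "keep"
#'   leaves the loading unchanged, "flip" reverses its sign (planting
#'   reversed links), "drop" detaches the gene (planting A-specific links).
#' @param recruit_frac fraction (of module size) of background genes
#'   recruited into each rewired module in condition B only, planting
#'   B-specific links.
#' @param region region label carried on the generated count matrices.
#' @param seed integer RNG seed; identical config and seed give
#'   byte-identical output.
#'
#' @return A validated list of class `synth_config`.
#' @seealso [generate_study()]
#' @export
synth_config <- function(n_genes = 220,
                         frac_lncrna = 0.25,
                         n_modules = 4,
                         module_sizes = rep(50L, 4),
                         n_datasets_per_condition = 3,
                         n_samples = 40,
                         rewired_module_fraction = 0.25,
                         within_module_cor = 0.97,
                         nb_dispersion = 0.05,
                         mean_log_expression = 6.5,
                         latent_sd = 1.0,
                         frac_negative_loadings = 0.5,
                         libsize_range = 2,
                         rewire_probs = c(keep = 0.2, flip = 0.3, drop = 0.5),
                         recruit_frac = 0.2,
                         region = "TCX",
                         seed = 1L) {
  n_genes <- assert_count(n_genes, "n_genes")
  n_modules <- assert_count(n_modules, "n_modules")
  n_datasets_per_condition <- assert_count(n_datasets_per_condition, "n_datasets_per_condition")
  n_samples <- assert_count(n_samples, "n_samples")
  assert_fraction(frac_lncrna, "frac_lncrna")
  assert_fraction(rewired_module_fraction, "rewired_module_fraction")
  assert_fraction(within_module_cor, "within_module_cor")
  assert_fraction(frac_negative_loadings, "frac_negative_loadings")
  assert_fraction(recruit_frac, "recruit_frac")
  if (length(module_sizes) != n_modules) {
    abort("`module_sizes` must have length `n_modules`")
  }
  module_sizes <- vapply(seq_along(module_sizes), function(i) {
    assert_count(module_sizes[i], sprintf("module_sizes[%d]", i))
  }, integer(1))
  if (sum(module_sizes) > n_genes) {
    abort("sum(module_sizes) must be <= n_genes")
  }
  if (!is.numeric(nb_dispersion) || nb_dispersion < 0) abort("`nb_dispersion` must be >= 0")
  if (!is.numeric(latent_sd) || latent_sd <= 0) abort("`latent_sd` must be > 0")
  if (!is.numeric(libsize_range) || libsize_range < 1) abort("`libsize_range` must be >= 1")
  if (length(rewire_probs) != 3 || any(rewire_probs < 0) || sum(rewire_probs) <= 0) {
    abort("`rewire_probs` must be 3 non-negative probabilities (keep, flip, drop)")
  }
  rewire_probs <- rewire_probs / sum(rewire_probs)
  structure(
    list(
      n_genes = n_genes, frac_lncrna = frac_lncrna, n_modules = n_modules,
      module_sizes = module_sizes,
      n_datasets_per_condition = n_datasets_per_condition,
      n_samples = n_samples,
      rewired_module_fraction = rewired_module_fraction,
      within_module_cor = within_module_cor,
      nb_dispersion = nb_dispersion,
      mean_log_expression = mean_log_expression,
      latent_sd = latent_sd,
      frac_negative_loadings = frac_negative_loadings,
      libsize_range = libsize_range,
      rewire_probs = setNames(as.numeric(rewire_probs), c("keep", "flip", "drop")),
      recruit_frac = recruit_frac,
      region = as.character(region)[1],
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

#' Generate a synthetic multi-dataset two-condition study
#'
#' Simulates one count matrix per (dataset, condition) pair under the latent
#' eigengene model of [synth_config()], together with a gene catalog
#' (biotypes), module-derived functional category gene sets, and the planted
#' ground truth needed to score downstream recovery.
#'
#' Genes of a non-rewired module share the same latent structure in both
#' conditions (module eigengenes themselves are redrawn per dataset and
#' condition; it is the correlation structure that is shared). Rewired
#' modules have their gene loadings re-assigned in condition B (kept,
#' sign-flipped, or dropped, per `rewire_probs`) and recruit background
#' genes, so that conserved, condition-specific and reversed links are all
#' planted. Protein-coding members of module *m* form the gene set of
#' category `CAT_m`; lncRNA members are left out of the category sets but
#' recorded in the ground truth.
#'
#' @param config a [synth_config()].
#' @return An object of class `synth_study`: a list with elements
#'   * `counts`: named list of [count_matrix] objects (`"<dataset>_<condition>"`),
#'   * `catalog`: tibble with `gene_id`, `biotype`,
#'   * `category_sets`: named list of protein-coding gene id vectors,
#'   * `truth`: list with `module_of` (named integer, `NA` = background),
#'     `lncrna_category_of` (named list of character), `rewired_modules`,
#'     `rewire_action` (named character for genes of rewired modules),
#'     `recruits` (named integer: background gene -> module joined in B),
#'     `loadings_A`/`loadings_B` (named numeric), and `de_genes`
#'     (named numeric log2 effects, empty until planted),
#'   * `config`: the input configuration.
#' @export
generate_study <- function(config) {
  if (!inherits(config, "synth_config")) abort("`config` must be a `synth_config`")
  set.seed(config$seed)
  cf <- config

  gene_ids <- sprintf("g%04d", seq_len(cf$n_genes))
  module_of <- rep(NA_integer_, cf$n_genes)
  names(module_of) <- gene_ids
  idx <- 1L
  for (m in seq_len(cf$n_modules)) {
    module_of[idx:(idx + cf$module_sizes[m] - 1L)] <- m
    idx <- idx + cf$module_sizes[m]
  }

  # biotypes: a fixed fraction of each module (and of the background) are
  # lncRNAs, so every module carries annotatable lncRNAs
  biotype <- rep("protein_coding", cf$n_genes)
  names(biotype) <- gene_ids
  for (m in c(seq_len(cf$n_modules), NA)) {
    in_grp <- if (is.na(m)) which(is.na(module_of)) else which(module_of == m)
    if (!length(in_grp)) next
    n_lnc <- round(cf$frac_lncrna * length(in_grp))
    if (n_lnc > 0) biotype[sample(in_grp, n_lnc)] <- "lncRNA"
  }

  # signed loadings in condition A
  loadings_A <- ifelse(is.na(module_of), 0, 1)
  names(loadings_A) <- gene_ids
  for (m in seq_len(cf$n_modules)) {
    members <- which(module_of == m)
    n_neg <- round(cf$frac_negative_loadings * length(members))
    if (n_neg > 0) loadings_A[sample(members, n_neg)] <- -1
  }

  # condition-B rewiring
  n_rewired <- round(cf$rewired_module_fraction * cf$n_modules)
  rewired_modules <- if (n_rewired > 0) sort(sample(cf$n_modules, n_rewired)) else integer(0)
  loadings_B <- loadings_A
  module_of_B <- module_of
  rewire_action <- character(0)
  recruits <- integer(0)
  background <- which(is.na(module_of))
  for (m in rewired_modules) {
    members <- which(module_of == m)
    act <- sample(c("keep", "flip", "drop"), length(members),
                  replace = TRUE, prob = cf$rewire_probs)
    loadings_B[members] <- loadings_A[members] * c(keep = 1, flip = -1, drop = 0)[act]
    module_of_B[members[act == "drop"]] <- NA_integer_
    rewire_action <- c(rewire_action, setNames(act, gene_ids[members]))
    n_rec <- min(round(cf$recruit_frac * length(members)), length(background))
    if (n_rec > 0) {
      rec <- sample(background, n_rec)
      background <- setdiff(background, rec)
      loadings_B[rec] <- 1
      module_of_B[rec] <- m
      recruits <- c(recruits, setNames(rep(m, n_rec), gene_ids[rec]))
    }
  }

  category_sets <- lapply(seq_len(cf$n_modules), function(m) {
    gene_ids[which(module_of == m & biotype == "protein_coding")]
  })
  names(category_sets) <- sprintf("CAT_%d", seq_len(cf$n_modules))

  lnc_ids <- gene_ids[biotype == "lncRNA"]
  lncrna_category_of <- lapply(lnc_ids, function(g) {
    m <- module_of[[g]]
    if (is.na(m)) character(0) else sprintf("CAT_%d", m)
  })
  names(lncrna_category_of) <- lnc_ids

  counts <- list()
  for (k in seq_len(cf$n_datasets_per_condition)) {
    for (cond in c("A", "B")) {
      load <- if (cond == "A") loadings_A else loadings_B
      mod <- if (cond == "A") module_of else module_of_B
      Z <- matrix(rnorm(cf$n_modules * cf$n_samples), cf$n_modules, cf$n_samples)
      if (cf$n_samples >= cf$n_modules && cf$n_modules > 1) {
        # module eigengenes are independent latent pathways: orthogonalize
        # so no chance sample-correlation between modules leaks into the
        # planted structure
        Z <- t(qr.Q(qr(t(Z)))) * sqrt(cf$n_samples)
      }
      E <- matrix(rnorm(cf$n_genes * cf$n_samples), cf$n_genes, cf$n_samples)
      x <- E
      member <- which(load != 0)
      rho <- cf$within_module_cor
      x[member, ] <- load[member] *
        (sqrt(rho) * Z[mod[member], , drop = FALSE] +
           sqrt(1 - rho) * E[member, , drop = FALSE])
      sf <- exp(runif(cf$n_samples, -log(cf$libsize_range) / 2, log(cf$libsize_range) / 2))
      mu <- exp(cf$mean_log_expression + cf$latent_sd * x)
      mu <- sweep(mu, 2, sf, `*`)
      cts <- draw_nb(mu, cf$nb_dispersion)
      dimnames(cts) <- list(gene_ids, sprintf("ds%d_%s_s%02d", k, cond, seq_len(cf$n_samples)))
      dimnames(mu) <- dimnames(cts)
      cm <- count_matrix(cts, dataset_id = sprintf("ds%d", k),
                         condition = cond, region = cf$region)
      cm$sim <- list(mu = mu, dispersion = cf$nb_dispersion, libsize_factors = sf)
      counts[[sprintf("ds%d_%s", k, cond)]] <- cm
    }
  }

  structure(
    list(
      counts = counts,
      catalog = tibble(gene_id = gene_ids, biotype = unname(biotype)),
      category_sets = category_sets,
      truth = list(
        module_of = module_of,
        module_of_B = module_of_B,
        lncrna_category_of = lncrna_category_of,
        rewired_modules = rewired_modules,
        rewire_action = rewire_action,
        recruits = recruits,
        loadings_A = loadings_A,
        loadings_B = loadings_B,
        de_genes = setNames(numeric(0), character(0))
      ),
      config = cf
    ),
    class = "synth_study"
  )
}

draw_nb <- function(mu, dispersion) {
  n <- length(mu)
  cts <- if (dispersion > 0) {
    rnbinom(n, mu = as.vector(mu), size = 1 / dispersion)
  } else {
    rpois(n, as.vector(mu))
  }
  matrix(cts, nrow = nrow(mu), ncol = ncol(mu))
}

#' @export
print.synth_study <- function(x, ...) {
  cat(sprintf(
    "<synth_study> %d genes (%d lncRNA), %d modules, %d count matrices, %d rewired module(s)\n",
    x$config$n_genes, sum(x$catalog$biotype == "lncRNA"), x$config$n_modules,
    length(x$counts), length(x$truth$rewired_modules)
  ))
  invisible(x)
}

#' Plant differential expression into a synthetic count matrix
#'
#' Scales the negative-binomial mean of selected genes by `2^effect` and
#' redraws their counts (dispersion unchanged). Genes with a zero effect
#' keep their original counts. Only matrices produced by [generate_study()]
#' carry the simulation parameters this needs.
#'
#' @param counts a [count_matrix] produced by [generate_study()].
#' @param effects named numeric vector of log2 effects; names must be gene
#'   ids present in `counts`.
#' @return The modified [count_matrix].
#' @export
plant_differential_expression <- function(counts, effects) {
  if (!inherits(counts, "count_matrix")) abort("`counts` must be a `count_matrix`")
  if (is.null(counts$sim)) {
    abort("`counts` carries no simulation parameters; only synthetic matrices from generate_study() can be modified")
  }
  if (is.null(names(effects)) || !is.numeric(effects)) {
    abort("`effects` must be a named numeric vector")
  }
  unknown <- setdiff(names(effects), genes(counts))
  if (length(unknown)) {
    abort(sprintf("unknown gene(s) in `effects`: %s", paste(head(unknown, 5), collapse = ", ")))
  }
  hit <- names(effects)[effects != 0]
  if (length(hit)) {
    mu <- counts$sim$mu
    mu[hit, ] <- mu[hit, , drop = FALSE] * 2^effects[hit]
    new_rows <- draw_nb(mu[hit, , drop = FALSE], counts$sim$dispersion)
    counts$counts[hit, ] <- new_rows
    counts$sim$mu <- mu
  }
  counts
}

#' Write the plain-text artifacts of a synthetic study
#'
#' Writes one count TSV per (dataset, condition), the gene catalog TSV, the
#' category sets as GMT, and the ground truth as YAML.
#'
#' @param study a `synth_study` from [generate_study()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the vector of written file paths.
#' @export
write_study <- function(study, dir) {
  if (!inherits(study, "synth_study")) abort("`study` must be a `synth_study`")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(study$counts)) {
    p <- file.path(dir, paste0("counts_", nm, ".tsv"))
    write_count_tsv(study$counts[[nm]], p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "gene_catalog.tsv")
  write.table(study$catalog, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "category_sets.gmt")
  write_gmt(study$category_sets, p)
  paths <- c(paths, p)
  p <- file.path(dir, "ground_truth.yaml")
  tr <- study$truth
  yaml::write_yaml(list(
    module_of = as.list(tr$module_of),
    rewired_modules = as.list(tr$rewired_modules),
    lncrna_category_of = tr$lncrna_category_of,
    de_genes = as.list(tr$de_genes)
  ), p)
  paths <- c(paths, p)
  invisible(paths)
}
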