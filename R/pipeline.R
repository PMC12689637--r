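#' Pipeline configuration
#'
#' Collects every tunable threshold of the workflow in one object that
#' round-trips losslessly through YAML ([write_config()] / [read_config()]).
#'
#' @param wto_cutoff absolute wTO weight below which links are discarded
#'   per dataset (default 0.5; the boundary value is retained).
#' @param diff_cutoff presence cutoff for differential link classification
#'   (default 0.33).
#' @param rwr_restart restart probability for the random walk (default 0.7).
#' @param assign_percentile percentile of cluster lncRNA scores defining
#'   assignment eligibility (default 90, i.e. the top decile).
#' @param min_cluster_links minimum internal links for a Louvain cluster to
#'   be retained (default 20).
#' @param louvain_resolution Louvain resolution (default 1).
#' @param cpm_min,cpm_frac CPM filter thresholds (defaults 1 and 0.7).
#' @param de_fdr,de_lfc significance thresholds for differential expression
#'   (defaults 0.05 and 0.3, log2 scale).
#' @param n_perm permutations for the overlap consistency test
#'   (default 10000).
#' @param seed master seed for the pipeline's stochastic stages (Louvain
#'   order, permutation tests).
#' @param synth a [synth_config()] used when [run_pipeline()] is asked to
#'   simulate its input; `NULL` when data are supplied.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(wto_cutoff = 0.5,
                            diff_cutoff = 0.33,
                            rwr_restart = 0.7,
                            assign_percentile = 90,
                            min_cluster_links = 20,
                            louvain_resolution = 1,
                            cpm_min = 1,
                            cpm_frac = 0.7,
                            de_fdr = 0.05,
                            de_lfc = 0.3,
                            n_perm = 10000,
                            seed = 1L,
                            synth = synth_config()) {
  stopifnot(wto_cutoff > 0, wto_cutoff < 1, diff_cutoff > 0, diff_cutoff < 1,
            rwr_restart >= 0, rwr_restart <= 1,
            assign_percentile >= 0, assign_percentile <= 100,
            min_cluster_links >= 0, cpm_min >= 0, cpm_frac >= 0, cpm_frac <= 1,
            de_fdr > 0, de_fdr < 1, de_lfc >= 0, n_perm >= 1)
  structure(
    list(
      wto_cutoff = wto_cutoff, diff_cutoff = diff_cutoff,
      rwr_restart = rwr_restart, assign_percentile = assign_percentile,
      min_cluster_links = min_cluster_links,
      louvain_resolution = louvain_resolution,
      cpm_min = cpm_min, cpm_frac = cpm_frac,
      de_fdr = de_fdr, de_lfc = de_lfc,
      n_perm = n_perm, seed = as.integer(seed),
      synth = synth
    ),
    class = "pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$synth <- if (is.null(config$synth)) NULL else unclass(config$synth)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  synth <- if (is.null(x$synth)) NULL else do.call(synth_config, x$synth[names(x$synth) != "rewire_probs"] |>
                                                    c(list(rewire_probs = unlist(x$synth$rewire_probs))))
  x$synth <- NULL
  do.call(pipeline_config, c(x, list(synth = synth)))
}

#' Log-scale normalized expression for network construction
#'
#' Median-of-ratios normalization followed by a `log2(x + 1)` transform:
#' the expression scale on which gene-gene correlations are computed.
#'
#' @param counts a [count_matrix].
#' @return A genes x samples numeric matrix.
#' @export
log_normalized <- function(counts) {
  log2(median_of_ratios_normalize(counts)$normalized + 1)
}

#' Run the full consensus co-expression workflow
#'
#' Per-dataset signed wTO networks are built from filtered, normalized,
#' log-transformed counts and hard-thresholded; same-condition networks are
#' integrated into a consensus network; the two condition networks are
#' compared link by link; core hubs, Louvain clusters, cluster enrichment
#' and RWR-based lncRNA assignments are derived per condition; and the
#' validation statistics (core lncRNA enrichment, assignment consistency
#' between conditions) are computed.
#'
#' @param config a [pipeline_config()].
#' @param study optional `synth_study` (or a list shaped like one:
#'   `counts` as a named list of [count_matrix] per dataset/condition,
#'   `catalog`, `category_sets`); when `NULL`, a study is simulated from
#'   `config$synth`.
#' @param verbose emit progress messages (default TRUE).
#' @return A `consenet_result` list: `networks` (per dataset/condition
#'   thresholded `wto_network`s), `bookkeeping` (link/node counts per
#'   stage), `consensus` (`$A`, `$B`), `diff_links`, `abundance` (per
#'   cluster of A), `cores`, `core_overlap`, `partitions`, `enrichment`,
#'   `assignments`, `degs` (per dataset and `$consensus`), `validation`,
#'   `config`, `config_hash`, and `study` when simulated.
#' @export
run_pipeline <- function(config = pipeline_config(), study = NULL, verbose = TRUE) {
  if (!inherits(config, "pipeline_config")) abort("`config` must be a `pipeline_config`")
  say <- function(...) if (verbose) inform(sprintf(...))
  simulated <- is.null(study)
  if (simulated) {
    if (is.null(config$synth)) abort("no input study and no `synth` config to simulate one")
    say("simulating study (seed %d)", config$synth$seed)
    study <- generate_study(config$synth)
  }
  cm <- study$counts
  conds <- vapply(cm, function(x) x$condition, character(1))
  dsets <- vapply(cm, function(x) x$dataset_id, character(1))
  if (!setequal(unique(conds), c("A", "B"))) abort("study must contain conditions A and B")

  # per-dataset networks -----------------------------------------------
  networks <- list()
  filtered_genes <- list()
  bookkeeping <- list()
  for (nm in names(cm)) {
    filtered <- cpm_filter(cm[[nm]], min_cpm = config$cpm_min, min_frac = config$cpm_frac)
    filtered_genes[[nm]] <- genes(filtered)
    expr <- log_normalized(filtered)
    net <- hard_threshold(signed_wto(pearson_adjacency(expr)), cutoff = config$wto_cutoff)
    networks[[nm]] <- net
    fc <- attr(net, "filter_counts")
    bookkeeping[[nm]] <- dplyr::mutate(fc, network = nm, .before = 1)
    say("network %-8s %6d -> %5d links, %4d -> %4d nodes", nm,
        fc$links[1], fc$links[2], fc$nodes[1], fc$nodes[2])
  }

  # consensus per condition --------------------------------------------
  consensus <- list()
  for (cond in c("A", "B")) {
    nets <- networks[conds == cond]
    consensus[[cond]] <- consensus_integrate(nets)
    bookkeeping[[paste0("consensus_", cond)]] <- tibble(
      network = paste0("consensus_", cond), stage = "consensus",
      links = nrow(consensus[[cond]]),
      nodes = length(attr(consensus[[cond]], "nodes")),
      cutoff = config$wto_cutoff
    )
    say("consensus %s: %d links over %d nodes", cond,
        nrow(consensus[[cond]]), length(attr(consensus[[cond]], "nodes")))
  }

  # differential expression --------------------------------------------
  degs <- list()
  for (d in unique(dsets)) {
    a <- cm[[which(dsets == d & conds == "A")[1]]]
    b <- cm[[which(dsets == d & conds == "B")[1]]]
    degs[[d]] <- differential_expression(a, b, fdr_max = config$de_fdr, lfc_min = config$de_lfc)
  }
  degs$consensus <- consensus_degs(degs[unique(dsets)])
  say("consensus DEGs: %d", nrow(degs$consensus))

  # differential co-expression -----------------------------------------
  diff_links <- classify_links(consensus$A, consensus$B, cutoff = config$diff_cutoff)
  say("link categories: %s",
      paste(sprintf("%s=%d", levels(diff_links$category), table(diff_links$category)), collapse = " "))

  # topology -------------------------------------------------------------
  cores <- lapply(consensus, kcore_decomposition)
  partitions <- list(
    A = louvain_clusters(consensus$A, resolution = config$louvain_resolution,
                         min_links = config$min_cluster_links, seed = config$seed),
    B = louvain_clusters(consensus$B, resolution = config$louvain_resolution,
                         min_links = config$min_cluster_links, seed = config$seed + 1L)
  )
  abundance <- list(
    A = category_abundance(diff_links, as_tibble(partitions$A)),
    B = category_abundance(diff_links, as_tibble(partitions$B))
  )
  say("clusters: A=%d B=%d; cores: A=%d B=%d",
      glance(partitions$A)$n_clusters, glance(partitions$B)$n_clusters,
      length(attr(cores$A, "core_set")), length(attr(cores$B, "core_set")))

  # enrichment + lncRNA annotation --------------------------------------
  enrichment <- list()
  assignments <- list()
  for (cond in c("A", "B")) {
    bg <- Reduce(intersect, filtered_genes[conds == cond])
    enrichment[[cond]] <- cluster_enrichment(
      partitions[[cond]], study$catalog, study$category_sets, background = bg
    )
    assignments[[cond]] <- annotate_lncrnas(
      consensus[[cond]], partitions[[cond]], enrichment[[cond]],
      study$catalog, study$category_sets,
      r = config$rwr_restart, percentile = config$assign_percentile
    )
    say("%s: %d significant (cluster, term) pairs, %d accepted lncRNA assignments",
        cond, sum(enrichment[[cond]]$significant), sum(assignments[[cond]]$accepted))
  }

  # validation ----------------------------------------------------------
  lnc_ids <- study$catalog$gene_id[study$catalog$biotype == "lncRNA"]
  core_counts <- lapply(cores, function(co) {
    cs <- attr(co, "core_set")
    c(n_lnc = sum(cs %in% lnc_ids), n_pc = sum(!cs %in% lnc_ids))
  })
  fisher <- tryCatch(
    core_lncrna_enrichment(core_counts$A, core_counts$B),
    error = function(e) e
  )
  acc_sets <- lapply(assignments, function(asg) {
    asg <- dplyr::filter(asg, .data$accepted)
    split(asg$gene, asg$category)
  })
  pools <- lapply(consensus, function(net) intersect(attr(net, "nodes"), lnc_ids))
  consistency <- tryCatch(
    overlap_consistency_test(acc_sets$A, acc_sets$B, pools$A, pools$B,
                             n_perm = config$n_perm, seed = config$seed + 2L),
    error = function(e) e
  )
  validation <- list(
    core_counts = core_counts,
    core_lncrna_fisher = fisher,
    assignment_consistency = consistency
  )

  structure(
    list(
      networks = networks,
      bookkeeping = dplyr::bind_rows(bookkeeping),
      consensus = consensus,
      degs = degs,
      diff_links = diff_links,
      abundance = abundance,
      cores = cores,
      core_overlap = core_overlap(cores$A, cores$B),
      partitions = partitions,
      enrichment = enrichment,
      assignments = assignments,
      validation = validation,
      config = config,
      config_hash = config_hash(unclass(config)),
      study = if (simulated) study else NULL
    ),
    class = "consenet_result"
  )
}

#' @export
print.consenet_result <- function(x, ...) {
  cat("<consenet_result>\n")
  cat(sprintf("  consensus A: %d links | consensus B: %d links\n",
              nrow(x$consensus$A), nrow(x$consensus$B)))
  cat(sprintf("  cores: A=%d B=%d (shared %d)\n",
              length(attr(x$cores$A, "core_set")),
              length(attr(x$cores$B, "core_set")),
              x$core_overlap$counts[["shared"]]))
  cat(sprintf("  accepted lncRNA assignments: A=%d B=%d\n",
              sum(x$assignments$A$accepted), sum(x$assignments$B$accepted)))
  cat(sprintf("  config hash: %s\n", x$config_hash))
  invisible(x)
}

#' Write every pipeline artifact to a directory
#'
#' All tables are TSV with `#` provenance headers carrying the config hash;
#' identical configurations produce identical hashes.
#'
#' @param result a `consenet_result` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_pipeline_results <- function(result, dir) {
  if (!inherits(result, "consenet_result")) abort("`result` must come from run_pipeline()")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  hdr <- sprintf("config_hash=%s", result$config_hash)
  paths <- character(0)
  wt <- function(df, name, edge = FALSE) {
    p <- file.path(dir, name)
    if (edge) {
      write_edges_tsv(df, p, header = hdr)
    } else {
      write_lines_with_header(hdr, function(con) {
        write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
      }, p)
    }
    paths <<- c(paths, p)
  }
  for (nm in names(result$networks)) wt(result$networks[[nm]], sprintf("wto_%s.tsv", nm), edge = TRUE)
  for (cond in c("A", "B")) {
    wt(result$consensus[[cond]], sprintf("consensus_%s.tsv", cond), edge = TRUE)
    wt(result$cores[[cond]], sprintf("coreness_%s.tsv", cond))
    wt(result$partitions[[cond]], sprintf("clusters_%s.tsv", cond))
    wt(result$enrichment[[cond]], sprintf("enrichment_%s.tsv", cond))
    wt(result$assignments[[cond]], sprintf("lncrna_assignments_%s.tsv", cond))
  }
  wt(as_tibble(result$diff_links), "diff_links.tsv", edge = TRUE)
  wt(result$bookkeeping, "network_sizes.tsv")
  for (d in names(result$degs)) wt(result$degs[[d]], sprintf("degs_%s.tsv", d))
  p <- file.path(dir, "config.yaml")
  write_config(result$config, p)
  paths <- c(paths, p)
  invisible(paths)
}
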