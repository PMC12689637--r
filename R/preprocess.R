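#' Filter lowly expressed genes by counts per million
#'
#' Keeps genes with at least `min_cpm` counts per million in at least
#' `min_frac` of the samples. CPM is computed against each sample's total
#' library size, so the filter does not favour genes from larger libraries.
#'
#' @param counts a [count_matrix].
#' @param min_cpm minimum counts-per-million, default 1.
#' @param min_frac minimum fraction of samples reaching `min_cpm`
#'   (boundary included: a gene passing in exactly `min_frac` of samples is
#'   retained), default 0.7.
#' @return The filtered [count_matrix] (sample set unchanged). Warns if no
#'   gene survives.
#' @export
cpm_filter <- function(counts, min_cpm = 1, min_frac = 0.7) {
  if (!inherits(counts, "count_matrix")) abort("`counts` must be a `count_matrix`")
  assert_fraction(min_frac, "min_frac")
  lib <- colSums(counts$counts)
  if (any(lib <= 0)) abort("all library sizes must be > 0")
  cpm <- sweep(counts$counts, 2, lib / 1e6, `/`)
  keep <- rowMeans(cpm >= min_cpm) >= min_frac
  if (!any(keep)) warn("cpm_filter removed every gene")
  counts$counts <- counts$counts[keep, , drop = FALSE]
  if (!is.null(counts$sim)) counts$sim$mu <- counts$sim$mu[keep, , drop = FALSE]
  counts
}

#' Median-of-ratios size factors and normalized counts
#'
#' The standard RNA-seq size-factor estimator: each sample's size factor is
#' the median, over genes expressed in every sample, of the ratio between
#' the gene's count in that sample and the gene's geometric mean across
#' samples. Normalized counts are raw counts divided by the sample's size
#' factor.
#'
#' @param counts a [count_matrix] or a plain genes x samples matrix.
#' @return A list with `normalized` (matrix), `size_factors` (named numeric).
#' @export
median_of_ratios_normalize <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  if (!is.matrix(m)) abort("`counts` must be a matrix or count_matrix")
  all_pos <- rowSums(m > 0) == ncol(m)
  if (!any(all_pos)) {
    abort("no gene has a nonzero count in every sample; size factors are undefined")
  }
  log_geo <- rowMeans(log(m[all_pos, , drop = FALSE]))
  sf <- apply(m[all_pos, , drop = FALSE], 2, function(col) {
    exp(median(log(col) - log_geo))
  })
  list(normalized = sweep(m, 2, sf, `/`), size_factors = sf)
}

#' Per-dataset differential expression between two conditions
#'
#' A deterministic two-sample engine: counts of both groups are normalized
#' together by [median_of_ratios_normalize()], log2(x+1)-transformed, and
#' compared gene-wise with Welch's t-test; p-values are BH-adjusted. The
#' fold change is `log2((mean_B + 0.5) / (mean_A + 0.5))` on normalized
#' counts (pseudocount 0.5), so positive values mean higher expression in
#' condition B. A gene is called `up`/`down` only when both `fdr < fdr_max`
#' and `|log2FC| > lfc_min` hold; otherwise `ns`.
#'
#' @param counts_a,counts_b [count_matrix] objects for conditions A and B
#'   over the same gene set; each needs at least 2 samples.
#' @param fdr_max FDR significance threshold, default 0.05.
#' @param lfc_min absolute log2 fold-change threshold, default 0.3.
#' @return A tibble of class `de_table`: `gene`, `log2fc`, `pvalue`, `fdr`,
#'   `direction`, `degenerate` (TRUE when both groups had zero variance, in
#'   which case p = 1), `dataset_id`.
#' @export
differential_expression <- function(counts_a, counts_b, fdr_max = 0.05, lfc_min = 0.3) {
  for (cm in list(counts_a, counts_b)) {
    if (!inherits(cm, "count_matrix")) abort("inputs must be `count_matrix` objects")
    if (ncol(cm$counts) < 2) abort("each condition needs at least 2 samples")
  }
  if (!identical(genes(counts_a), genes(counts_b))) {
    shared <- intersect(genes(counts_a), genes(counts_b))
    if (!length(shared)) abort("the two conditions share no genes")
    counts_a$counts <- counts_a$counts[shared, , drop = FALSE]
    counts_b$counts <- counts_b$counts[shared, , drop = FALSE]
  }
  na <- ncol(counts_a$counts)
  joint <- cbind(counts_a$counts, counts_b$counts)
  norm <- median_of_ratios_normalize(joint)$normalized
  a <- norm[, seq_len(na), drop = FALSE]
  b <- norm[, -seq_len(na), drop = FALSE]
  la <- log2(a + 1)
  lb <- log2(b + 1)

  welch <- welch_t_rows(la, lb)
  log2fc <- log2((rowMeans(b) + 0.5) / (rowMeans(a) + 0.5))
  fdr <- p.adjust(welch$p, method = "BH")
  direction <- ifelse(
    fdr < fdr_max & abs(log2fc) > lfc_min,
    ifelse(log2fc > 0, "up", "down"),
    "ns"
  )
  out <- tibble(
    gene = rownames(norm),
    log2fc = unname(log2fc),
    pvalue = unname(welch$p),
    fdr = unname(fdr),
    direction = unname(direction),
    degenerate = unname(welch$degenerate),
    dataset_id = counts_a$dataset_id
  )
  class(out) <- c("de_table", class(out))
  attr(out, "thresholds") <- c(fdr_max = fdr_max, lfc_min = lfc_min)
  out
}

# vectorized Welch's t-test across matrix rows; degenerate rows (zero
# variance in both groups) get p = 1
welch_t_rows <- function(a, b) {
  na <- ncol(a)
  nb <- ncol(b)
  ma <- rowMeans(a)
  mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  degenerate <- se2 == 0
  tstat <- ifelse(degenerate, 0, (mb - ma) / sqrt(se2))
  df <- ifelse(
    degenerate, 1,
    se2^2 / (ifelse(va > 0, (va / na)^2 / (na - 1), 0) +
               ifelse(vb > 0, (vb / nb)^2 / (nb - 1), 0))
  )
  p <- ifelse(degenerate, 1, 2 * pt(abs(tstat), df, lower.tail = FALSE))
  list(p = p, stat = tstat, df = df, degenerate = degenerate)
}

#' Cross-dataset consensus of differentially expressed genes
#'
#' Applies the all-datasets intersection rule: a gene is a consensus DEG
#' only if it is significant (`direction != "ns"`) with the same direction
#' in every contributing table.
#'
#' @param tables a list of `de_table` tibbles from
#'   [differential_expression()] (at least one).
#' @return A tibble with `gene` and `direction`, one row per consensus DEG.
#' @export
consensus_degs <- function(tables) {
  if (!is.list(tables) || !length(tables) || inherits(tables, "data.frame")) {
    abort("`tables` must be a non-empty list of de_table objects")
  }
  sig <- purrr::map(tables, function(t) {
    dplyr::filter(as_tibble(t), .data$direction != "ns") |>
      dplyr::select("gene", "direction")
  })
  out <- purrr::reduce(sig, dplyr::inner_join, by = c("gene", "direction"))
  dplyr::arrange(out, .data$gene)
}

#' @export
#' @method glance de_table
glance.de_table <- function(x, ...) {
  tibble(
    dataset_id = x$dataset_id[1],
    n_genes = nrow(x),
    n_up = sum(x$direction == "up"),
    n_down = sum(x$direction == "down"),
    n_degenerate = sum(x$degenerate)
  )
}
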