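#' Szymkiewicz-Simpson overlap coefficient
#'
#' `|A intersect B| / min(|A|, |B|)`: the overlap of two sets normalized by
#' the smaller set, which accommodates large disparities in set size.
#'
#' @param a,b non-empty vectors (coerced to sets).
#' @return The coefficient in `[0, 1]`.
#' @export
szymkiewicz_simpson <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  if (!length(a) || !length(b)) abort("both sets must be non-empty")
  length(intersect(a, b)) / min(length(a), length(b))
}

#' Permutation test for the overlap of two annotated sets
#'
#' Tests whether the observed overlap coefficient between set `A` (drawn
#' from pool `pool_a`) and set `B` (from `pool_b`) exceeds what random
#' sets of the same sizes would produce. Each permutation draws `|A|`
#' elements from `pool_a` and `|B|` from `pool_b` without replacement and
#' recomputes the coefficient; the p-value is the proportion of
#' permutations with a coefficient at least as large as observed. When no
#' permutation reaches the observed value the p-value is reported as the
#' resolution bound `< 1/n_perm`.
#'
#' With `exact = TRUE` (pools of up to ~10 elements) every possible pair
#' of draws is enumerated instead, giving the exact permutation p-value.
#'
#' @param a,b the observed sets; must be subsets of their pools.
#' @param pool_a,pool_b the pools the sets were drawn from.
#' @param n_perm number of permutations, default 10000.
#' @param seed RNG seed for reproducible permutations.
#' @param exact enumerate all draws instead of sampling.
#' @return An `overlap_test` object: list with `observed`, `n_perm`,
#'   `count_ge` (permutations >= observed), `p_value` (`count_ge/n_perm`),
#'   `p_report` (character; the bound when `count_ge == 0`), `exact`,
#'   `seed`.
#' @export
permutation_overlap_test <- function(a, b, pool_a, pool_b, n_perm = 10000,
                                     seed = NULL, exact = FALSE) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  pool_a <- unique(as.character(pool_a)); pool_b <- unique(as.character(pool_b))
  if (length(setdiff(a, pool_a))) abort("`a` must be a subset of `pool_a`")
  if (length(setdiff(b, pool_b))) abort("`b` must be a subset of `pool_b`")
  observed <- szymkiewicz_simpson(a, b)
  if (exact) {
    if (choose(length(pool_a), length(a)) * choose(length(pool_b), length(b)) > 1e6) {
      abort("pools too large for exact enumeration; use exact = FALSE")
    }
    draws_a <- combn(pool_a, length(a), simplify = FALSE)
    draws_b <- combn(pool_b, length(b), simplify = FALSE)
    coefs <- unlist(lapply(draws_a, function(da) {
      vapply(draws_b, function(db) szymkiewicz_simpson(da, db), numeric(1))
    }))
    n_perm <- length(coefs)
    count_ge <- sum(coefs >= observed)
  } else {
    n_perm <- assert_count(n_perm, "n_perm")
    if (!is.null(seed)) set.seed(seed)
    count_ge <- 0L
    for (i in seq_len(n_perm)) {
      coef <- szymkiewicz_simpson(
        sample(pool_a, length(a)),
        sample(pool_b, length(b))
      )
      if (coef >= observed) count_ge <- count_ge + 1L
    }
  }
  p_value <- count_ge / n_perm
  structure(
    list(
      observed = observed,
      n_perm = n_perm,
      count_ge = count_ge,
      p_value = p_value,
      p_report = if (count_ge == 0) sprintf("< %g", 1 / n_perm) else format(p_value),
      exact = exact,
      seed = seed
    ),
    class = "overlap_test"
  )
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "Set-overlap permutation test\n  overlap coefficient = %.3g\n  p %s (%d of %d permutations >= observed%s)\n",
    x$observed,
    if (x$count_ge == 0) x$p_report else sprintf("= %s", format(x$p_value)),
    x$count_ge, x$n_perm, if (x$exact) ", exact enumeration" else ""
  ))
  invisible(x)
}

#' @export
#' @method tidy overlap_test
tidy.overlap_test <- function(x, ...) {
  tibble(
    observed = x$observed, p_value = x$p_value, p_report = x$p_report,
    count_ge = x$count_ge, n_perm = x$n_perm, exact = x$exact
  )
}

#' Aggregate consistency test for per-category set assignments
#'
#' Generalizes [permutation_overlap_test()] to a collection of category-wise
#' set pairs (e.g. lncRNAs assigned to each functional category in two
#' networks, or assigned vs ground-truth sets): the statistic is the mean
#' Szymkiewicz-Simpson coefficient across categories, and each permutation
#' redraws every category's sets from their pools preserving set sizes.
#' This combined statistic can resolve small per-category sets that an
#' individual test cannot.
#'
#' @param sets_a,sets_b named lists of sets; names are matched, categories
#'   missing from either side or empty on either side are dropped.
#' @param pool_a,pool_b the pools for the two sides.
#' @param n_perm number of permutations, default 1000.
#' @param seed RNG seed.
#' @return An `overlap_test` (statistic = mean coefficient) with an extra
#'   `per_category` tibble of observed coefficients.
#' @export
overlap_consistency_test <- function(sets_a, sets_b, pool_a, pool_b,
                                     n_perm = 1000, seed = NULL) {
  cats <- intersect(names(sets_a), names(sets_b))
  cats <- cats[vapply(cats, function(cc) length(sets_a[[cc]]) > 0 && length(sets_b[[cc]]) > 0, logical(1))]
  if (!length(cats)) abort("no category has non-empty sets on both sides")
  pool_a <- unique(as.character(pool_a)); pool_b <- unique(as.character(pool_b))
  obs <- vapply(cats, function(cc) szymkiewicz_simpson(sets_a[[cc]], sets_b[[cc]]), numeric(1))
  observed <- mean(obs)
  n_perm <- assert_count(n_perm, "n_perm")
  if (!is.null(seed)) set.seed(seed)
  sizes_a <- vapply(cats, function(cc) length(unique(sets_a[[cc]])), integer(1))
  sizes_b <- vapply(cats, function(cc) length(unique(sets_b[[cc]])), integer(1))
  count_ge <- 0L
  for (i in seq_len(n_perm)) {
    stat <- mean(vapply(seq_along(cats), function(j) {
      szymkiewicz_simpson(sample(pool_a, sizes_a[j]), sample(pool_b, sizes_b[j]))
    }, numeric(1)))
    if (stat >= observed) count_ge <- count_ge + 1L
  }
  out <- structure(
    list(
      observed = observed, n_perm = n_perm, count_ge = count_ge,
      p_value = count_ge / n_perm,
      p_report = if (count_ge == 0) sprintf("< %g", 1 / n_perm) else format(count_ge / n_perm),
      exact = FALSE, seed = seed,
      per_category = tibble(category = cats, observed = unname(obs))
    ),
    class = "overlap_test"
  )
  out
}

#' Fisher's exact test for core lncRNA enrichment
#'
#' Builds the 2x2 contingency table of (lncRNA, protein-coding) counts
#' among the core genes of two networks and tests whether lncRNAs are
#' enriched among one network's core. The odds ratio is the cross-product
#' `(a_lnc * b_pc) / (a_pc * b_lnc)`; the p-value is the standard two-sided
#' exact test (sum of hypergeometric probabilities of tables at most as
#' probable as the observed one).
#'
#' @param core_a,core_b length-2 numeric vectors `c(n_lncrna, n_pc)` for
#'   the two networks' core genes.
#' @return A `fisher_result`: list with `table`, `odds_ratio`, `p_value`.
#' @export
core_lncrna_enrichment <- function(core_a, core_b) {
  if (length(core_a) != 2 || length(core_b) != 2) {
    abort("`core_a` and `core_b` must each be c(n_lncrna, n_pc)")
  }
  m <- rbind(A = as.numeric(core_a), B = as.numeric(core_b))
  colnames(m) <- c("lncRNA", "protein_coding")
  if (any(m < 0) || any(m != round(m))) abort("counts must be non-negative integers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("every margin of the contingency table must be positive")
  }
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  p <- fisher.test(m)$p.value
  structure(
    list(table = m, odds_ratio = or, p_value = p),
    class = "fisher_result"
  )
}

#' @export
print.fisher_result <- function(x, ...) {
  cat("Core lncRNA enrichment (Fisher's exact test)\n")
  print(x$table)
  cat(sprintf("  odds ratio = %.3g, two-sided p = %.3g\n", x$odds_ratio, x$p_value))
  invisible(x)
}

#' @export
#' @method tidy fisher_result
tidy.fisher_result <- function(x, ...) {
  tibble(odds_ratio = x$odds_ratio, p_value = x$p_value,
         n11 = x$table[1, 1], n12 = x$table[1, 2],
         n21 = x$table[2, 1], n22 = x$table[2, 2])
}
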