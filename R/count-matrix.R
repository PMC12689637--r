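#' Count matrix container
#'
#' A light container for a genes x samples matrix of non-negative integer
#' RNA-seq counts together with the study metadata the pipeline needs:
#' which dataset the matrix came from, which condition (e.g. disease vs
#' control) and which brain region it profiles.
#'
#' @param counts numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids); non-negative integers.
#' @param dataset_id single string identifying the dataset.
#' @param condition single string, one of the two study conditions
#'   (conventionally `"A"` for control and `"B"` for case).
#' @param region single string, brain-region label (e.g. `"TCX"`).
#'
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, dataset_id, condition, region = "R1") {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    abort("`counts` must be a numeric matrix")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` must have gene ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(counts))) abort("duplicate gene ids in `counts`")
  if (anyDuplicated(colnames(counts))) abort("duplicate sample ids in `counts`")
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("`counts` must contain non-negative integers")
  }
  storage.mode(counts) <- "double" # one storage mode regardless of source
  structure(
    list(
      counts = counts,
      dataset_id = as.character(dataset_id)[1],
      condition = as.character(condition)[1],
      region = as.character(region)[1]
    ),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "<count_matrix> %d genes x %d samples | dataset=%s condition=%s region=%s\n",
    nrow(x$counts), ncol(x$counts), x$dataset_id, x$condition, x$region
  ))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

genes <- function(x) rownames(x$counts)
samples <- function(x) colnames(x$counts)

#' Tidy a count matrix into long format
#'
#' @param x a [count_matrix].
#' @param ... unused.
#' @return A tibble with columns `gene_id`, `sample_id`, `count`,
#'   `dataset_id`, `condition`, `region`.
#' @export
#' @method tidy count_matrix
tidy.count_matrix <- function(x, ...) {
  tibble(
    gene_id = rep(rownames(x$counts), times = ncol(x$counts)),
    sample_id = rep(colnames(x$counts), each = nrow(x$counts)),
    count = as.vector(x$counts),
    dataset_id = x$dataset_id,
    condition = x$condition,
    region = x$region
  )
}

#' @export
#' @method glance count_matrix
glance.count_matrix <- function(x, ...) {
  tibble(
    dataset_id = x$dataset_id, condition = x$condition, region = x$region,
    n_genes = nrow(x$counts), n_samples = ncol(x$counts),
    median_library_size = median(colSums(x$counts))
  )
}
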