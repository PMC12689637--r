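# Plain-text readers and writers. Every table is TSV; lines starting with
# `#` are provenance comments and are skipped on read.

write_lines_with_header <- function(header, writer, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  writer(con)
  invisible(path)
}

#' Write / read a count matrix as TSV
#'
#' Rows are genes (first column `gene_id`), columns are samples; dataset,
#' condition and region metadata travel in `#`-comment header lines.
#'
#' @param counts a [count_matrix].
#' @param path file path.
#' @return `write_count_tsv()` returns the path invisibly;
#'   `read_count_tsv()` returns a [count_matrix].
#' @export
write_count_tsv <- function(counts, path) {
  if (!inherits(counts, "count_matrix")) abort("`counts` must be a `count_matrix`")
  header <- c(
    sprintf("dataset_id=%s", counts$dataset_id),
    sprintf("condition=%s", counts$condition),
    sprintf("region=%s", counts$region)
  )
  write_lines_with_header(header, function(con) {
    df <- data.frame(gene_id = rownames(counts$counts), counts$counts,
                     check.names = FALSE)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }, path)
}

read_header_fields <- function(path) {
  lines <- readLines(path, n = 50)
  lines <- lines[startsWith(lines, "# ")]
  kv <- strsplit(sub("^# ", "", lines), "=", fixed = TRUE)
  kv <- kv[vapply(kv, length, integer(1)) == 2]
  setNames(vapply(kv, `[`, character(1), 2), vapply(kv, `[`, character(1), 1))
}

#' @rdname write_count_tsv
#' @export
read_count_tsv <- function(path) {
  meta <- read_header_fields(path)
  df <- read.delim(path, comment.char = "#", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") abort(sprintf("%s: first column must be `gene_id`", path))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  count_matrix(
    m,
    dataset_id = meta[["dataset_id"]] %||% "unknown",
    condition = meta[["condition"]] %||% "A",
    region = meta[["region"]] %||% "R1"
  )
}

#' Write / read an edge list as TSV
#'
#' Canonical form: columns `node1`, `node2` (with `node1 < node2`) plus any
#' weight columns. The writer enforces canonical ordering; the reader
#' re-canonicalizes (swapping reversed pairs) and rejects malformed rows.
#'
#' @param edges an edge tibble (`wto_network`, `consensus_network`,
#'   `diff_links`, or plain tibble with `node1`/`node2`).
#' @param path file path.
#' @param header optional character vector of extra provenance lines.
#' @return The path invisibly / a tibble of edges.
#' @export
write_edges_tsv <- function(edges, path, header = character(0)) {
  t <- canonicalize_edges(as_tibble(edges))
  write_lines_with_header(header, function(con) {
    write.table(t, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }, path)
}

#' @rdname write_edges_tsv
#' @export
read_edges_tsv <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                   check.names = FALSE)
  if (!all(c("node1", "node2") %in% names(df))) {
    abort(sprintf("%s: edge table needs `node1` and `node2` columns", path))
  }
  bad <- which(is.na(df$node1) | is.na(df$node2) | df$node1 == "" | df$node2 == "")
  if (length(bad)) {
    abort(sprintf("%s: malformed edge row(s) at line(s) %s", path,
                  paste(head(bad, 5), collapse = ", ")))
  }
  as_tibble(canonicalize_edges(df))
}

#' Write / read gene sets in GMT format
#'
#' One term per line: term, description, then tab-separated gene ids.
#' Duplicate genes within a term are deduplicated with a warning on read.
#'
#' @param sets named list of character vectors.
#' @param path file path.
#' @param descriptions optional named character vector of term descriptions.
#' @return The path invisibly / a named list of character vectors.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(names(sets) == "")) abort("`sets` must be a named list")
  lines <- vapply(names(sets), function(term) {
    desc <- if (!is.null(descriptions) && term %in% names(descriptions)) {
      descriptions[[term]]
    } else {
      "na"
    }
    paste(c(term, desc, sets[[term]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, integer(1)) < 3
  if (any(short)) {
    abort(sprintf("%s: GMT line(s) %s have fewer than 3 fields", path,
                  paste(head(which(short), 5), collapse = ", ")))
  }
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[`, character(1), 1)
  dup <- vapply(sets, anyDuplicated, integer(1)) > 0
  if (any(dup)) {
    warn(sprintf("deduplicated gene(s) within term(s): %s",
                 paste(head(names(sets)[dup], 5), collapse = ", ")))
    sets <- lapply(sets, unique)
  }
  sets
}

#' Read a gene catalog TSV
#'
#' Two columns: `gene_id`, `biotype` (`protein_coding` or `lncRNA`).
#'
#' @param path file path.
#' @return A tibble.
#' @export
read_catalog_tsv <- function(path) {
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("gene_id", "biotype") %in% names(df))) {
    abort(sprintf("%s: catalog needs `gene_id` and `biotype` columns", path))
  }
  if (anyDuplicated(df$gene_id)) abort(sprintf("%s: duplicate gene ids", path))
  as_tibble(df)
}
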