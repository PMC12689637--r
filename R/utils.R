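# Internal helpers shared across modules.

# Canonical unordered edge orientation: node1 < node2 in byte (C-locale)
# order.  All edge tables in the package are kept in this orientation so
# joins across networks line up without extra bookkeeping.
canonicalize_edges <- function(edges) {
  stopifnot(all(c("node1", "node2") %in% names(edges)))
  a <- as.character(edges$node1)
  b <- as.character(edges$node2)
  if (any(a == b)) abort("self-loops are not allowed in an edge table")
  swap <- str_gt(a, b)
  if (any(swap)) {
    tmp <- a[swap]
    a[swap] <- b[swap]
    b[swap] <- tmp
  }
  edges$node1 <- a
  edges$node2 <- b
  edges
}

# element-wise a > b under locale-independent (radix/byte) collation
str_gt <- function(a, b) {
  n <- length(a)
  o <- order(c(a, b), method = "radix")
  rk <- integer(2L * n)
  rk[o] <- seq_len(2L * n)
  rk[seq_len(n)] > rk[n + seq_len(n)]
}

edge_key <- function(node1, node2) paste(node1, node2, sep = "\r")

assert_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single number in [0, 1], got %s", name, deparse(x)))
  }
  invisible(x)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d, got %s", name, min, deparse(x)))
  }
  invisible(as.integer(x))
}

# stable configuration hash used for provenance headers
config_hash <- function(x) rlang::hash(x)
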