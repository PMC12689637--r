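#' Integrate wTO networks into a sign-consistent consensus network
#'
#' Keeps only links present in *every* input network with the same sign,
#' and combines their weights with the strength-weighted average
#' \deqn{\Omega_{ij} = \sum_k \alpha_{ij}^k \omega_{ij}^k,\qquad
#'       \alpha_{ij}^k = |\omega_{ij}^k| \big/ \sum_k |\omega_{ij}^k|,}
#' so stronger inputs contribute more than a simple mean would allow.
#' Links whose signs differ between inputs are excluded, as are exact
#' zero weights (their mixing factor is undefined).
#'
#' @param nets a list of at least two `wto_network` objects (typically
#'   already [hard_threshold()]ed), covering the same region/condition.
#' @return A `consensus_network`: tibble with `node1`, `node2`, `omega` and
#'   one `w_<k>` column per input network; `attr(, "n_inputs")` records the
#'   number of inputs and `attr(, "nodes")` the incident node set.
#' @export
consensus_integrate <- function(nets) {
  if (!is.list(nets) || length(nets) < 2) {
    abort("`nets` must be a list of at least 2 networks")
  }
  if (!all(vapply(nets, inherits, logical(1), "wto_network"))) {
    abort("every element of `nets` must be a `wto_network`")
  }
  k <- length(nets)
  tabs <- lapply(seq_len(k), function(i) {
    t <- as_tibble(nets[[i]])[, c("node1", "node2", "wto")]
    names(t)[3] <- paste0("w_", i)
    t
  })
  merged <- purrr::reduce(tabs, dplyr::inner_join, by = c("node1", "node2"))
  w <- as.matrix(merged[, paste0("w_", seq_len(k)), drop = FALSE])
  nonzero <- rowSums(w == 0) == 0
  same_sign <- apply(sign(w), 1, function(s) all(s == s[1]))
  keep <- nonzero & same_sign
  merged <- merged[keep, , drop = FALSE]
  w <- w[keep, , drop = FALSE]
  merged$omega <- rowSums(w * abs(w)) / rowSums(abs(w))
  out <- merged[, c("node1", "node2", "omega", paste0("w_", seq_len(k)))]
  out <- dplyr::arrange(out, .data$node1, .data$node2)
  class(out) <- c("consensus_network", setdiff(class(out), "consensus_network"))
  attr(out, "n_inputs") <- k
  attr(out, "nodes") <- sort(unique(c(out$node1, out$node2)))
  out
}

#' @export
print.consensus_network <- function(x, ...) {
  cat(sprintf(
    "<consensus_network> %d links over %d nodes (%d input networks)\n",
    nrow(x), length(attr(x, "nodes")), attr(x, "n_inputs")
  ))
  NextMethod()
}

#' @export
#' @method glance consensus_network
glance.consensus_network <- function(x, ...) {
  tibble(
    n_links = nrow(x),
    n_nodes = length(attr(x, "nodes")),
    n_inputs = attr(x, "n_inputs"),
    n_negative = sum(x$omega < 0),
    mean_abs_weight = if (nrow(x)) mean(abs(x$omega)) else NA_real_
  )
}
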