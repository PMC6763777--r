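# Independent brute-force oracles, deliberately written as direct
# transcriptions of the definitions (no shared code with the package).

# hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws
enumerate_hypergeom_tail <- function(k, K, N, n) {
  universe <- seq_len(N)
  success <- seq_len(K)
  draws <- utils::combn(universe, n)
  hits <- apply(draws, 2L, function(d) sum(d %in% success) >= k)
  mean(hits)
}

# ssGSEA as the literal position-by-position running sum
stepwise_ssgsea <- function(values, gene_set, tau) {
  ids <- names(values)
  v <- unname(values)
  v[is.na(v)] <- -Inf
  ord <- order(-v, ids, method = "radix")
  ordered_ids <- ids[ord]
  n <- length(ids)
  rank_val <- n:1 # rank value of the feature at each list position
  in_set <- ordered_ids %in% gene_set
  w <- rank_val^tau
  es <- 0
  p_in <- 0
  p_out <- 0
  w_total <- sum(w[in_set])
  n_out <- sum(!in_set)
  for (i in seq_len(n)) {
    if (in_set[i]) p_in <- p_in + w[i] / w_total else p_out <- p_out + 1 / n_out
    es <- es + (p_in - p_out)
  }
  es
}

# Pearson r over complete pairs, from the definition
plain_pearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# closed-form steady state of the restart walk: p = alpha (I - (1-alpha)A)^-1 p0
rwr_direct_solve <- function(network, seeds, alpha = 0.7,
                             p0_mode = c("unit", "normalized")) {
  p0_mode <- match.arg(p0_mode)
  nodes <- network_nodes(network)
  A <- as.matrix(column_normalize(network))
  p0 <- as.numeric(nodes %in% seeds)
  if (p0_mode == "normalized") p0 <- p0 / sum(p0)
  p <- solve(diag(length(nodes)) - (1 - alpha) * A, alpha * p0)
  stats::setNames(p, nodes)
}

# trapezoidal area under a step ROC curve (fpr/tpr nondecreasing)
trapezoid_area <- function(fpr, tpr) {
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# an Erdos-Renyi style random drug_network over `n` labelled nodes
random_network <- function(n, p_edge = 0.1) {
  ids <- sprintf("n%03d", seq_len(n))
  pairs <- utils::combn(ids, 2L)
  keep <- stats::runif(ncol(pairs)) < p_edge
  drug_network(
    data.frame(from = pairs[1L, keep], to = pairs[2L, keep]),
    nodes = ids
  )
}

write_tsv_lines <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}
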