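#' Degree-preserving network randomization
#'
#' Randomizes the edge set by repeated double-edge swaps — pick two edges
#' (a,b) and (c,d) and rewire them to (a,d), (c,b) unless a self-loop or
#' multi-edge would result — so that every node's degree is preserved
#' exactly. This is the permutation null for prioritization scores. The
#' swap loop is delegated to [igraph::rewire()] with
#' [igraph::keeping_degseq()], which implements exactly this Markov chain;
#' failed swap attempts are skipped. An alternative, weaker null relabels
#' the nodes (preserving the degree multiset but not per-node degrees).
#'
#' @param network a [drug_network()].
#' @param n_swaps number of swap attempts; default `10 * |E|`.
#' @param null_model `"rewire"` (degree-preserving double-edge swaps,
#'   default) or `"relabel"` (node label permutation).
#' @param seed optional RNG seed for reproducibility; `NULL` uses (and
#'   advances) the caller's RNG stream.
#' @return a [drug_network()] with the same node set.
#' @export
randomize_network <- function(network, n_swaps = NULL,
                              null_model = c("rewire", "relabel"),
                              seed = NULL) {
  stopifnot(inherits(network, "drug_network"))
  null_model <- match.arg(null_model)
  m <- nrow(network_edges(network))
  if (m == 0L) return(network)
  with_optional_seed(seed, {
    if (null_model == "relabel") {
      nodes <- network_nodes(network)
      relab <- stats::setNames(sample(nodes), nodes)
      e <- network_edges(network)
      drug_network(
        data.frame(from = relab[e$from], to = relab[e$to], weight = e$weight),
        nodes = nodes
      )
    } else {
      n_swaps <- n_swaps %||% (10L * m)
      g <- as_igraph(network)
      g2 <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                     niter = n_swaps))
      from_igraph(g2)
    }
  })
}

#' Permutation significance of prioritization scores
#'
#' Runs the random walk on `n_perm` degree-preserving randomizations of the
#' network with the same seed drugs, and for every drug computes the
#' empirical p-value as the fraction of permutations whose score exceeds
#' the real one (strict `>`, the literal count estimator; the `"add_one"`
#' estimator reports `(count + 1) / (n_perm + 1)` so p is never exactly 0).
#' P-values are Benjamini-Hochberg adjusted over all drugs.
#'
#' A seed drug left isolated (or far from the others) in a permuted network
#' simply scores what it scores — every permutation counts.
#'
#' @inheritParams rwr
#' @inheritParams randomize_network
#' @param n_perm number of random networks (default 1000).
#' @param estimator `"literal"` (default) or `"add_one"`.
#' @return tibble: `drug_id`, `prior_score`, `p_value`, `fdr`, `rank`,
#'   `is_seed` (ranked by decreasing score, ties by drug ID).
#' @export
permutation_significance <- function(network, seeds, alpha = 0.7, tol = 1e-10,
                                     max_iter = 1e6,
                                     p0_mode = c("unit", "normalized"),
                                     n_perm = 1000, n_swaps = NULL,
                                     estimator = c("literal", "add_one"),
                                     null_model = c("rewire", "relabel"),
                                     seed = NULL) {
  p0_mode <- match.arg(p0_mode)
  estimator <- match.arg(estimator)
  null_model <- match.arg(null_model)
  fit <- rwr(network, seeds, alpha = alpha, tol = tol, max_iter = max_iter,
             p0_mode = p0_mode)
  nodes <- network_nodes(network)
  real <- stats::setNames(fit$scores$prior_score, fit$scores$drug_id)[nodes]
  exceed <- integer(length(nodes))
  with_optional_seed(seed, {
    for (b in seq_len(n_perm)) {
      pnet <- randomize_network(network, n_swaps = n_swaps,
                                null_model = null_model)
      pfit <- rwr(pnet, seeds, alpha = alpha, tol = tol, max_iter = max_iter,
                  p0_mode = p0_mode)
      ps <- stats::setNames(pfit$scores$prior_score, pfit$scores$drug_id)[nodes]
      exceed <- exceed + unname(ps > real)
    }
  })
  p <- switch(estimator,
    literal = exceed / n_perm,
    add_one = (exceed + 1) / (n_perm + 1)
  )
  out <- tibble(
    drug_id = nodes,
    prior_score = as.numeric(real),
    p_value = p,
    fdr = bh_fdr(p),
    is_seed = nodes %in% fit$seeds
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$prior_score), .data$drug_id)
  out$rank <- seq_len(nrow(out))
  dplyr::relocate(out, "drug_id", "prior_score", "p_value", "fdr", "rank",
                  "is_seed")
}
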