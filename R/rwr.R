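#' Random walk with restart over a drug similarity network
#'
#' Iterates \deqn{p^{t} = (1 - \alpha) A p^{t-1} + \alpha p^{0}, \qquad
#' p^{1} = p^{0},} where `A` is the column-normalized adjacency of the
#' network ([column_normalize()]) and \eqn{\alpha} the restart probability,
#' until the L1 difference \eqn{\|p^{t} - p^{t-1}\|_1} falls below `tol`.
#' The steady-state visiting probabilities are the drug prioritization
#' scores; drugs are ranked by decreasing score with ties broken by drug ID.
#'
#' The initial vector assigns mass to the seed (restart) drugs only:
#' `p0_mode = "unit"` gives every seed 1 (the binary prior-knowledge
#' encoding), `"normalized"` gives each seed `1/|seeds|` so the vector sums
#' to 1. Ranks — and any rank-based downstream quantity — are identical
#' under the two modes because the steady state is linear in `p0`.
#'
#' @param network a [drug_network()].
#' @param seeds character vector of seed drug IDs (the restart set); must
#'   all be nodes of `network`.
#' @param alpha restart probability in (0, 1), default 0.7.
#' @param tol L1 convergence threshold, default 1e-10.
#' @param max_iter iteration cap, default 1e6 (exceeding it is an error).
#' @param p0_mode `"unit"` (default) or `"normalized"` seed mass.
#' @return an object of class `rwr_fit` with elements `scores` (tibble:
#'   `drug_id`, `prior_score`, `rank`, `is_seed`), `alpha`, `p0_mode`,
#'   `iterations`, `residual`, `seeds`. [tidy()][generics::tidy] returns the
#'   score tibble, [glance()][generics::glance] a one-row summary.
#' @examples
#' net <- drug_network(data.frame(from = "a", to = "b"))
#' rwr(net, "a")$scores
#' @export
rwr <- function(network, seeds, alpha = 0.7, tol = 1e-10, max_iter = 1e6,
                p0_mode = c("unit", "normalized")) {
  stopifnot(inherits(network, "drug_network"))
  p0_mode <- match.arg(p0_mode)
  assert_scalar_number(alpha, "alpha", 0, 1)
  if (alpha <= 0 || alpha >= 1) {
    stop_dsn("`alpha` must lie strictly in (0, 1)", "dsn_bad_argument")
  }
  assert_scalar_number(tol, "tol", lower = .Machine$double.xmin)
  seeds <- unique(as.character(seeds))
  nodes <- network_nodes(network)
  missing_seeds <- setdiff(seeds, nodes)
  if (length(seeds) == 0L || length(missing_seeds) == length(seeds)) {
    stop_dsn("the restart set contains no network node", "dsn_empty_seed_set")
  }
  if (length(missing_seeds) > 0L) {
    stop_dsn(
      sprintf("seed drug(s) not in the network: %s",
              paste(utils::head(missing_seeds, 5L), collapse = ", ")),
      "dsn_unmapped_seeds"
    )
  }
  A <- column_normalize(network)
  p0 <- numeric(length(nodes))
  names(p0) <- nodes
  p0[seeds] <- if (p0_mode == "unit") 1 else 1 / length(seeds)
  st <- rwr_steady_state(A, p0, alpha, tol, max_iter)
  scores <- tibble(
    drug_id = nodes,
    prior_score = as.numeric(st$p),
    is_seed = nodes %in% seeds
  )
  scores <- dplyr::arrange(scores, dplyr::desc(.data$prior_score), .data$drug_id)
  scores$rank <- seq_len(nrow(scores))
  structure(
    list(scores = scores, alpha = alpha, tol = tol, p0_mode = p0_mode,
         iterations = st$iterations, residual = st$residual, seeds = seeds,
         n_nodes = length(nodes)),
    class = "rwr_fit"
  )
}

# power iteration on a prepared transition matrix; p1 = p0
rwr_steady_state <- function(A, p0, alpha, tol, max_iter) {
  p <- p0
  for (it in seq_len(max_iter)) {
    p_new <- as.numeric((1 - alpha) * (A %*% p)) + alpha * p0
    res <- sum(abs(p_new - p))
    p <- p_new
    if (res < tol) {
      return(list(p = p, iterations = it, residual = res))
    }
  }
  stop_dsn(
    sprintf("random walk did not converge in %d iterations (last L1 residual %.3e)",
            max_iter, res),
    "dsn_no_convergence"
  )
}

#' @exportS3Method
print.rwr_fit <- function(x, ...) {
  cat(sprintf(
    "<rwr_fit> %d nodes, %d seeds, alpha = %g, p0 = %s, converged in %d iterations (L1 residual %.2e)\n",
    x$n_nodes, length(x$seeds), x$alpha, x$p0_mode, x$iterations, x$residual
  ))
  print(utils::head(x$scores, 10L))
  invisible(x)
}

#' @rdname rwr
#' @param x,object an `rwr_fit`.
#' @param ... unused.
#' @export
tidy.rwr_fit <- function(x, ...) x$scores

#' @rdname rwr
#' @export
glance.rwr_fit <- function(x, ...) {
  tibble(
    n_nodes = x$n_nodes, n_seeds = length(x$seeds), alpha = x$alpha,
    p0_mode = x$p0_mode, iterations = x$iterations, residual = x$residual,
    total_score = sum(x$scores$prior_score)
  )
}

#' @rdname rwr
#' @param n_top number of top-ranked drugs to display.
#' @export
autoplot.rwr_fit <- function(object, n_top = 20, ...) {
  d <- utils::head(object$scores, n_top)
  ggplot2::ggplot(
    d,
    ggplot2::aes(
      x = .data$prior_score,
      y = stats::reorder(.data$drug_id, .data$prior_score),
      fill = .data$is_seed
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "prioritization score (steady-state visiting probability)",
      y = NULL, fill = "seed drug",
      title = sprintf("Top %d prioritized drugs", nrow(d))
    ) +
    ggplot2::theme_minimal()
}

#' Candidate (non-seed) drugs from a prioritization
#'
#' Convenience filter returning the ranked non-seed drugs, optionally cut at
#' an FDR threshold when the table carries permutation significance columns.
#'
#' @param scores an `rwr_fit` or a score tibble (with `is_seed`).
#' @param fdr_max optional FDR cutoff (requires an `fdr` column).
#' @return tibble of candidate drugs, re-ranked 1..n among non-seeds.
#' @export
candidate_drugs <- function(scores, fdr_max = NULL) {
  if (inherits(scores, "rwr_fit")) scores <- scores$scores
  out <- dplyr::filter(scores, !.data$is_seed)
  if (!is.null(fdr_max)) {
    if (!"fdr" %in% names(out)) {
      stop_dsn("no `fdr` column; run permutation_significance() first",
               "dsn_bad_argument")
    }
    out <- dplyr::filter(out, !is.na(.data$fdr) & .data$fdr < fdr_max)
  }
  out <- dplyr::arrange(out, dplyr::desc(.data$prior_score), .data$drug_id)
  out$rank <- seq_len(nrow(out))
  out
}
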