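#' Single-sample gene set enrichment score
#'
#' Rank-weighted running-sum enrichment score for one gene set in one
#' sample. Features are ranked by decreasing expression (ties broken by
#' feature ID after a stable sort on value; missing values rank last), the
#' top feature receiving rank value \eqn{r = N} down to 1. The score is the
#' sum over list positions of the difference between the weighted in-set
#' ECDF and the unweighted out-of-set ECDF:
#' \deqn{ES = \sum_{i=1}^{N} \left[ P_{in}(i) - P_{out}(i) \right],\quad
#'   P_{in}(i) = \frac{\sum_{g \in S,\, pos(g) \le i} r_g^{\tau}}
#'                    {\sum_{g \in S} r_g^{\tau}},\quad
#'   P_{out}(i) = \frac{|\{g \notin S : pos(g) \le i\}|}{N - |S|}.}
#' No cross-sample normalization is applied: downstream Pearson
#' correlations are invariant to per-pathway affine rescaling, so raw
#' running-sum scores carry the same information.
#'
#' @param values named numeric vector: one sample's expression over all
#'   measured features.
#' @param gene_set character vector of member feature IDs.
#' @param tau rank weighting exponent \eqn{\tau \ge 0} (default 0.25).
#' @return the enrichment score (a single number).
#' @examples
#' ssgsea_score(c(g1 = 3, g2 = 2, g3 = 1), "g1", tau = 1) # 1.5
#' @export
ssgsea_score <- function(values, gene_set, tau = 0.25) {
  ids <- names(values)
  if (is.null(ids) || anyDuplicated(ids)) {
    stop_dsn("`values` must be named with unique feature IDs", "dsn_bad_argument")
  }
  assert_scalar_number(tau, "tau", lower = 0)
  r <- rank_values(values)
  es_from_ranks(r, match(intersect(gene_set, ids), ids), length(values), tau)
}

# rank values r_g = N..1 by decreasing expression; ties by feature ID
# (lexicographic); missing values sort below everything
rank_values <- function(values) {
  v <- unname(values)
  v[is.na(v)] <- -Inf
  ord <- order(-v, names(values), method = "radix")
  n <- length(v)
  r <- integer(n)
  r[ord] <- n:1
  r
}

# closed form of the running-sum ES: with rank values r_j of the k in-set
# features, sum_i P_in(i) = sum_j r_j^(tau+1) / sum_j r_j^tau and
# sum_i P_out(i) = (N(N+1)/2 - sum_j r_j) / (N - k)
es_from_ranks <- function(r_all, idx, n, tau) {
  k <- length(idx)
  if (k == 0L) {
    stop_dsn("gene set has no measured member", "dsn_empty_set")
  }
  if (k == n) {
    stop_dsn("gene set covers every measured feature; P_out is undefined",
             "dsn_degenerate_set")
  }
  r <- as.numeric(r_all[idx])
  w <- r^tau
  sum(w * r) / sum(w) - (n * (n + 1) / 2 - sum(r)) / (n - k)
}

#' Pathway activity matrix by ssGSEA
#'
#' Applies [ssgsea_score()] to every pathway and every sample, producing a
#' pathways-by-samples activity matrix. Pathways with no member measured in
#' the expression matrix are dropped (with a warning reporting how many);
#' an error is raised if none remain.
#'
#' @param expr numeric matrix, features x samples (e.g. from
#'   [read_expression_matrix()]).
#' @param gene_sets a [gene_set_collection()].
#' @param tau rank weighting exponent (default 0.25).
#' @return numeric matrix, retained pathways x samples.
#' @export
pathway_activity <- function(expr, gene_sets, tau = 0.25) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  if (!inherits(gene_sets, "gene_set_collection")) {
    gene_sets <- gene_set_collection(gene_sets)
  }
  assert_scalar_number(tau, "tau", lower = 0)
  ids <- rownames(expr)
  n <- nrow(expr)
  idx_list <- lapply(gene_sets, function(s) which(ids %in% s))
  measured <- lengths(idx_list) > 0L
  if (!any(measured)) {
    stop_dsn("no pathway has any member measured in the expression matrix",
             "dsn_empty_result")
  }
  if (any(!measured)) {
    warn_dsn(
      sprintf("%d pathway(s) with no measured member dropped", sum(!measured)),
      "dsn_dropped_pathways"
    )
    idx_list <- idx_list[measured]
  }
  out <- matrix(NA_real_, length(idx_list), ncol(expr),
                dimnames = list(names(idx_list), colnames(expr)))
  for (s in seq_len(ncol(expr))) {
    r <- rank_values(stats::setNames(expr[, s], ids))
    for (p in seq_along(idx_list)) {
      out[p, s] <- es_from_ranks(r, idx_list[[p]], n, tau)
    }
  }
  out
}
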