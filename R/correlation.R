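#' Pathway-drug and drug-drug correlation matrices
#'
#' The network construction is a "correlation of correlations": first each
#' pathway's activity profile is correlated with each drug's activity
#' profile across the shared cell lines; then two drugs are compared by the
#' Pearson correlation of their pathway-correlation profiles. Results are
#' returned as a lightweight `cor_matrix` object holding the coefficient
#' matrix `r`, the matrix `n` of complete observation pairs, two-sided
#' p-values `p` from the t transform \eqn{t = r\sqrt{(n-2)/(1-r^2)}}, and —
#' at the drug-drug stage — Benjamini-Hochberg adjusted values `fdr`
#' computed jointly over all unordered drug pairs.
#'
#' @param activity numeric matrix, pathways x samples (from
#'   [pathway_activity()]).
#' @param acts numeric matrix, drugs x samples (activity
#'   \eqn{-\log_{10}(\mathrm{GI50})}).
#' @param min_pairs minimum complete pairs for a correlation to be reported
#'   (default 3; entries below it are `NA`).
#' @return a `cor_matrix`: list with `r`, `n`, `p` (and `fdr` for
#'   [drug_drug_similarity()]).
#' @name correlations
NULL

new_cor_matrix <- function(r, n, p, fdr = NULL) {
  structure(list(r = r, n = n, p = p, fdr = fdr), class = "cor_matrix")
}

#' @exportS3Method
print.cor_matrix <- function(x, ...) {
  cat(sprintf("<cor_matrix> %d x %d%s\n", nrow(x$r), ncol(x$r),
              if (is.null(x$fdr)) "" else ", BH FDR attached"))
  invisible(x)
}

# two-sided p-value of a Pearson r with n complete pairs (t transform)
cor_pvalue <- function(r, n) {
  df <- n - 2
  p <- matrix(NA_real_, nrow(r), ncol(r), dimnames = dimnames(r))
  ok <- !is.na(r) & !is.na(df) & df >= 1
  rr <- pmin(pmax(r[ok], -1), 1)
  tt <- abs(rr) * sqrt(df[ok] / pmax(1 - rr^2, .Machine$double.eps))
  p[ok] <- 2 * stats::pt(tt, df[ok], lower.tail = FALSE)
  p[ok][abs(rr) >= 1] <- 0
  pmin(p, 1)
}

# correlation of the rows of X with the rows of Y over pairwise-complete
# shared columns, plus the complete-pair count matrix
pairwise_cor <- function(X, Y, min_pairs) {
  r <- suppressWarnings(stats::cor(t(X), t(Y), use = "pairwise.complete.obs"))
  n <- (!is.na(X)) %*% t(!is.na(Y))
  r[n < min_pairs] <- NA_real_
  list(r = r, n = n)
}

#' @rdname correlations
#' @export
pathway_drug_correlation <- function(activity, acts, min_pairs = 3) {
  stopifnot(is.matrix(activity), is.matrix(acts))
  shared <- intersect(colnames(activity), colnames(acts))
  if (length(shared) == 0L) {
    stop_dsn("pathway activity and drug activity share no samples",
             "dsn_no_shared_samples")
  }
  if (length(shared) < min_pairs) {
    stop_dsn(
      sprintf("only %d shared sample(s); need >= %d", length(shared), min_pairs),
      "dsn_no_shared_samples"
    )
  }
  pc <- pairwise_cor(activity[, shared, drop = FALSE],
                     acts[, shared, drop = FALSE], min_pairs)
  new_cor_matrix(pc$r, pc$n, cor_pvalue(pc$r, pc$n))
}

#' @rdname correlations
#' @param pd a pathways-x-drugs `cor_matrix` from
#'   [pathway_drug_correlation()].
#' @details For [drug_drug_similarity()] the functional similarity of two
#'   drugs is the Pearson correlation between their columns of `pd$r`
#'   (pathway-correlation profiles), over pathways where both are
#'   non-missing. The diagonal is 1 by construction and is excluded from the
#'   FDR pool.
#' @export
drug_drug_similarity <- function(pd, min_pairs = 3) {
  stopifnot(inherits(pd, "cor_matrix"))
  profiles <- pd$r # pathways x drugs
  dc <- pairwise_cor(t(profiles), t(profiles), min_pairs)
  r <- dc$r
  n <- dc$n
  diag(r) <- 1
  p <- cor_pvalue(r, n)
  diag(p) <- NA_real_
  n_missing_pairs <- (sum(is.na(r[upper.tri(r)])))
  if (n_missing_pairs > 0L) {
    warn_dsn(
      sprintf("%d drug pair(s) with < %d usable pathway correlations set missing",
              n_missing_pairs, min_pairs),
      "dsn_missing_pairs"
    )
  }
  fdr <- matrix(NA_real_, nrow(r), ncol(r), dimnames = dimnames(r))
  ut <- upper.tri(r)
  fdr[ut] <- bh_fdr(p[ut])
  fdr[lower.tri(fdr)] <- t(fdr)[lower.tri(fdr)]
  new_cor_matrix(r, n, p, fdr)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Thin validating wrapper over [stats::p.adjust()] with `method = "BH"`:
#' \eqn{q_{(i)} = \min_{j \ge i} \, m \, p_{(j)} / j}, clipped to 1 and
#' mapped back to input order. `NA` entries are passed through (and do not
#' count toward `m`).
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return vector of adjusted values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p)) stop_dsn("`p` must be numeric", "dsn_bad_argument")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop_dsn("p-values must lie in [0, 1]", "dsn_bad_argument")
  }
  stats::p.adjust(p, method = "BH")
}

#' Select significant similarity edges
#'
#' Applies the edge rule to a drugs-x-drugs `cor_matrix`. For each drug,
#' a partner qualifies when (\code{r >= r_min} AND \code{fdr <= fdr_max}) — the
#' significance rule — or when it ranks in the top `top_frac` of that
#' drug's partners by decreasing correlation (per-drug top
#' `ceiling(top_frac * (n - 1))` partners, ties at the cutoff all
#' included) — the rank rule. With `rule = "union"` (default) either
#' suffices; with `rule = "intersect"` both are required. Qualifying
#' (drug, partner) pairs are pooled over drugs and canonicalized into an
#' undirected network whose node set is all drugs (isolated drugs kept).
#'
#' @param dd a square `cor_matrix` from [drug_drug_similarity()].
#' @param r_min minimum correlation for the significance rule (default 0.7).
#' @param fdr_max maximum BH FDR for the significance rule (default 0.05).
#' @param top_frac per-drug top fraction for the rank rule (default 0.0005,
#'   i.e. 0.05 percent); set to 0 to disable.
#' @param rule `"union"` or `"intersect"` of the two rules.
#' @return a [drug_network()] with edge weights = correlation coefficients.
#' @export
select_edges <- function(dd, r_min = 0.7, fdr_max = 0.05, top_frac = 0.0005,
                         rule = c("union", "intersect")) {
  stopifnot(inherits(dd, "cor_matrix"))
  rule <- match.arg(rule)
  r <- dd$r
  if (nrow(r) != ncol(r)) stop_dsn("`dd` must be square", "dsn_bad_argument")
  drugs <- rownames(r)
  n <- length(drugs)
  k_top <- if (top_frac > 0 && n > 1L) ceiling(top_frac * (n - 1)) else 0L
  from <- character(0); to <- character(0); w <- numeric(0)
  for (d in seq_len(n)) {
    rd <- r[d, ]
    rd[d] <- NA_real_
    usable <- which(!is.na(rd))
    if (length(usable) == 0L) next
    sig <- usable[rd[usable] >= r_min &
                    !is.na(dd$fdr[d, usable]) & dd$fdr[d, usable] <= fdr_max]
    top <- integer(0)
    if (k_top > 0L) {
      rv <- sort(rd[usable], decreasing = TRUE)
      cutoff <- rv[min(k_top, length(rv))]
      top <- usable[rd[usable] >= cutoff]
    }
    sel <- switch(rule,
      union = union(sig, top),
      intersect = intersect(sig, top)
    )
    if (length(sel) > 0L) {
      from <- c(from, rep(drugs[d], length(sel)))
      to <- c(to, drugs[sel])
      w <- c(w, rd[sel])
    }
  }
  net <- drug_network(data.frame(from = from, to = to, weight = w),
                      nodes = drugs)
  if (nrow(network_edges(net)) == 0L) {
    warn_dsn("edge selection produced an empty network", "dsn_empty_network")
  }
  net
}
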