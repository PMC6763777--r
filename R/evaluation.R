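#' Leave-one-out cross-validation of seed recovery
#'
#' Hides each seed drug's label in turn, reruns the random walk with the
#' remaining seeds, and records the held-out drug's score and its rank among
#' the candidate pool for that round — the held-out drug itself plus every
#' network drug outside the full seed set (ranks by decreasing score, ties
#' by drug ID). A well-performing prioritization recovers held-out approved
#' drugs near the top.
#'
#' @inheritParams rwr
#' @return tibble: `held_out`, `score`, `rank`, `n_candidates`, with the
#'   per-round non-seed scores attached as attribute `rounds` (a list of
#'   named vectors) for ROC pooling.
#' @export
loocv_scores <- function(network, seeds, alpha = 0.7, tol = 1e-10,
                         max_iter = 1e6, p0_mode = c("unit", "normalized")) {
  p0_mode <- match.arg(p0_mode)
  seeds <- unique(as.character(seeds))
  if (length(seeds) < 2L) {
    stop_dsn("LOOCV needs at least 2 seed drugs", "dsn_bad_argument")
  }
  nodes <- network_nodes(network)
  if (!all(seeds %in% nodes)) {
    stop_dsn("all seeds must be network nodes", "dsn_unmapped_seeds")
  }
  non_seeds <- setdiff(nodes, seeds)
  rounds <- vector("list", length(seeds))
  names(rounds) <- seeds
  res <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    d <- seeds[i]
    fit <- rwr(network, setdiff(seeds, d), alpha = alpha, tol = tol,
               max_iter = max_iter, p0_mode = p0_mode)
    sc <- stats::setNames(fit$scores$prior_score, fit$scores$drug_id)
    pool <- c(d, non_seeds)
    ord <- order(-sc[pool], pool, method = "radix")
    rank_d <- which(pool[ord] == d)
    res[[i]] <- tibble(held_out = d, score = unname(sc[d]), rank = rank_d,
                       n_candidates = length(pool))
    rounds[[i]] <- sc[non_seeds]
  }
  out <- dplyr::bind_rows(res)
  attr(out, "rounds") <- rounds
  out
}

#' ROC curve and AUROC from positive and negative scores
#'
#' Builds the step ROC curve over descending score thresholds and computes
#' the area under it by Mann-Whitney pair counting,
#' \deqn{AUROC = \frac{\#\{(p, n): p > n\} + 0.5\,\#\{p = n\}}{|P|\,|N|},}
#' which equals the trapezoidal area under the step curve.
#'
#' @param pos_scores numeric vector of positive-class scores (e.g. held-out
#'   seed scores pooled over LOOCV rounds).
#' @param neg_scores numeric vector of negative-class scores.
#' @return an object of class `roc_result`: list with `curve` (tibble
#'   `threshold`, `fpr`, `tpr`), `auroc`, `n_pos`, `n_neg`.
#' @examples
#' roc_auroc(c(0.9, 0.4), c(0.5, 0.1))$auroc # 0.75
#' @export
roc_auroc <- function(pos_scores, neg_scores) {
  pos <- as.numeric(pos_scores)
  neg <- as.numeric(neg_scores)
  if (length(pos) == 0L || length(neg) == 0L || anyNA(pos) || anyNA(neg)) {
    stop_dsn("need >= 1 finite score in each class", "dsn_bad_argument")
  }
  gt <- vapply(pos, function(x) sum(x > neg), numeric(1))
  eq <- vapply(pos, function(x) sum(x == neg), numeric(1))
  auroc <- (sum(gt) + 0.5 * sum(eq)) / (length(pos) * length(neg))
  thr <- sort(unique(c(pos, neg)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg >= t), numeric(1))
  curve <- tibble(
    threshold = c(Inf, thr),
    fpr = c(0, fpr),
    tpr = c(0, tpr)
  )
  structure(
    list(curve = curve, auroc = auroc, n_pos = length(pos), n_neg = length(neg)),
    class = "roc_result"
  )
}

#' @exportS3Method
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUROC = %.4f (%d positives, %d negatives)\n",
              x$auroc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @rdname roc_auroc
#' @param x,object a `roc_result`.
#' @param ... unused.
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' @rdname roc_auroc
#' @export
glance.roc_result <- function(x, ...) {
  tibble(auroc = x$auroc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @rdname roc_auroc
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false-positive rate", y = "true-positive rate",
      title = sprintf("LOOCV ROC (AUROC = %.3f)", object$auroc)
    ) +
    ggplot2::theme_minimal()
}

#' LOOCV + ROC evaluation of a seed set
#'
#' Convenience wrapper: runs [loocv_scores()], pools the held-out seed
#' scores as positives and the non-seed scores as negatives —
#' `negatives = "pooled"` pools every round's non-seed scores,
#' `"per-round-mean"` averages each non-seed drug's score across rounds —
#' and computes the ROC/AUROC.
#'
#' @inheritParams rwr
#' @param negatives negative-class convention (see Details).
#' @return a list of class `loocv_eval`: `rounds` (the [loocv_scores()]
#'   tibble), `roc` (a [roc_auroc()] result) and `auroc`.
#' @export
loocv_evaluate <- function(network, seeds, alpha = 0.7, tol = 1e-10,
                           max_iter = 1e6, p0_mode = c("unit", "normalized"),
                           negatives = c("pooled", "per-round-mean")) {
  negatives <- match.arg(negatives)
  p0_mode <- match.arg(p0_mode)
  rounds <- loocv_scores(network, seeds, alpha = alpha, tol = tol,
                         max_iter = max_iter, p0_mode = p0_mode)
  per_round <- attr(rounds, "rounds")
  neg <- switch(negatives,
    pooled = unlist(per_round, use.names = FALSE),
    `per-round-mean` = Reduce(`+`, per_round) / length(per_round)
  )
  roc <- roc_auroc(rounds$score, neg)
  structure(list(rounds = rounds, roc = roc, auroc = roc$auroc),
            class = "loocv_eval")
}

#' @exportS3Method
print.loocv_eval <- function(x, ...) {
  cat(sprintf("<loocv_eval> %d rounds, AUROC = %.4f\n",
              nrow(x$rounds), x$auroc))
  invisible(x)
}
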