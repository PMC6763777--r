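#' Filter drugs to the high/diverse-activity subset
#'
#' Restricts a drug-activity matrix to drugs showing both high and diverse
#' activity across the cell-line panel: a drug is retained when its
#' inter-quartile range (IQR) lies in the top quartile of all drug IQRs AND
#' its maximum activity lies in the top quartile of all drug maxima. Both
#' statistics are computed over non-missing samples; drugs with fewer than
#' `min_obs` non-missing values are excluded before the quartile thresholds
#' are computed (with a warning reporting the count). "Top quartile" means
#' `value >= quantile(values, 0.75)` with the inclusive linear-interpolation
#' quantile (R type 7) by default; both the probability and the quantile
#' type are exposed because the retained count is sensitive to them.
#'
#' Note the filter is not idempotent: a second application re-computes the
#' thresholds on the already-filtered set and may shrink it further.
#'
#' @param acts numeric matrix, drugs x samples, of
#'   \eqn{-\log_{10}(\mathrm{GI50})} activities (duplicate drug IDs must
#'   already be mean-aggregated, as [read_drug_activity()] does).
#' @param min_obs minimum non-missing samples per drug (default 4).
#' @param prob quantile probability defining "top quartile" (default 0.75).
#' @param quantile_type quantile algorithm passed to [stats::quantile()]
#'   (default 7).
#' @return the retained sub-matrix, with attributes `iqr_threshold` and
#'   `max_threshold`.
#' @export
filter_drugs <- function(acts, min_obs = 4, prob = 0.75, quantile_type = 7) {
  stopifnot(is.matrix(acts), nrow(acts) >= 1L, !is.null(rownames(acts)))
  if (anyDuplicated(rownames(acts))) {
    stop_dsn("duplicate drug IDs; aggregate duplicates before filtering",
             "dsn_bad_argument")
  }
  n_obs <- rowSums(!is.na(acts))
  enough <- n_obs >= min_obs
  if (!any(enough)) {
    stop_dsn(
      sprintf("no drug has >= %d non-missing activity values", min_obs),
      "dsn_empty_result"
    )
  }
  if (any(!enough)) {
    warn_dsn(
      sprintf("%d drug(s) with < %d non-missing values excluded before quartiling",
              sum(!enough), min_obs),
      "dsn_low_coverage_drugs"
    )
  }
  x <- acts[enough, , drop = FALSE]
  iqr <- apply(x, 1L, stats::IQR, na.rm = TRUE, type = quantile_type)
  mx <- apply(x, 1L, max, na.rm = TRUE)
  thr_iqr <- stats::quantile(iqr, prob, type = quantile_type, names = FALSE)
  thr_max <- stats::quantile(mx, prob, type = quantile_type, names = FALSE)
  keep <- iqr >= thr_iqr & mx >= thr_max
  if (!any(keep)) {
    stop_dsn(
      sprintf(
        "no drug passes both filters (IQR >= %.4g and max >= %.4g)",
        thr_iqr, thr_max
      ),
      "dsn_empty_result"
    )
  }
  out <- x[keep, , drop = FALSE]
  attr(out, "iqr_threshold") <- thr_iqr
  attr(out, "max_threshold") <- thr_max
  out
}
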