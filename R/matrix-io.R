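#' Read a features-by-samples matrix from TSV
#'
#' Reads the tab-separated matrix dialect used throughout the package
#' (CellMiner-style exports): a header row of sample IDs, a first column of
#' feature IDs, and numeric or empty cells. Empty cells and the literal
#' strings `NA`/`na` are treated as missing values (never as zero). Rows
#' with duplicate feature IDs are collapsed by the element-wise mean over
#' non-missing values, preserving the order of first appearance.
#'
#' The same reader serves gene (mRNA) expression, microRNA expression,
#' pathway-activity matrices, and drug-activity matrices of
#' \eqn{-\log_{10}(\mathrm{GI50})} values (drugs as rows, cell lines as
#' columns; higher value = higher sensitivity).
#'
#' @param path TSV file path.
#' @return a numeric matrix with unique rownames (features) and colnames
#'   (samples).
#' @seealso [write_matrix_tsv()]
#' @export
read_expression_matrix <- function(path) {
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE, show_col_types = FALSE
  )
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop_dsn(
      sprintf("'%s' is empty or has no sample columns", path),
      "dsn_format_error"
    )
  }
  ids <- as.character(df[[1L]])
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples)) {
    stop_dsn("duplicate sample IDs in header", "dsn_format_error")
  }
  vals <- matrix(NA_real_, nrow(df), length(samples),
                 dimnames = list(NULL, samples))
  for (j in seq_along(samples)) {
    cell <- df[[j + 1L]]
    cell[cell == "" | cell == "NA" | cell == "na"] <- NA
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.na(cell) & is.na(num))
    if (length(bad) > 0L) {
      stop_dsn(
        sprintf(
          "non-numeric value '%s' at feature '%s', sample column '%s'",
          cell[bad[1L]], ids[bad[1L]], samples[j]
        ),
        "dsn_parse_error"
      )
    }
    vals[, j] <- num
  }
  rownames(vals) <- ids
  aggregate_duplicate_rows(vals)
}

#' @rdname read_expression_matrix
#' @export
read_drug_activity <- read_expression_matrix

# collapse duplicate rownames by element-wise mean over non-missing entries,
# keeping first-appearance order; idempotent on matrices with unique rownames
aggregate_duplicate_rows <- function(x) {
  ids <- rownames(x)
  if (!anyDuplicated(ids)) return(x)
  grp <- factor(ids, levels = unique(ids))
  sums <- rowsum(ifelse(is.na(x), 0, x), grp)
  counts <- rowsum((!is.na(x)) * 1, grp)
  out <- sums / counts
  out[counts == 0] <- NA_real_
  colnames(out) <- colnames(x)
  out
}

#' Write a features-by-samples matrix as TSV
#'
#' Inverse of [read_expression_matrix()]: first column of feature IDs under
#' the heading `id`, one column per sample, missing values written as `NA`.
#'
#' @param x numeric matrix with rownames and colnames.
#' @param path output path.
#' @param id_column heading for the feature-ID column.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path, id_column = "id") {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  df <- as.data.frame(x, check.names = FALSE)
  df <- cbind(stats::setNames(data.frame(rownames(x)), id_column), df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a seed (restart) drug list
#'
#' One drug ID per line; blank lines and `#` comments are skipped. IDs not
#' present in the network are dropped with a warning reporting the count;
#' an error is raised when no seed maps.
#'
#' @param path file path.
#' @param network a [drug_network()] the seeds must map into.
#' @param label optional cancer label attached as an attribute (defaults to
#'   the file name without extension).
#' @return character vector of mapped seed drug IDs with attribute `label`.
#' @export
read_seed_list <- function(path, network, label = NULL) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  ids <- unique(lines)
  if (length(ids) == 0L) {
    stop_dsn(sprintf("seed file '%s' contains no IDs", path), "dsn_format_error")
  }
  mapped <- intersect(ids, network_nodes(network))
  n_drop <- length(ids) - length(mapped)
  if (length(mapped) == 0L) {
    stop_dsn(
      sprintf("none of the %d seed drugs map into the network", length(ids)),
      "dsn_empty_seed_set"
    )
  }
  if (n_drop > 0L) {
    warn_dsn(
      sprintf("%d of %d seed drug(s) not found in the network; dropped",
              n_drop, length(ids)),
      "dsn_unmapped_seeds"
    )
  }
  label <- label %||% sub("\\.[^.]*$", "", basename(path))
  structure(mapped, label = label)
}
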