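#' Gene set collections
#'
#' A gene set collection is a named list of character vectors: one entry per
#' pathway, members are feature identifiers (gene symbols, probe IDs, or
#' microRNA IDs for microRNA pathways). The constructor validates uniqueness
#' of names, drops duplicate members within a set, and attaches optional
#' per-set descriptions.
#'
#' @param sets named list of character vectors of member feature IDs.
#' @param descriptions optional character vector of per-set descriptions,
#'   recycled to `length(sets)`.
#' @return an object of class `gene_set_collection` (a named list).
#' @examples
#' gs <- gene_set_collection(list(PWY1 = c("g1", "g2"), PWY2 = "g3"))
#' lengths(gs)
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || length(sets) == 0L) {
    stop_dsn("`sets` must be a non-empty named list", "dsn_format_error")
  }
  nm <- names(sets)
  if (is.null(nm) || anyNA(nm) || any(nm == "")) {
    stop_dsn("every gene set must be named", "dsn_format_error")
  }
  if (anyDuplicated(nm)) {
    dup <- unique(nm[duplicated(nm)])
    stop_dsn(
      sprintf("duplicate gene set name(s): %s", paste(dup, collapse = ", ")),
      "dsn_format_error"
    )
  }
  sets <- lapply(sets, function(x) unique(as.character(x)))
  if (any(lengths(sets) == 0L)) {
    stop_dsn("gene sets must be non-empty", "dsn_format_error")
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  descriptions <- rep_len(as.character(descriptions), length(sets))
  names(descriptions) <- nm
  structure(sets, descriptions = descriptions, class = "gene_set_collection")
}

#' @exportS3Method
print.gene_set_collection <- function(x, ...) {
  cat(sprintf(
    "<gene_set_collection> %d sets, member counts %d-%d\n",
    length(x), min(lengths(x)), max(lengths(x))
  ))
  invisible(x)
}

#' @export
`[.gene_set_collection` <- function(x, i) {
  desc <- attr(x, "descriptions")
  out <- unclass(x)[i]
  gene_set_collection(out, desc[names(out)])
}

#' Read and write gene sets in GMT format
#'
#' The Broad GMT dialect: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate members
#' within a line are dropped; duplicate set names are an error.
#'
#' @param path file path.
#' @return [read_gmt()] returns a [gene_set_collection]; [write_gmt()]
#'   returns `path` invisibly.
#' @examples
#' tf <- tempfile(fileext = ".gmt")
#' writeLines("PWY1\tdesc\tg1\tg2", tf)
#' read_gmt(tf)
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop_dsn(sprintf("GMT file '%s' is empty", path), "dsn_format_error")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short) > 0L) {
    stop_dsn(
      sprintf(
        "GMT line %d has %d field(s); need name, description and >= 1 member",
        short[1L], lengths(fields)[short[1L]]
      ),
      "dsn_format_error"
    )
  }
  nm <- vapply(fields, `[[`, character(1), 1L)
  desc <- vapply(fields, `[[`, character(1), 2L)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- nm
  gene_set_collection(sets, desc)
}

#' @rdname read_gmt
#' @param sets a [gene_set_collection] (or coercible named list).
#' @export
write_gmt <- function(sets, path) {
  if (!inherits(sets, "gene_set_collection")) sets <- gene_set_collection(sets)
  desc <- attr(sets, "descriptions")
  lines <- vapply(
    seq_along(sets),
    function(i) paste(c(names(sets)[i], desc[[i]], sets[[i]]), collapse = "\t"),
    character(1)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Upper-tail hypergeometric overlap p-value
#'
#' Probability of observing at least `k` members of a size-`K` pathway in a
#' random draw of `n` features from a universe of `N`, i.e. the exact
#' hypergeometric tail `P(X >= k)`. Used to decide whether a microRNA's
#' target genes are enriched in a pathway.
#'
#' @param k observed overlap.
#' @param K pathway size (within the universe).
#' @param n target-set size (within the universe).
#' @param N universe size.
#' @return p-value in `[0, 1]`.
#' @examples
#' hypergeom_overlap_p(2, 5, 2, 10) # choose(5,2)/choose(10,2)
#' @export
hypergeom_overlap_p <- function(k, K, n, N) {
  for (v in list(k = k, K = K, n = n, N = N)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v != round(v)) {
      stop_dsn("k, K, n, N must be single non-negative integers", "dsn_bad_argument")
    }
  }
  if (k > min(K, n) || K > N || n > N) {
    stop_dsn(
      sprintf("inconsistent counts: k=%d, K=%d, n=%d, N=%d", k, K, n, N),
      "dsn_bad_argument"
    )
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Build microRNA pathways from target overlap
#'
#' A microRNA is assigned to a pathway when its target genes overlap the
#' pathway's genes more than expected by chance (hypergeometric
#' `P(X >= k) < alpha`). The result is a collection of "microRNA pathways":
#' the same pathway names, but with member microRNA IDs; pathways with no
#' significant microRNA are dropped.
#'
#' @param targets named list: microRNA ID -> character vector of target genes.
#' @param gene_sets a [gene_set_collection] of mRNA pathways.
#' @param universe character vector of gene IDs defining the sampling
#'   universe. Default (`NULL`): the union of all pathway members and all
#'   target genes.
#' @param alpha significance threshold on the hypergeometric p-value
#'   (default 0.05, strict `<` comparison).
#' @return a [gene_set_collection] mapping pathway name -> microRNA IDs.
#' @export
build_mirna_pathways <- function(targets, gene_sets, universe = NULL,
                                 alpha = 0.05) {
  if (!is.list(targets) || is.null(names(targets))) {
    stop_dsn("`targets` must be a named list of target-gene vectors", "dsn_bad_argument")
  }
  if (!inherits(gene_sets, "gene_set_collection")) {
    gene_sets <- gene_set_collection(gene_sets)
  }
  if (is.null(universe)) {
    universe <- unique(c(unlist(gene_sets, use.names = FALSE),
                         unlist(targets, use.names = FALSE)))
  }
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) {
    stop_dsn("the gene universe is empty", "dsn_bad_argument")
  }
  N <- length(universe)
  targets_u <- lapply(targets, function(x) intersect(unique(x), universe))
  out <- list()
  for (pw in names(gene_sets)) {
    P <- intersect(gene_sets[[pw]], universe)
    if (length(P) == 0L) next
    members <- character(0)
    for (m in names(targets_u)) {
      Tu <- targets_u[[m]]
      if (length(Tu) == 0L) next
      k <- length(intersect(Tu, P))
      p <- hypergeom_overlap_p(k, length(P), length(Tu), N)
      if (p < alpha) members <- c(members, m)
    }
    if (length(members) > 0L) out[[pw]] <- members
  }
  if (length(out) == 0L) {
    warn_dsn("no pathway retained any microRNA member", "dsn_empty_result")
    return(structure(list(), descriptions = character(0),
                     class = "gene_set_collection"))
  }
  small <- sum(lengths(out) < 2L)
  if (small > 0L) {
    inform(sprintf("%d microRNA pathway(s) have a single member microRNA", small))
  }
  desc <- attr(gene_sets, "descriptions")[names(out)]
  gene_set_collection(out, desc)
}

#' Remove redundant (highly overlapping) pathways
#'
#' Two pathways are redundant when their two-way overlap exceeds
#' `overlap_thresh`: `|A & B|/|A| > t` AND `|A & B|/|B| > t`. Redundant
#' pairs are resolved greedily in order of decreasing overlap
#' (`|A & B| / max(|A|, |B|)`), removing the smaller set of the pair (ties
#' broken by dropping the lexicographically later name), until no pair
#' violates the threshold.
#'
#' @param gene_sets a [gene_set_collection].
#' @param overlap_thresh two-way overlap threshold (default 0.80, strict `>`).
#' @return a [gene_set_collection] with no remaining redundant pair.
#' @export
remove_redundant_pathways <- function(gene_sets, overlap_thresh = 0.80) {
  if (!inherits(gene_sets, "gene_set_collection")) {
    gene_sets <- gene_set_collection(gene_sets)
  }
  assert_scalar_number(overlap_thresh, "overlap_thresh", 0, 1)
  alive <- names(gene_sets)
  repeat {
    if (length(alive) < 2L) break
    sizes <- lengths(gene_sets[alive])
    pairs <- utils::combn(alive, 2L)
    ov <- apply(pairs, 2L, function(ab) {
      length(intersect(gene_sets[[ab[1L]]], gene_sets[[ab[2L]]]))
    })
    ra <- ov / sizes[pairs[1L, ]]
    rb <- ov / sizes[pairs[2L, ]]
    bad <- which(ra > overlap_thresh & rb > overlap_thresh)
    if (length(bad) == 0L) break
    # resolve the strongest overlap first
    score <- pmin(ra, rb)[bad]
    pick <- bad[order(-score, pairs[1L, bad], pairs[2L, bad])][1L]
    a <- pairs[1L, pick]; b <- pairs[2L, pick]
    drop <- if (sizes[[a]] < sizes[[b]]) a
            else if (sizes[[b]] < sizes[[a]]) b
            else max(a, b) # equal sizes: drop the lexicographically later name
    alive <- setdiff(alive, drop)
  }
  gene_sets[alive]
}
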