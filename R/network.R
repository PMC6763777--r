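#' Drug functional similarity network
#'
#' An undirected, unweighted (for propagation purposes) graph over drug IDs.
#' Edges are stored canonically — `from < to` lexicographically, each
#' undirected edge once — in a tibble with an optional `weight` annotation
#' column (retained for bookkeeping; propagation treats the network as an
#' unweighted adjacency). Self-loops are rejected; duplicate and reversed
#' duplicate edges are collapsed (first weight kept).
#'
#' @param edges data frame with at least two character columns (endpoints);
#'   a third numeric column, if present, is kept as `weight`. May have zero
#'   rows.
#' @param nodes optional character vector of node IDs; the final node set is
#'   the union of `nodes` and all edge endpoints, so isolated nodes can be
#'   declared explicitly.
#' @return an object of class `drug_network`: a list with elements `nodes`
#'   (sorted character vector) and `edges` (tibble `from`, `to`, `weight`).
#' @examples
#' net <- drug_network(data.frame(from = c("b", "a"), to = c("a", "c")))
#' network_degree(net)
#' @export
drug_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    et <- tibble(from = character(0), to = character(0), weight = numeric(0))
  } else {
    edges <- as.data.frame(edges)
    if (ncol(edges) < 2L) {
      stop_dsn("edge table needs at least two columns", "dsn_format_error")
    }
    a <- as.character(edges[[1L]])
    b <- as.character(edges[[2L]])
    w <- if (ncol(edges) >= 3L) as.numeric(edges[[3L]]) else rep(NA_real_, length(a))
    loop <- which(a == b)
    if (length(loop) > 0L) {
      stop_dsn(
        sprintf("self-loop(s) at row(s) %s (node '%s')",
                paste(utils::head(loop, 5L), collapse = ", "), a[loop[1L]]),
        "dsn_self_loop"
      )
    }
    et <- tibble(from = pmin(a, b), to = pmax(a, b), weight = w)
    et <- dplyr::distinct(et, .data$from, .data$to, .keep_all = TRUE)
    et <- dplyr::arrange(et, .data$from, .data$to)
  }
  nodes <- sort(unique(c(as.character(nodes %||% character(0)), et$from, et$to)))
  structure(list(nodes = nodes, edges = et), class = "drug_network")
}

#' @exportS3Method
print.drug_network <- function(x, ...) {
  cat(sprintf("<drug_network> %d nodes, %d undirected edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @rdname drug_network
#' @param network a `drug_network`.
#' @export
network_nodes <- function(network) {
  stopifnot(inherits(network, "drug_network"))
  network$nodes
}

#' @rdname drug_network
#' @export
network_edges <- function(network) {
  stopifnot(inherits(network, "drug_network"))
  network$edges
}

#' @rdname drug_network
#' @return `network_degree()` returns a tibble (`drug_id`, `degree`) over all
#'   nodes, isolated nodes included with degree 0.
#' @export
network_degree <- function(network) {
  stopifnot(inherits(network, "drug_network"))
  cnt <- table(factor(c(network$edges$from, network$edges$to),
                      levels = network$nodes))
  tibble(drug_id = network$nodes, degree = as.integer(cnt))
}

# 0/1 symmetric sparse adjacency with node dimnames
adjacency_matrix <- function(network) {
  stopifnot(inherits(network, "drug_network"))
  n <- length(network$nodes)
  i <- match(network$edges$from, network$nodes)
  j <- match(network$edges$to, network$nodes)
  Matrix::sparseMatrix(
    i = c(i, j), j = c(j, i), x = 1,
    dims = c(n, n), dimnames = list(network$nodes, network$nodes)
  )
}

#' Column-normalized transition matrix
#'
#' Divides each column of the 0/1 adjacency matrix by its node degree, the
#' transition structure used by the random walk. Columns of isolated nodes
#' are left all-zero (their restart mass leaks out of the walk, matching a
#' literal column normalization with no teleport correction).
#'
#' @param network a [drug_network()].
#' @return a sparse `dgCMatrix` with node IDs as dimnames.
#' @export
column_normalize <- function(network) {
  A <- adjacency_matrix(network)
  deg <- Matrix::colSums(A)
  scale <- ifelse(deg > 0, 1 / deg, 0)
  out <- A %*% Matrix::Diagonal(x = scale, n = length(deg))
  dimnames(out) <- dimnames(A)
  out
}

as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    network$edges[, c("from", "to")],
    directed = FALSE,
    vertices = network$nodes
  )
}

from_igraph <- function(g) {
  el <- igraph::as_data_frame(g, what = "edges")
  drug_network(el, nodes = igraph::V(g)$name)
}

#' Merge drug similarity networks
#'
#' Union of node sets and union of edge sets (canonical, deduplicated); the
#' first weight seen for an edge is kept. Used to integrate the
#' mRNA-pathway-level and microRNA-pathway-level networks.
#'
#' @param ... `drug_network` objects.
#' @return a `drug_network`.
#' @export
merge_networks <- function(...) {
  nets <- list(...)
  stopifnot(length(nets) >= 1L, all(vapply(nets, inherits, logical(1), "drug_network")))
  edges <- dplyr::bind_rows(lapply(nets, network_edges))
  nodes <- unique(unlist(lapply(nets, network_nodes), use.names = FALSE))
  drug_network(edges, nodes = nodes)
}

#' Read and write undirected edge lists
#'
#' TSV with two drug-ID columns and an optional numeric weight column
#' (the dialect of published drug-similarity-network tables). A header row
#' is auto-detected when a third column is present and its first value is
#' non-numeric; two-column files are assumed headerless unless `header` is
#' set. Reversed duplicates collapse onto one canonical undirected edge and
#' self-loop rows are an error.
#'
#' @param path file path.
#' @param header `NULL` (auto-detect), `TRUE` or `FALSE`.
#' @param nodes optional character vector declaring nodes beyond the edge
#'   endpoints (e.g. isolated drugs).
#' @return [read_edge_list()] returns a [drug_network()];
#'   [write_edge_list()] returns `path` invisibly.
#' @export
read_edge_list <- function(path, header = NULL, nodes = NULL) {
  raw <- readLines(path, warn = FALSE)
  raw <- raw[nzchar(trimws(raw))]
  if (length(raw) == 0L) {
    return(drug_network(NULL, nodes = nodes))
  }
  fields <- strsplit(raw, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop_dsn(
      sprintf("edge-list row %d has fewer than 2 columns", which(nf < 2L)[1L]),
      "dsn_format_error"
    )
  }
  if (is.null(header)) {
    first <- fields[[1L]]
    header <- length(first) >= 3L &&
      is.na(suppressWarnings(as.numeric(first[3L])))
  }
  if (header) fields <- fields[-1L]
  if (length(fields) == 0L) return(drug_network(NULL, nodes = nodes))
  a <- vapply(fields, `[[`, character(1), 1L)
  b <- vapply(fields, `[[`, character(1), 2L)
  w <- vapply(fields, function(f) {
    if (length(f) >= 3L) suppressWarnings(as.numeric(f[3L])) else NA_real_
  }, numeric(1))
  drug_network(data.frame(from = a, to = b, weight = w), nodes = nodes)
}

#' @rdname read_edge_list
#' @param network a [drug_network()].
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "drug_network"))
  utils::write.table(
    network_edges(network), path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}
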