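#' Binary brain network
#'
#' An undirected simple binary graph on labelled nodes, the common currency
#' of the package.  The adjacency matrix is symmetric 0/1 with a zero
#' diagonal; `sparsity` records the fraction of realised node pairs and
#' `coordinates` (optional) the 3D region centroids in millimetres.
#'
#' @param adjacency square symmetric 0/1 matrix, zero diagonal; dimnames
#'   supply node labels (generated if absent).
#' @param sparsity fraction of realised node pairs; computed from the edge
#'   count when `NULL`.
#' @param coordinates optional data frame with columns `label`, `x`, `y`,
#'   `z` (mm), one row per node, as produced by [generate_coordinates()].
#' @return An object of class `brain_network`: a list with elements
#'   `labels`, `adjacency`, `sparsity`, `coordinates`.
#' @examples
#' a <- matrix(0, 3, 3); a[1, 2] <- a[2, 1] <- 1
#' net <- brain_network(a)
#' edge_count(net)
#' @export
brain_network <- function(adjacency, sparsity = NULL, coordinates = NULL) {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (n != ncol(adjacency)) stop("adjacency must be square")
  if (any(is.na(adjacency)) || !all(adjacency %in% c(0, 1)))
    stop("adjacency must be a 0/1 matrix with no missing values")
  if (any(diag(adjacency) != 0)) stop("self-loops are not allowed")
  if (any(adjacency != t(adjacency))) stop("adjacency must be symmetric")
  labels <- rownames(adjacency)
  if (is.null(labels)) labels <- default_labels(n)
  storage.mode(adjacency) <- "integer"
  dimnames(adjacency) <- list(labels, labels)
  m <- sum(adjacency) / 2L
  if (is.null(sparsity)) sparsity <- m / (n * (n - 1) / 2)
  if (!is.null(coordinates)) {
    coordinates <- validate_coordinates(coordinates)
    if (!identical(coordinates$label, labels))
      stop("coordinate labels do not match network labels")
  }
  structure(
    list(labels = labels, adjacency = adjacency,
         sparsity = sparsity, coordinates = coordinates),
    class = "brain_network"
  )
}

#' @export
print.brain_network <- function(x, ...) {
  cat(sprintf("<brain_network> %d nodes, %d edges (sparsity %.3f)\n",
              length(x$labels), edge_count(x), x$sparsity))
  invisible(x)
}

#' Number of edges in a brain network
#' @param network a [brain_network()].
#' @return integer edge count.
#' @export
edge_count <- function(network) {
  stopifnot(inherits(network, "brain_network"))
  as.integer(sum(network$adjacency) / 2L)
}

#' Convert a brain network to an igraph graph
#' @param network a [brain_network()].
#' @return an [igraph::igraph] undirected graph.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "brain_network"))
  igraph::graph_from_adjacency_matrix(network$adjacency, mode = "undirected")
}

default_labels <- function(n) sprintf("R%03d", seq_len(n))

validate_coordinates <- function(coords) {
  coords <- as.data.frame(coords)
  need <- c("label", "x", "y", "z")
  if (!all(need %in% names(coords)))
    stop("coordinates need columns label, x, y, z")
  coords$label <- as.character(coords$label)
  if (anyDuplicated(coords$label)) stop("duplicate coordinate labels")
  if (!all(is.finite(as.matrix(coords[, c("x", "y", "z")]))))
    stop("coordinates must be finite")
  coords
}

coord_matrix <- function(coords) {
  m <- as.matrix(coords[, c("x", "y", "z")])
  rownames(m) <- coords$label
  m
}

# round half away from zero (positive arguments), the edge-count rule:
# m = round(S * n(n-1)/2)
round_half_away <- function(x) floor(x + 0.5)

n_pairs <- function(n) n * (n - 1) / 2

# linear indices of the upper triangle, with their (i, j) rows/cols
upper_index <- function(n) which(upper.tri(matrix(NA_integer_, n, n)))

# build a symmetric 0/1 adjacency from linear upper-triangle indices
adjacency_from_upper <- function(n, idx, labels = default_labels(n)) {
  a <- matrix(0L, n, n)
  a[idx] <- 1L
  a <- a + t(a)
  dimnames(a) <- list(labels, labels)
  a
}

# seeded ranking of values with uniform tie-break; returns the indices of
# the m largest values
top_m_indices <- function(values, m, tie_seed) {
  stopifnot(m >= 1, m <= length(values))
  tb <- local({ set.seed(as.integer(tie_seed)); stats::runif(length(values)) })
  order(values, tb, decreasing = TRUE)[seq_len(m)]
}

#' Write / read a network edge list
#'
#' Plain TSV with columns `node_a`, `node_b`, one edge per row.
#'
#' @param network a [brain_network()].
#' @param path file path.
#' @export
write_edge_list <- function(network, path) {
  a <- network$adjacency
  idx <- which(upper.tri(a) & a == 1L, arr.ind = TRUE)
  df <- data.frame(node_a = network$labels[idx[, 1]],
                   node_b = network$labels[idx[, 2]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @param labels full node label set (edge lists do not record isolates).
#' @return `read_edge_list()` returns a [brain_network()].
#' @export
read_edge_list <- function(path, labels) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character")
  n <- length(labels)
  a <- matrix(0L, n, n, dimnames = list(labels, labels))
  ia <- match(df$node_a, labels); ib <- match(df$node_b, labels)
  if (anyNA(ia) || anyNA(ib)) stop("edge list contains unknown labels")
  a[cbind(ia, ib)] <- 1L
  a[cbind(ib, ia)] <- 1L
  brain_network(a)
}

#' Write / read an adjacency matrix TSV
#'
#' 0/1 matrix with a header row and a leading label column.
#'
#' @param network a [brain_network()].
#' @param path file path.
#' @export
write_adjacency <- function(network, path) {
  utils::write.table(network$adjacency, path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname write_adjacency
#' @export
read_adjacency <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  brain_network(m)
}
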