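#' Local-information similarity indices
#'
#' Seven node-pair similarity scores computed from immediate neighbourhoods
#' of a binary network.  Writing `cn_ij = |N(i) intersect N(j)|` for the
#' number of common neighbours and `k_i` for degree:
#'
#' * `CN`    — `cn_ij`
#' * `HDI`   — `cn_ij / max(k_i, k_j)` (hub depressed)
#' * `HPI`   — `cn_ij / min(k_i, k_j)` (hub promoted)
#' * `LHN-I` — `cn_ij / (k_i * k_j)` (Leicht-Holme-Newman)
#' * `PA`    — `k_i * k_j` (preferential attachment)
#' * `RA`    — `sum over common neighbours z of 1/k_z` (resource allocation)
#' * `SI`    — `2 cn_ij / (k_i + k_j)` (Sorensen)
#'
#' Ratios with a zero denominator (isolated nodes) are defined as 0 so no
#' non-finite score propagates downstream.  Diagonal entries are set to 0
#' and are excluded from all ranking.
#'
#' @param network a [brain_network()].
#' @return a symmetric nonnegative matrix of class `similarity_matrix` with
#'   attribute `index` naming the index.
#' @name local_information
NULL

similarity_result <- function(s, labels, index) {
  diag(s) <- 0
  dimnames(s) <- list(labels, labels)
  structure(s, index = index, class = c("similarity_matrix", "matrix"))
}

common_neighbor_counts <- function(a) {
  cn <- a %*% a
  diag(cn) <- 0
  cn
}

# elementwise ratio with the 0/0 -> 0 convention
safe_ratio <- function(num, den) {
  out <- num / den
  out[den == 0] <- 0
  out
}

#' @rdname local_information
#' @export
common_neighbors <- function(network) {
  a <- network$adjacency
  similarity_result(common_neighbor_counts(a), network$labels, "CN")
}

#' @rdname local_information
#' @export
hub_depressed <- function(network) {
  a <- network$adjacency
  k <- rowSums(a)
  s <- safe_ratio(common_neighbor_counts(a), outer(k, k, pmax))
  similarity_result(s, network$labels, "HDI")
}

#' @rdname local_information
#' @export
hub_promoted <- function(network) {
  a <- network$adjacency
  k <- rowSums(a)
  s <- safe_ratio(common_neighbor_counts(a), outer(k, k, pmin))
  similarity_result(s, network$labels, "HPI")
}

#' @rdname local_information
#' @export
leicht_holme_newman <- function(network) {
  a <- network$adjacency
  k <- rowSums(a)
  s <- safe_ratio(common_neighbor_counts(a), outer(k, k))
  similarity_result(s, network$labels, "LHN-I")
}

#' @rdname local_information
#' @export
preferential_attachment <- function(network) {
  k <- rowSums(network$adjacency)
  similarity_result(outer(k, k), network$labels, "PA")
}

#' @rdname local_information
#' @export
resource_allocation <- function(network) {
  a <- network$adjacency
  k <- rowSums(a)
  kinv <- ifelse(k > 0, 1 / k, 0)
  s <- a %*% (kinv * a)    # sum over common neighbours z of 1/k_z
  similarity_result(s, network$labels, "RA")
}

#' @rdname local_information
#' @export
sorensen <- function(network) {
  a <- network$adjacency
  k <- rowSums(a)
  s <- safe_ratio(2 * common_neighbor_counts(a), outer(k, k, "+"))
  similarity_result(s, network$labels, "SI")
}

#' The seven index names
#' @return character vector.
#' @export
similarity_indices <- function() {
  c("CN", "HDI", "HPI", "LHN-I", "PA", "RA", "SI")
}

#' Compute a named similarity index
#'
#' Dispatches over the seven indices of [local_information].
#'
#' @param network a [brain_network()].
#' @param index one of `r paste(similarity_indices(), collapse = ", ")`.
#' @return a `similarity_matrix`.
#' @export
compute_similarity <- function(network, index) {
  fns <- list("CN" = common_neighbors, "HDI" = hub_depressed,
              "HPI" = hub_promoted, "LHN-I" = leicht_holme_newman,
              "PA" = preferential_attachment, "RA" = resource_allocation,
              "SI" = sorensen)
  if (!index %in% names(fns))
    stop("unknown index '", index, "'; valid indices: ",
         paste(names(fns), collapse = ", "))
  fns[[index]](network)
}

#' Set-operation reference implementation of the indices
#'
#' Computes the same seven indices by explicit neighbour-set operations
#' (intersections and degree lookups in a double loop).  Slow but direct;
#' serves as the independent check of the matrix-algebra implementations.
#'
#' @inheritParams compute_similarity
#' @return a `similarity_matrix`.
#' @export
similarity_bruteforce <- function(network, index) {
  if (!index %in% similarity_indices())
    stop("unknown index '", index, "'")
  a <- network$adjacency
  n <- nrow(a)
  nb <- lapply(seq_len(n), function(i) which(a[i, ] == 1L))
  k <- lengths(nb)
  s <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      common <- intersect(nb[[i]], nb[[j]])
      cn <- length(common)
      val <- switch(index,
        "CN" = cn,
        "HDI" = if (max(k[i], k[j]) == 0) 0 else cn / max(k[i], k[j]),
        "HPI" = if (min(k[i], k[j]) == 0) 0 else cn / min(k[i], k[j]),
        "LHN-I" = if (k[i] * k[j] == 0) 0 else cn / (k[i] * k[j]),
        "PA" = k[i] * k[j],
        "RA" = if (cn == 0) 0 else sum(1 / k[common]),
        "SI" = if (k[i] + k[j] == 0) 0 else 2 * cn / (k[i] + k[j]))
      s[i, j] <- s[j, i] <- val
    }
  }
  similarity_result(s, network$labels, index)
}

#' Write a similarity matrix with an index tag
#'
#' TSV matrix preceded by a `# index: NAME` comment line.
#'
#' @param sim a `similarity_matrix`.
#' @param path file path.
#' @export
write_similarity <- function(sim, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# index: %s", attr(sim, "index")), con)
  utils::write.table(unclass(sim), con, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
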