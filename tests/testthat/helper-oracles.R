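# Fixtures and independent brute-force oracles used across the suite.
# Oracles are deliberately naive (set operations, boolean matrix powers,
# triple enumeration) and never call the code paths they check.

net_from_edges <- function(n, edges) {
  a <- matrix(0L, n, n)
  for (r in seq_len(nrow(edges))) {
    a[edges[r, 1], edges[r, 2]] <- 1L
    a[edges[r, 2], edges[r, 1]] <- 1L
  }
  brain_network(a)
}

cycle4 <- function() net_from_edges(4, rbind(c(1,2), c(2,3), c(3,4), c(4,1)))
star4  <- function() net_from_edges(4, rbind(c(1,2), c(1,3), c(1,4)))
path3  <- function() net_from_edges(3, rbind(c(1,2), c(2,3)))
k_n    <- function(n) net_from_edges(n, t(utils::combn(n, 2)))
two_triangles <- function()
  net_from_edges(6, rbind(c(1,2), c(2,3), c(1,3), c(4,5), c(5,6), c(4,6)))

# ring lattice: each node joined to its k nearest neighbours (k even)
ring_lattice <- function(n, k) {
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, ((i - 1 + seq_len(k / 2)) %% n) + 1)
  }))
  net_from_edges(n, edges)
}

# Erdos-Renyi G(n, m) with a fixed seed
rand_network <- function(n, m, seed) {
  set.seed(seed)
  idx <- which(upper.tri(matrix(NA, n, n)))
  a <- matrix(0L, n, n)
  a[sample(idx, m)] <- 1L
  brain_network(a + t(a))
}

rand_connected_network <- function(n, m, seed) {
  for (try in 0:50) {
    net <- rand_network(n, m, seed + 1000 * try)
    g <- as_igraph(net)
    if (igraph::is_connected(g)) return(net)
  }
  stop("could not draw a connected graph")
}

# shortest-path matrix by repeated boolean products (BFS oracle)
oracle_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a == 1] <- 1
  reach <- (a == 1)
  for (len in 2:n) {
    reach_new <- (reach %*% a) > 0
    newly <- reach_new & !reach & !diag(TRUE, n)
    if (!any(newly)) break
    d[newly & is.infinite(d)] <- len
    reach <- reach | reach_new
  }
  d
}

oracle_char_path_length <- function(net) {
  d <- oracle_distances(net$adjacency)
  v <- d[upper.tri(d)]
  mean(v[is.finite(v)])
}

oracle_global_efficiency <- function(net) {
  d <- oracle_distances(net$adjacency)
  mean(1 / d[upper.tri(d)])
}

oracle_local_efficiency <- function(net) {
  a <- net$adjacency
  n <- nrow(a)
  mean(vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1L)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(brain_network(a[nb, nb, drop = FALSE]))
  }, numeric(1)))
}

# per-node clustering by direct neighbour-pair counting
oracle_clustering <- function(net) {
  a <- net$adjacency
  n <- nrow(a)
  mean(vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1L)
    k <- length(nb)
    if (k < 2) return(0)
    sum(a[nb, nb]) / (k * (k - 1))
  }, numeric(1)))
}

# transitivity by explicit triple enumeration
oracle_transitivity <- function(net) {
  a <- net$adjacency
  n <- nrow(a)
  triangles <- 0
  triples <- 0
  for (trip in utils::combn(n, 3, simplify = FALSE)) {
    e <- a[trip[1], trip[2]] + a[trip[1], trip[3]] + a[trip[2], trip[3]]
    if (e == 3) triangles <- triangles + 1
    # a connected triple centred at each node with both edges present
  }
  k <- rowSums(a)
  triples <- sum(k * (k - 1) / 2)
  if (triples == 0) return(NA_real_)
  3 * triangles / triples
}

# degree correlation over directed edge ends
oracle_assortativity <- function(net) {
  a <- net$adjacency
  k <- rowSums(a)
  ends <- which(a == 1, arr.ind = TRUE)   # both directions
  stats::cor(k[ends[, 1]], k[ends[, 2]])
}

# set-operation similarity oracle, independent of the package's own
# bruteforce implementation
oracle_similarity <- function(net, index) {
  a <- net$adjacency
  n <- nrow(a)
  nbr <- lapply(seq_len(n), function(i) which(a[i, ] > 0))
  deg <- lengths(nbr)
  s <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    z <- intersect(nbr[[i]], nbr[[j]])
    cn <- length(z)
    s[i, j] <- switch(index,
      "CN" = cn,
      "HDI" = if (max(deg[i], deg[j]) > 0) cn / max(deg[i], deg[j]) else 0,
      "HPI" = if (min(deg[i], deg[j]) > 0) cn / min(deg[i], deg[j]) else 0,
      "LHN-I" = if (deg[i] * deg[j] > 0) cn / (deg[i] * deg[j]) else 0,
      "PA" = deg[i] * deg[j],
      "RA" = if (cn > 0) sum(1 / deg[z]) else 0,
      "SI" = if (deg[i] + deg[j] > 0) 2 * cn / (deg[i] + deg[j]) else 0)
  }
  s
}
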