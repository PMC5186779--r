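#' Global topological properties of a binary network
#'
#' The eight properties used to compare real and predicted networks:
#' assortativity `R`, clustering coefficient `C`, characteristic path
#' length `L`, global efficiency `E_glob`, local efficiency `E_loc`,
#' modularity `Q`, transitivity `T`, and the truncated power-law degree
#' distribution (see [fit_degree_distribution()]).  Metrics that are
#' undefined on a given graph (e.g. assortativity of a regular graph)
#' return `NA` with a `reason` attribute rather than a silent zero.
#'
#' @param network a [brain_network()].
#' @name graph_metrics
NULL

undefined_metric <- function(reason) structure(NA_real_, reason = reason)

#' @describeIn graph_metrics Newman's degree assortativity: the Pearson
#'   correlation of the degrees at the two ends of each edge.  `NA` when
#'   degrees over edge endpoints have zero variance.
#' @export
assortativity_coef <- function(network) {
  g <- as_igraph(network)
  if (igraph::ecount(g) < 2) return(undefined_metric("fewer than 2 edges"))
  r <- igraph::assortativity_degree(g, directed = FALSE)
  if (!is.finite(r)) return(undefined_metric("zero degree variance"))
  r
}

#' @describeIn graph_metrics Mean local clustering coefficient; nodes with
#'   degree < 2 contribute 0.
#' @export
clustering_coef <- function(network) {
  g <- as_igraph(network)
  igraph::transitivity(g, type = "localaverage", isolates = "zero")
}

#' @describeIn graph_metrics Mean shortest-path length over connected
#'   ordered pairs; disconnected pairs are excluded and flagged in the
#'   `disconnected` attribute.
#' @export
char_path_length <- function(network) {
  g <- as_igraph(network)
  if (igraph::ecount(g) == 0) return(undefined_metric("no connected pair"))
  l <- igraph::mean_distance(g, unconnected = TRUE)
  structure(l, disconnected = !igraph::is_connected(g))
}

#' @describeIn graph_metrics Mean over distinct pairs of the inverse
#'   shortest-path length (0 for disconnected pairs).
#' @export
global_efficiency <- function(network) {
  g <- as_igraph(network)
  if (igraph::vcount(g) < 2) return(undefined_metric("single node"))
  igraph::global_efficiency(g)
}

#' @describeIn graph_metrics Mean over nodes of the global efficiency of
#'   each node's open neighbourhood subgraph; nodes with degree < 2
#'   contribute 0.
#' @export
local_efficiency <- function(network) {
  g <- as_igraph(network)
  n <- igraph::vcount(g)
  if (n == 0) return(undefined_metric("empty graph"))
  a <- network$adjacency
  eff <- vapply(seq_len(n), function(i) {
    nb <- which(a[i, ] == 1L)
    if (length(nb) < 2) return(0)
    igraph::global_efficiency(igraph::induced_subgraph(g, nb))
  }, numeric(1))
  mean(eff)
}

#' @describeIn graph_metrics Newman-Girvan modularity
#'   `Q = sum_c (l_c/m - (d_c/2m)^2)`.  When `membership` is `NULL` the
#'   best partition found by a seeded greedy agglomerative run is scored;
#'   otherwise the supplied partition is scored directly by the formula.
#' @param membership optional integer community assignment to score.
#' @param seed seed for the community-detection run.
#' @export
modularity_q <- function(network, membership = NULL, seed = 1L) {
  m <- edge_count(network)
  if (m == 0L) return(undefined_metric("edgeless graph"))
  if (is.null(membership)) {
    g <- as_igraph(network)
    set.seed(as.integer(seed))
    membership <- igraph::membership(igraph::cluster_fast_greedy(g))
  }
  a <- network$adjacency
  comms <- unique(membership)
  q <- 0
  for (cm in comms) {
    nodes <- which(membership == cm)
    l_c <- sum(a[nodes, nodes, drop = FALSE]) / 2
    d_c <- sum(a[nodes, , drop = FALSE])
    q <- q + l_c / m - (d_c / (2 * m))^2
  }
  q
}

#' @describeIn graph_metrics Transitivity: 3 x triangles / connected
#'   triples.  `NA` when the graph has no connected triple.
#' @export
transitivity_ratio <- function(network) {
  g <- as_igraph(network)
  t <- igraph::transitivity(g, type = "global")
  if (!is.finite(t)) return(undefined_metric("no connected triple"))
  t
}

#' Fit an exponentially truncated power law to the degree distribution
#'
#' Fits the complementary cumulative degree distribution
#' `P(K >= k) ~ k^(alpha-1) * exp(-k / k_c)` by least squares on the log
#' scale over the observed positive degrees.  On that scale the model
#' `log S = c + (alpha - 1) log k - k / k_c` is linear in its parameters,
#' so the least-squares optimum is unique and obtained in closed form.
#'
#' @param network a [brain_network()], or an integer vector of degrees.
#' @return list of class `degree_fit`: `alpha` (estimated exponent), `k_c`
#'   (cutoff degree; `Inf` when no exponential decay is detected, with a
#'   warning), `fit_error` (residual norm on the log scale).
#' @export
fit_degree_distribution <- function(network) {
  degrees <- if (inherits(network, "brain_network")) {
    rowSums(network$adjacency)
  } else {
    as.numeric(network)
  }
  degrees <- degrees[degrees > 0]
  k <- sort(unique(degrees))
  if (length(k) < 5)
    stop("need at least 5 distinct positive degrees to fit")
  # empirical survival P(K >= k) over observed degrees
  s <- vapply(k, function(kk) mean(degrees >= kk), numeric(1))
  fit_truncated_powerlaw(k, s)
}

#' Fit the truncated power-law form to a survival curve
#'
#' Workhorse behind [fit_degree_distribution()], usable directly on a
#' tabulated curve `s(k) ~ k^(alpha-1) exp(-k/k_c)`.
#'
#' @param k degrees (positive).
#' @param s survival values in (0, 1]; zeros are dropped.
#' @param weights observation weights; the default `s` itself
#'   (proportional to the number of observations at or above `k`)
#'   stabilises the variance of the log-scale residuals, which otherwise
#'   explodes in the sparse tail.
#' @return a `degree_fit` list (`alpha`, `k_c`, `fit_error`).
#' @export
fit_truncated_powerlaw <- function(k, s, weights = s) {
  keep <- s > 0 & k > 0
  k <- k[keep]; s <- s[keep]; w <- weights[keep]
  if (length(k) < 3) stop("need at least 3 usable points")
  fit <- stats::lm(log(s) ~ log(k) + k, weights = w)
  co <- stats::coef(fit)
  alpha <- unname(co["log(k)"]) + 1
  slope <- unname(co["k"])
  if (slope >= -1e-10) {
    warning("no exponential decay detected; cutoff degree set to Inf")
    k_c <- Inf
  } else {
    k_c <- -1 / slope
  }
  structure(list(alpha = alpha, k_c = k_c,
                 fit_error = sqrt(sum(stats::residuals(fit)^2))),
            class = "degree_fit")
}

#' Area under a property curve over the sparsity grid
#'
#' Trapezoidal integral of per-sparsity property values; `NA` entries are
#' excluded pairwise.  Gives one summary scalar per property per network.
#'
#' @param values property values aligned to `grid`.
#' @param grid sparsity grid, default [sparsity_grid()].
#' @return scalar AUC, or `NA` with a reason if fewer than 2 points are
#'   defined.
#' @export
auc_over_sparsity <- function(values, grid = sparsity_grid()) {
  if (length(values) != length(grid))
    stop("values must align with the grid")
  keep <- is.finite(values)
  x <- grid[keep]; y <- values[keep]
  if (length(x) < 2) return(undefined_metric("fewer than 2 defined points"))
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

topology_properties <- c("R", "C", "L", "Eglob", "Eloc", "Q", "T")

# the seven scalar properties of one network
network_properties <- function(network, seed = 1L) {
  c(R = as.numeric(assortativity_coef(network)),
    C = as.numeric(clustering_coef(network)),
    L = as.numeric(char_path_length(network)),
    Eglob = as.numeric(global_efficiency(network)),
    Eloc = as.numeric(local_efficiency(network)),
    Q = as.numeric(modularity_q(network, seed = seed)),
    T = as.numeric(transitivity_ratio(network)))
}

#' Topology profile of a network family across the sparsity grid
#'
#' Computes the seven scalar properties and the degree-distribution fit for
#' one network per grid sparsity, plus the per-property AUC over the grid.
#' Undefined metrics are recorded as `NA`, never dropped.
#'
#' @param networks list of [brain_network()], one per grid entry.
#' @param grid sparsity grid, default [sparsity_grid()].
#' @param seed seed for the modularity optimiser.
#' @return list of class `topology_profile`: `values` (long data frame:
#'   `sparsity`, `property`, `value`, `defined`), `degree_fits` (one
#'   `degree_fit` or `NULL` per sparsity), `auc` (named vector over the
#'   seven properties).
#' @export
topology_profile <- function(networks, grid = sparsity_grid(), seed = 1L) {
  if (length(networks) != length(grid))
    stop("need exactly one network per grid sparsity")
  props <- t(vapply(networks, network_properties, numeric(7), seed = seed))
  colnames(props) <- topology_properties
  fits <- lapply(networks, function(net) {
    f <- try(fit_degree_distribution(net), silent = TRUE)
    if (inherits(f, "try-error")) NULL else f
  })
  values <- data.frame(
    sparsity = rep(grid, times = length(topology_properties)),
    property = rep(topology_properties, each = length(grid)),
    value = as.vector(props),
    defined = as.vector(is.finite(props))
  )
  auc <- apply(props, 2, auc_over_sparsity, grid = grid)
  structure(list(values = values, degree_fits = fits, auc = auc),
            class = "topology_profile")
}
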