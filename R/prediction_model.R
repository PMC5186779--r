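#' Euclidean distance matrix of region centroids
#'
#' @param coords centroid table (`label`, `x`, `y`, `z` in mm) with >= 2
#'   rows and no coincident positions.
#' @return symmetric matrix of straight-line distances in mm, zero diagonal.
#' @export
euclidean_distance_matrix <- function(coords) {
  coords <- validate_coordinates(coords)
  if (nrow(coords) < 2) stop("need at least 2 nodes")
  d <- as.matrix(stats::dist(coord_matrix(coords)))
  zero <- which(upper.tri(d) & d == 0, arr.ind = TRUE)
  if (nrow(zero) > 0)
    stop("coincident centroids: ",
         paste(coords$label[zero[1, 1]], coords$label[zero[1, 2]],
               sep = " / "))
  dimnames(d) <- list(coords$label, coords$label)
  d
}

#' The study gamma grid
#'
#' Exponents 0 to 3 in steps of 0.1 (31 values) over which the prediction
#' model is scanned.
#'
#' @return numeric vector of length 31.
#' @export
gamma_grid <- function() round(seq(0, 3, by = 0.1), 1)

#' Connection scores of the distance + similarity prediction model
#'
#' The model scores every node pair by combining anatomical distance with a
#' local-information similarity raised to the exponent `gamma`.  Under the
#' default `distance_mode = "penalty"` the score is `s_ij^gamma / d_ij`
#' (closer and more similar pairs score higher, the distance-penalisation
#' premise); `distance_mode = "literal"` scores `d_ij * s_ij^gamma`.  The
#' convention `s^0 = 1` (including `0^0`) makes `gamma = 0` the pure
#' distance model.
#'
#' @param dist distance matrix from [euclidean_distance_matrix()].
#' @param sim a `similarity_matrix` with matching labels.
#' @param gamma exponent >= 0.
#' @param distance_mode `"penalty"` (default) or `"literal"`.
#' @return symmetric matrix of class `score_matrix` with attributes
#'   `gamma`, `index`, `distance_mode`; diagonal 0.
#' @export
prediction_scores <- function(dist, sim, gamma,
                              distance_mode = c("penalty", "literal")) {
  distance_mode <- match.arg(distance_mode)
  if (gamma < 0) stop("gamma must be >= 0")
  if (!identical(rownames(dist), rownames(sim)))
    stop("distance and similarity labels do not match")
  sg <- unclass(sim)^gamma          # R gives 0^0 = 1, as required
  p <- if (distance_mode == "penalty") {
    off <- dist
    diag(off) <- 1                  # avoid 0/0 on the diagonal
    sg / off
  } else {
    dist * sg
  }
  diag(p) <- 0
  structure(p, gamma = gamma, index = attr(sim, "index"),
            distance_mode = distance_mode,
            class = c("score_matrix", "matrix"))
}

#' Select the top-m scoring pairs as a predicted network
#'
#' Returns the `m` node pairs with the highest connection scores as a
#' binary network, so the predicted network is edge-matched to the real
#' one.  Ties at the cutoff are broken by a seeded uniform draw.
#'
#' @param scores a `score_matrix` (or any symmetric score matrix).
#' @param m number of edges, `1 <= m <= n(n-1)/2`.
#' @param tie_seed seed for tie-breaking.
#' @return a [brain_network()] with exactly `m` edges.
#' @export
select_edges <- function(scores, m, tie_seed = 1L) {
  n <- nrow(scores)
  if (m < 1 || m > n_pairs(n))
    stop(sprintf("m = %s out of range [1, %d]", m, n_pairs(n)))
  idx <- upper_index(n)
  chosen <- idx[top_m_indices(unclass(scores)[idx], m, tie_seed)]
  labels <- rownames(scores)
  if (is.null(labels)) labels <- default_labels(n)
  brain_network(adjacency_from_upper(n, chosen, labels))
}

#' Predict a network from distance and one similarity index
#'
#' Convenience wrapper: similarity from the real network, scores at a fixed
#' `gamma`, edge selection matched to the real edge count.
#'
#' @param real the real [brain_network()] being predicted.
#' @param dist distance matrix.
#' @param index similarity index name (see [similarity_indices()]).
#' @param gamma exponent.
#' @inheritParams prediction_scores
#' @inheritParams select_edges
#' @return predicted [brain_network()].
#' @export
predict_network <- function(real, dist, index, gamma,
                            distance_mode = "penalty", tie_seed = 1L) {
  sim <- compute_similarity(real, index)
  p <- prediction_scores(dist, sim, gamma, distance_mode)
  select_edges(p, edge_count(real), tie_seed)
}

#' Scan the gamma grid for the best prediction
#'
#' Evaluates the prediction model at every grid exponent, scoring each
#' predicted network either by prediction power against the real network
#' (cheap, the default) or by the energy of its topological agreement
#' (expensive).  Similarity is computed from the real network itself — the
#' method's deliberate circularity.  On ties the smallest gamma wins.
#'
#' @param real the real [brain_network()].
#' @param dist distance matrix.
#' @param index similarity index name.
#' @param grid exponent grid, default [gamma_grid()].
#' @param criterion `"prediction_power"` or `"energy"`.
#' @param distance_mode `"penalty"` or `"literal"`.
#' @param tie_seed seed for edge-selection tie-breaks.
#' @param metric_seed seed for the modularity optimiser (energy criterion).
#' @return list with `best_gamma`, `predicted` ([brain_network()]),
#'   `trace` (data frame of gamma and criterion values).
#' @export
gamma_scan <- function(real, dist, index, grid = gamma_grid(),
                       criterion = c("prediction_power", "energy"),
                       distance_mode = "penalty", tie_seed = 1L,
                       metric_seed = 1L) {
  criterion <- match.arg(criterion)
  m <- edge_count(real)
  if (m == 0L) stop("real network has no edges")
  sim <- compute_similarity(real, index)
  preds <- lapply(grid, function(g) {
    select_edges(prediction_scores(dist, sim, g, distance_mode), m, tie_seed)
  })
  vals <- vapply(preds, function(p) {
    if (criterion == "prediction_power") {
      prediction_power(p, real)
    } else {
      single_network_energy(p, real, seed = metric_seed)
    }
  }, numeric(1))
  best <- which.max(vals)   # which.max takes the first (smallest gamma) tie
  list(best_gamma = grid[best], predicted = preds[[best]],
       trace = data.frame(gamma = grid, criterion = vals))
}

# energy of agreement between one predicted and one real network at a single
# sparsity, over the property set defined at that level (degree fit included
# when both fits are defined); used by the energy criterion of gamma_scan
single_network_energy <- function(predicted, real, seed = 1L) {
  props <- function(net) {
    c(R = assortativity_coef(net), C = clustering_coef(net),
      L = char_path_length(net), Eglob = global_efficiency(net),
      Eloc = local_efficiency(net), Q = modularity_q(net, seed = seed),
      T = transitivity_ratio(net))
  }
  pd <- props(real)
  pm <- props(predicted)
  re <- abs((pd - pm) / pd)
  fr <- try(fit_degree_distribution(real), silent = TRUE)
  fp <- try(fit_degree_distribution(predicted), silent = TRUE)
  if (!inherits(fr, "try-error") && !inherits(fp, "try-error")) {
    re <- c(re, Pk = degree_distribution_error(fr, fp) / 100)
  }
  re <- re[is.finite(re)]
  if (length(re) == 0 || sum(re) == 0) return(1e6)
  1 / sum(re)
}
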