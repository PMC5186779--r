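#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic cohort: a 90-region parcellation with
#' ~238 retained volumes per subject is emulated by default, with spatially
#' embedded modular networks at 15% sparsity.  Edges are laid down with an
#' exponential distance decay (`distance_decay_lambda`, mm) and a
#' within-module preference (`within_module_boost`), the two ingredients
#' that give the ensemble the distance penalty, triadic clustering and hub
#' structure the prediction models exploit.  Time series are drawn from a
#' multivariate normal whose covariance is `noise_sd^2 * I +
#' coupling_strength * A`.
#'
#' @param n_regions number of regions (nodes).
#' @param n_modules number of spatial modules.
#' @param n_timepoints number of volumes (samples) per region.
#' @param sparsity fraction of realised node pairs in (0, 1).
#' @param distance_decay_lambda exponential decay length of the edge
#'   probability with distance, mm.
#' @param within_module_boost multiplicative preference (>= 1) for pairs in
#'   the same module.
#' @param coupling_strength covariance contributed by each edge
#'   (dimensionless, >= 0).
#' @param noise_sd standard deviation of the independent noise (> 0).
#' @param seed integer seed; every generator is a pure function of
#'   (inputs, seed).
#' @return a list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_regions = 90L, n_modules = 6L,
                             n_timepoints = 238L, sparsity = 0.15,
                             distance_decay_lambda = 20,
                             within_module_boost = 20,
                             coupling_strength = 0.6, noise_sd = 1,
                             seed = 42L) {
  cfg <- list(n_regions = as.integer(n_regions),
              n_modules = as.integer(n_modules),
              n_timepoints = as.integer(n_timepoints),
              sparsity = sparsity,
              distance_decay_lambda = distance_decay_lambda,
              within_module_boost = within_module_boost,
              coupling_strength = coupling_strength,
              noise_sd = noise_sd,
              seed = as.integer(seed))
  if (cfg$n_modules > cfg$n_regions) stop("n_modules must be <= n_regions")
  if (cfg$sparsity <= 0 || cfg$sparsity >= 1) stop("sparsity must be in (0,1)")
  if (round_half_away(cfg$sparsity * n_pairs(cfg$n_regions)) < 1)
    stop("sparsity too small: no edges would be drawn")
  if (cfg$within_module_boost < 1) stop("within_module_boost must be >= 1")
  if (cfg$coupling_strength < 0) stop("coupling_strength must be >= 0")
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate region centroid coordinates
#'
#' Samples `n_regions` centroids uniformly in a 140 x 170 x 120 mm box
#' (roughly a brain bounding box in MNI space).  When `mirror` is `TRUE`
#' and `n_regions` is even, points come in left/right pairs mirrored across
#' the x midplane, emulating the hemispheric symmetry of an anatomical
#' parcellation.
#'
#' @param n_regions number of regions (>= 2).
#' @param seed integer seed.
#' @param mirror mirror pairs across the x midplane (cosmetic).
#' @return data frame with columns `label`, `x`, `y`, `z` (mm).
#' @export
generate_coordinates <- function(n_regions, seed, mirror = TRUE) {
  n_regions <- as.integer(n_regions)
  if (n_regions < 2) stop("n_regions must be >= 2")
  set.seed(as.integer(seed))
  if (mirror && n_regions %% 2L == 0L) {
    h <- n_regions %/% 2L
    x <- stats::runif(h, 1, 70)   # strictly positive so mirrors never touch
    y <- stats::runif(h, -85, 85)
    z <- stats::runif(h, -60, 60)
    xyz <- rbind(cbind(x, y, z), cbind(-x, y, z))
  } else {
    xyz <- cbind(stats::runif(n_regions, -70, 70),
                 stats::runif(n_regions, -85, 85),
                 stats::runif(n_regions, -60, 60))
  }
  data.frame(label = default_labels(n_regions),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

#' Generate a spatially embedded modular network
#'
#' Partitions the nodes into `config$n_modules` contiguous spatial clusters
#' (k-means on the centroids), weights every node pair by
#' `exp(-d_ij / lambda)` times `within_module_boost` for same-module pairs,
#' and draws exactly `round(sparsity * n(n-1)/2)` edges without replacement
#' with probability proportional to the weights.  The result is a simple
#' undirected graph whose ensemble shows distance-dependent connectivity,
#' high clustering and small-worldness.
#'
#' @param coords centroid table from [generate_coordinates()].
#' @param config a [synthetic_config()]; its `seed` drives all randomness.
#' @return a list of class `ground_truth`: `network` ([brain_network()]),
#'   `coordinates`, `module_assignment` (integer vector named by label).
#' @export
generate_spatial_modular_network <- function(coords, config) {
  coords <- validate_coordinates(coords)
  n <- nrow(coords)
  if (n != config$n_regions)
    stop("coords row count does not match config$n_regions")
  m <- round_half_away(config$sparsity * n_pairs(n))
  if (m > n_pairs(n)) stop("requested edge count exceeds number of pairs")
  xyz <- coord_matrix(coords)
  set.seed(config$seed)
  modules <- if (config$n_modules > 1L) {
    stats::kmeans(xyz, centers = config$n_modules, nstart = 5L)$cluster
  } else rep(1L, n)
  names(modules) <- coords$label
  d <- as.matrix(stats::dist(xyz))
  same <- outer(modules, modules, "==")
  w <- exp(-d / config$distance_decay_lambda) *
    ifelse(same, config$within_module_boost, 1)
  idx <- upper_index(n)
  chosen <- idx[sample.int(length(idx), m, prob = w[idx])]
  net <- brain_network(adjacency_from_upper(n, chosen, coords$label),
                       sparsity = config$sparsity, coordinates = coords)
  structure(list(network = net, coordinates = coords,
                 module_assignment = modules),
            class = "ground_truth")
}

#' Generate regional time series from a ground-truth network
#'
#' Draws `n_timepoints` independent samples from a zero-mean multivariate
#' normal with covariance `Sigma = noise_sd^2 * I + coupling_strength * A`
#' (A the adjacency matrix).  If `Sigma` is not positive definite a ridge
#' of `|min eigenvalue| + 1e-6` is added to the diagonal, with a message.
#' Connected pairs therefore share covariance `coupling_strength` and
#' unconnected pairs none, which is what correlation-based network
#' construction can recover.
#'
#' @param truth a `ground_truth` from [generate_spatial_modular_network()].
#' @param config a [synthetic_config()].
#' @return regions x timepoints numeric matrix, rownames = region labels.
#' @export
generate_time_series <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"))
  a <- truth$network$adjacency
  n <- nrow(a)
  sigma <- config$noise_sd^2 * diag(n) + config$coupling_strength * a
  sigma <- (sigma + t(sigma)) / 2
  ev_min <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min <= 1e-8) {
    ridge <- abs(ev_min) + 1e-6
    message(sprintf("covariance not positive definite; adding ridge %.4g",
                    ridge))
    sigma <- sigma + ridge * diag(n)
  }
  set.seed(config$seed)
  x <- MASS::mvrnorm(config$n_timepoints, mu = rep(0, n), Sigma = sigma)
  ts <- t(x)
  dimnames(ts) <- list(truth$network$labels,
                       sprintf("t%03d", seq_len(config$n_timepoints)))
  ts
}

#' Small-world scalar sigma
#'
#' `sigma = (C / C_rand) / (L / L_rand)` where `C` is the mean local
#' clustering coefficient, `L` the characteristic path length, and the
#' `_rand` values are means over `n_random` degree-preserving rewirings of
#' the network's largest connected component.  `sigma > 1` indicates
#' small-worldness.
#'
#' @param network a [brain_network()].
#' @param n_random number of rewired null graphs (>= 1).
#' @param seed integer seed for the rewiring.
#' @return scalar sigma.
#' @export
small_world_scalar <- function(network, n_random = 20L, seed = 1L) {
  stopifnot(inherits(network, "brain_network"))
  if (edge_count(network) == 0L) stop("network has no edges")
  if (n_random < 1L) stop("n_random must be >= 1")
  g <- as_igraph(network)
  comp <- igraph::components(g)
  g <- igraph::induced_subgraph(g, which(comp$membership ==
                                           which.max(comp$csize)))
  c_obs <- igraph::transitivity(g, type = "localaverage", isolates = "zero")
  l_obs <- igraph::mean_distance(g, unconnected = TRUE)
  set.seed(as.integer(seed))
  nulls <- vapply(seq_len(n_random), function(i) {
    gr <- igraph::rewire(g, igraph::keeping_degseq(
      niter = 10 * igraph::ecount(g)))
    c(igraph::transitivity(gr, type = "localaverage", isolates = "zero"),
      igraph::mean_distance(gr, unconnected = TRUE))
  }, numeric(2))
  c_rand <- mean(nulls[1, ])
  l_rand <- mean(nulls[2, ])
  (c_obs / c_rand) / (l_obs / l_rand)
}

#' Sample degrees from a truncated power law
#'
#' Draws integer degrees whose complementary cumulative distribution
#' follows `S(k) proportional to k^(alpha-1) * exp(-k/k_c)` on the
#' decreasing branch of that form (k at and beyond its mode
#' `(alpha-1)*k_c`), the regime in which the form is a valid survival
#' function.  Used for parameter-recovery simulations of
#' [fit_degree_distribution()].
#'
#' @param n number of draws.
#' @param alpha exponent of the truncated power law.
#' @param k_c cutoff degree.
#' @param k_max largest degree represented.
#' @param seed integer seed.
#' @return integer vector of degrees.
#' @export
sample_truncated_powerlaw <- function(n, alpha, k_c, k_max = 500L, seed = 1L) {
  k0 <- max(1L, as.integer(ceiling((alpha - 1) * k_c)))
  k <- seq.int(k0, k_max)
  s <- k^(alpha - 1) * exp(-k / k_c)
  s <- s / s[1]
  pmf <- c(-diff(s), s[length(s)])
  set.seed(as.integer(seed))
  sample(k, n, replace = TRUE, prob = pmf)
}

#' Write the synthetic-study text outputs
#'
#' Writes the coordinate table, the regions x timepoints series matrix,
#' the ground-truth edge list and the module assignment, all as TSV.
#'
#' @param truth a `ground_truth`.
#' @param ts time-series matrix from [generate_time_series()].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_synthetic_subject <- function(truth, ts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(truth$coordinates, file.path(dir, "coordinates.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ts, file.path(dir, "timeseries.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  write_edge_list(truth$network, file.path(dir, "truth_edges.tsv"))
  utils::write.table(
    data.frame(label = names(truth$module_assignment),
               module = as.integer(truth$module_assignment)),
    file.path(dir, "modules.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
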