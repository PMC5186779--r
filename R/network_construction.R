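#' Regress nuisance signals out of regional time series
#'
#' Each regional series is regressed (ordinary least squares) on an
#' intercept plus the supplied confound columns — typically mean CSF and
#' white-matter signals and the six motion parameters — and the residuals
#' are returned.  With no confounds this is mean-centring.
#'
#' @param ts regions x timepoints numeric matrix.
#' @param confounds timepoints x k numeric matrix (or `NULL` for none).
#' @return regions x timepoints matrix of residuals.
#' @export
regress_confounds <- function(ts, confounds = NULL) {
  ts <- as.matrix(ts)
  tp <- ncol(ts)
  if (is.null(confounds) || NCOL(confounds) == 0L) {
    return(ts - rowMeans(ts))
  }
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != tp)
    stop("confound rows must match the number of timepoints")
  x <- cbind(`(intercept)` = 1, confounds)
  if (is.null(colnames(confounds)))
    colnames(x)[-1] <- sprintf("confound%d", seq_len(ncol(confounds)))
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[-seq_len(qx$rank)]]
    stop("confound design is rank deficient; offending columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm.fit(x, t(ts))
  res <- t(fit$residuals)
  dimnames(res) <- dimnames(ts)
  res
}

#' Pearson correlation matrix of regional time series
#'
#' @param ts regions x timepoints numeric matrix with >= 3 timepoints; every
#'   region must have positive variance.
#' @return symmetric correlation matrix with unit diagonal, labelled by the
#'   rownames of `ts`.
#' @export
pearson_correlation_matrix <- function(ts) {
  ts <- as.matrix(ts)
  if (ncol(ts) < 3) stop("need at least 3 timepoints")
  if (anyNA(ts)) stop("time series contain missing values")
  v <- apply(ts, 1, stats::var)
  if (any(v <= 0)) {
    labs <- rownames(ts)
    if (is.null(labs)) labs <- default_labels(nrow(ts))
    stop("zero-variance region(s): ", paste(labs[v <= 0], collapse = ", "))
  }
  r <- stats::cor(t(ts))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  if (is.null(rownames(r))) dimnames(r) <- list(default_labels(nrow(ts)),
                                                default_labels(nrow(ts)))
  r
}

#' Threshold a correlation matrix at a target sparsity
#'
#' Keeps exactly `m = round(S * n(n-1)/2)` edges: the `m` largest
#' off-diagonal correlations (`mode = "signed"`, the default) or largest
#' absolute correlations (`mode = "absolute"`).  Ties at the cutoff are
#' broken by a seeded uniform draw so runs are reproducible.
#'
#' @param corr symmetric correlation matrix with unit diagonal.
#' @param sparsity target edge fraction S in (0, 1].
#' @param tie_seed seed for tie-breaking at the cutoff.
#' @param mode rank signed correlations or their absolute values.
#' @param coordinates optional centroid table attached to the result.
#' @return a [brain_network()] with exactly `m` edges.
#' @export
threshold_by_sparsity <- function(corr, sparsity, tie_seed = 1L,
                                  mode = c("signed", "absolute"),
                                  coordinates = NULL) {
  mode <- match.arg(mode)
  corr <- as.matrix(corr)
  n <- nrow(corr)
  if (n != ncol(corr)) stop("correlation matrix must be square")
  if (sparsity <= 0 || sparsity > 1) stop("sparsity must be in (0, 1]")
  m <- round_half_away(sparsity * n_pairs(n))
  if (m < 1 || m > n_pairs(n))
    stop(sprintf("edge count %d out of range [1, %d]", m, n_pairs(n)))
  idx <- upper_index(n)
  vals <- corr[idx]
  if (mode == "absolute") vals <- abs(vals)
  chosen <- idx[top_m_indices(vals, m, tie_seed)]
  labels <- rownames(corr)
  if (is.null(labels)) labels <- default_labels(n)
  brain_network(adjacency_from_upper(n, chosen, labels),
                sparsity = sparsity, coordinates = coordinates)
}

#' The study sparsity grid
#'
#' Sparsity thresholds from 5% to 40% in steps of 5%, the standard range
#' over which binary functional brain networks retain small-worldness.
#'
#' @return numeric vector of 8 fractions.
#' @export
sparsity_grid <- function() seq(0.05, 0.40, by = 0.05)

#' Read a regions x timepoints time-series TSV
#'
#' @param path TSV with a leading label column and one column per timepoint.
#' @return numeric matrix with region rownames.
#' @export
read_timeseries <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                              row.names = 1, check.names = FALSE))
}

#' Read a centroid coordinate TSV (label, x, y, z)
#' @param path TSV path.
#' @return coordinate data frame.
#' @export
read_coordinates <- function(path) {
  validate_coordinates(utils::read.table(path, sep = "\t", header = TRUE,
                                         stringsAsFactors = FALSE))
}
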