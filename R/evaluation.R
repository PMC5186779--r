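#' Relative error of a predicted property value
#'
#' `re = |(pd - pm) / pd| * 100` percent, where `pd` is the real network's
#' property value and `pm` the predicted network's.
#'
#' @param pd real value (nonzero).
#' @param pm predicted value.
#' @return percent relative error; `NA` with a warning when `pd = 0`.
#' @export
relative_error <- function(pd, pm) {
  if (!is.finite(pd) || !is.finite(pm)) return(NA_real_)
  if (pd == 0) {
    warning("relative error undefined for a zero reference value")
    return(NA_real_)
  }
  abs((pd - pm) / pd) * 100
}

#' Relative error between two degree-distribution fits
#'
#' The degree distribution is compared through its two fitted parameters:
#' the mean of the relative errors of the exponent `alpha` and of the
#' cutoff degree `k_c`.
#'
#' @param fit_real,fit_pred `degree_fit` objects from
#'   [fit_degree_distribution()].
#' @return percent error, or `NA` if either fit is undefined.
#' @export
degree_distribution_error <- function(fit_real, fit_pred) {
  if (is.null(fit_real) || is.null(fit_pred)) return(NA_real_)
  re_a <- relative_error(fit_real$alpha, fit_pred$alpha)
  re_k <- if (is.infinite(fit_real$k_c) && is.infinite(fit_pred$k_c)) {
    0
  } else if (is.infinite(fit_real$k_c) || is.infinite(fit_pred$k_c)) {
    NA_real_
  } else {
    relative_error(fit_real$k_c, fit_pred$k_c)
  }
  mean(c(re_a, re_k))
}

#' Energy of a prediction
#'
#' The reciprocal of the summed relative errors of the eight topological
#' properties, `E = 1 / (re_R + re_C + re_L + re_Eloc + re_Eglob + re_Q +
#' re_T + re_P(k))`, with the errors as fractions (not percent).  All
#' properties carry equal weight; higher E means a predicted network more
#' similar to the real one.
#'
#' @param re named vector of the eight relative errors as fractions.
#' @param cap sentinel returned (with a warning) for a perfect prediction
#'   with zero summed error.
#' @return scalar E; `NA` if any entry is missing.
#' @export
energy <- function(re, cap = 1e6) {
  if (length(re) != 8) stop("energy needs the eight property errors")
  if (anyNA(re)) return(NA_real_)
  s <- sum(re)
  if (s == 0) {
    warning("zero summed error (perfect prediction); returning capped E")
    return(cap)
  }
  1 / s
}

#' Prediction power in decibels
#'
#' `10 * log10(Pre_M / Pre_R)` where `Pre_M` is the fraction of the real
#' network's edges recovered by the prediction and `Pre_R` the recovery
#' fraction of a random m-edge prediction — analytically
#' `m / (n(n-1)/2)` (the expected overlap fraction of a uniformly random
#' m-edge graph), or a seeded Monte-Carlo mean.  0 dB is chance level.
#'
#' @param predicted,real edge-matched [brain_network()]s on the same nodes.
#' @param baseline `"analytic"` (default) or `"monte_carlo"`.
#' @param n_random Monte-Carlo draws.
#' @param seed Monte-Carlo seed.
#' @return prediction power in dB.  A prediction recovering zero edges is
#'   floored at `Pre_M = 1/(2m)` with a warning rather than -Inf.
#' @export
prediction_power <- function(predicted, real,
                             baseline = c("analytic", "monte_carlo"),
                             n_random = 100L, seed = 1L) {
  baseline <- match.arg(baseline)
  stopifnot(inherits(predicted, "brain_network"),
            inherits(real, "brain_network"))
  if (!identical(predicted$labels, real$labels))
    stop("networks are on different node sets")
  m <- edge_count(real)
  if (edge_count(predicted) != m)
    stop(sprintf("edge counts differ (predicted %d, real %d)",
                 edge_count(predicted), m))
  if (m == 0L) stop("real network has no edges")
  n <- length(real$labels)
  overlap <- sum(predicted$adjacency * real$adjacency) / 2
  pre_m <- overlap / m
  if (pre_m == 0) {
    warning("prediction recovers no edge; flooring Pre_M at 1/(2m)")
    pre_m <- 1 / (2 * m)
  }
  pre_r <- if (baseline == "analytic") {
    m / n_pairs(n)
  } else {
    idx <- upper_index(n)
    real_set <- which(real$adjacency[idx] == 1L)
    set.seed(as.integer(seed))
    draws <- vapply(seq_len(n_random), function(i) {
      length(intersect(sample.int(length(idx), m), real_set)) / m
    }, numeric(1))
    nz <- draws[draws > 0]
    if (length(nz) < length(draws))
      message(sprintf("%d zero-overlap baseline draw(s) excluded",
                      length(draws) - length(nz)))
    if (length(nz) == 0) stop("all baseline draws had zero overlap")
    mean(nz)
  }
  10 * log10(pre_m / pre_r)
}

#' Paired nonparametric test on per-subject property values
#'
#' Two-sided Wilcoxon signed-rank test on the paired differences between
#' real and predicted per-subject values (exact null distribution for
#' n <= 25 when free of zeros and ties).
#'
#' @param real_values,pred_values equal-length numeric vectors (n >= 6).
#' @return two-sided p-value; 1 when all differences are zero.
#' @export
paired_property_test <- function(real_values, pred_values) {
  if (length(real_values) != length(pred_values))
    stop("paired vectors must have equal length")
  n <- length(real_values)
  if (n < 6) stop("need at least 6 pairs")
  d <- real_values - pred_values
  if (all(d == 0)) return(1)
  d_nz <- d[d != 0]
  exact <- length(d_nz) <= 25 && !any(duplicated(abs(d_nz))) && all(d != 0)
  stats::wilcox.test(real_values, pred_values, paired = TRUE,
                     exact = exact)$p.value
}

#' Benjamini-Hochberg FDR rejection flags
#'
#' Step-up procedure at level `q`: reject all `p <= p_(k*)` where `k*` is
#' the largest `k` with `p_(k) <= k q / m`.
#'
#' @param pvals p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return logical rejection flags, same order as `pvals`.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (length(pvals) == 0) return(logical(0))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH") <= q
}

#' One-way fixed-effects ANOVA across prediction models
#'
#' @param groups list of numeric vectors, one per model (>= 2 groups of
#'   >= 2 values each).
#' @return list with `F` and `p`.
#' @export
model_anova <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) < 2))
    stop("need at least 2 groups of at least 2 values")
  values <- unlist(groups, use.names = FALSE)
  grp <- factor(rep(seq_along(groups), lengths(groups)))
  if (all(vapply(groups, stats::var, numeric(1)) == 0) &&
      stats::var(values) == 0)
    stop("degenerate: no variance anywhere")
  fit <- stats::oneway.test(values ~ grp, var.equal = TRUE)
  list(F = unname(fit$statistic), p = unname(fit$p.value))
}

#' Correlation between energy and prediction power
#'
#' Pearson correlation with a two-sided p-value across subjects.
#'
#' @param e_values per-subject energies.
#' @param pp_values per-subject prediction powers (same length >= 4).
#' @return list with `r` and `p`.
#' @export
energy_power_correlation <- function(e_values, pp_values) {
  if (length(e_values) != length(pp_values) || length(e_values) < 4)
    stop("need equal-length vectors of at least 4 values")
  if (stats::var(e_values) == 0 || stats::var(pp_values) == 0)
    stop("degenerate: zero variance")
  ct <- stats::cor.test(e_values, pp_values, method = "pearson")
  list(r = unname(ct$estimate), p = unname(ct$p.value))
}
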