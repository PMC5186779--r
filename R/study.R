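#' Evaluate predicted networks against real ones across a cohort
#'
#' Assembles the full evaluation surface: per-property relative errors
#' between real and predicted AUC-over-sparsity summaries (plus the
#' degree-distribution error at a reference sparsity), per-subject energy
#' and prediction power, FDR-flagged paired signed-rank tests per property
#' per model, one-way ANOVA over models for energy and prediction power,
#' and the energy-prediction-power correlation per model.
#'
#' @param real_networks list over subjects; each element a list of
#'   [brain_network()], one per grid sparsity.
#' @param predictions list over subjects; each element a named list over
#'   model indices, each holding `networks` (per-sparsity predicted
#'   [brain_network()]s) and `gamma` (the exponent used).
#' @param grid sparsity grid, default [sparsity_grid()].
#' @param reference_sparsity sparsity at which degree distributions are
#'   fitted and compared (default 0.15).
#' @param q FDR level for the group tests.
#' @param seed seed for the modularity optimiser.
#' @return list of class `evaluation_report`; see Details.
#' @details The report holds `per_subject` (subject, index, gamma, energy,
#'   prediction_power), `property_errors` (percent relative error per
#'   subject x index x property), `pp_by_sparsity`, `group_tests`
#'   (paired-test p per property x index with BH rejection flags at `q`),
#'   `anova` (energy and prediction power), and `correlations` (energy vs
#'   prediction power per index, BH-flagged).  Group statistics needing
#'   more subjects than supplied are reported as `NA`.
#' @export
evaluate_models <- function(real_networks, predictions,
                            grid = sparsity_grid(),
                            reference_sparsity = 0.15, q = 0.05, seed = 1L) {
  n_sub <- length(real_networks)
  if (n_sub == 0) stop("no subjects supplied")
  if (length(predictions) != n_sub)
    stop("predictions must cover every subject")
  indices <- names(predictions[[1]])
  for (s in seq_len(n_sub)) {
    if (!identical(names(predictions[[s]]), indices))
      stop("subject ", s, " is missing predictions for some model(s)")
    if (length(real_networks[[s]]) != length(grid))
      stop("subject ", s, ": one real network per grid sparsity required")
  }
  ref_i <- which.min(abs(grid - reference_sparsity))

  real_profiles <- lapply(real_networks, topology_profile, grid = grid,
                          seed = seed)

  err_rows <- list(); subj_rows <- list(); pp_rows <- list()
  pred_aucs <- array(NA_real_,
                     dim = c(n_sub, length(indices),
                             length(topology_properties)),
                     dimnames = list(NULL, indices, topology_properties))
  for (s in seq_len(n_sub)) {
    for (idx in indices) {
      pred <- predictions[[s]][[idx]]
      prof_p <- topology_profile(pred$networks, grid = grid, seed = seed)
      pred_aucs[s, idx, ] <- prof_p$auc[topology_properties]
      prof_r <- real_profiles[[s]]
      re <- vapply(topology_properties, function(pr) {
        relative_error(prof_r$auc[[pr]], prof_p$auc[[pr]])
      }, numeric(1))
      re["Pk"] <- degree_distribution_error(prof_r$degree_fits[[ref_i]],
                                            prof_p$degree_fits[[ref_i]])
      err_rows[[length(err_rows) + 1L]] <- data.frame(
        subject = s, index = idx, property = names(re),
        re_percent = unname(re))
      pp <- vapply(seq_along(grid), function(g) {
        prediction_power(pred$networks[[g]], real_networks[[s]][[g]])
      }, numeric(1))
      pp_rows[[length(pp_rows) + 1L]] <- data.frame(
        subject = s, index = idx, sparsity = grid, power_db = pp)
      subj_rows[[length(subj_rows) + 1L]] <- data.frame(
        subject = s, index = idx, gamma = pred$gamma,
        energy = energy(re / 100), prediction_power = mean(pp))
    }
  }
  property_errors <- do.call(rbind, err_rows)
  per_subject <- do.call(rbind, subj_rows)
  pp_by_sparsity <- do.call(rbind, pp_rows)

  # paired tests: real vs predicted AUC per property, per model, across
  # subjects; BH correction across the models within each property
  real_auc <- function(pr) vapply(real_profiles, function(p) p$auc[[pr]],
                                  numeric(1))
  group_rows <- list()
  for (pr in topology_properties) {
    pv <- vapply(indices, function(idx) {
      x <- real_auc(pr); y <- pred_aucs[, idx, pr]
      ok <- is.finite(x) & is.finite(y)
      if (sum(ok) < 6) return(NA_real_)
      paired_property_test(x[ok], y[ok])
    }, numeric(1))
    rej <- rep(NA, length(pv))
    if (!anyNA(pv)) rej <- bh_fdr(pv, q)
    group_rows[[length(group_rows) + 1L]] <- data.frame(
      property = pr, index = indices, p = unname(pv), rejected = rej)
  }
  group_tests <- do.call(rbind, group_rows)

  anova_for <- function(col) {
    groups <- lapply(indices, function(idx) {
      v <- per_subject[per_subject$index == idx, col]
      v[is.finite(v)]
    })
    if (length(indices) < 2 || any(lengths(groups) < 2))
      return(list(F = NA_real_, p = NA_real_))
    model_anova(groups)
  }

  correlations <- do.call(rbind, lapply(indices, function(idx) {
    e <- per_subject[per_subject$index == idx, "energy"]
    pp <- per_subject[per_subject$index == idx, "prediction_power"]
    ok <- is.finite(e) & is.finite(pp)
    if (sum(ok) < 4)
      return(data.frame(index = idx, r = NA_real_, p = NA_real_))
    ct <- energy_power_correlation(e[ok], pp[ok])
    data.frame(index = idx, r = ct$r, p = ct$p)
  }))
  correlations$rejected <- if (anyNA(correlations$p)) {
    rep(NA, nrow(correlations))
  } else bh_fdr(correlations$p, q)

  structure(list(
    per_subject = per_subject,
    property_errors = property_errors,
    pp_by_sparsity = pp_by_sparsity,
    group_tests = group_tests,
    anova = list(energy = anova_for("energy"),
                 prediction_power = anova_for("prediction_power")),
    correlations = correlations,
    settings = list(grid = grid, reference_sparsity = reference_sparsity,
                    q = q, seed = seed, indices = indices)
  ), class = "evaluation_report")
}

#' Run a complete synthetic prediction study
#'
#' Generates a cohort of synthetic subjects (shared centroid geometry,
#' per-subject spatial modular networks and correlated time series),
#' constructs binary networks across the sparsity grid by Pearson
#' correlation thresholding, predicts every network with each requested
#' similarity index (exponent chosen per subject and model by a gamma scan
#' at the reference sparsity), and evaluates the predictions.
#'
#' @param n_subjects number of synthetic subjects.
#' @param config a [synthetic_config()]; its seed is overridden per subject
#'   from `seed`.
#' @param indices model indices to run (default all seven).
#' @param grid sparsity grid.
#' @param reference_sparsity sparsity for the gamma scan and degree fits.
#' @param distance_mode `"penalty"` or `"literal"` (see
#'   [prediction_scores()]).
#' @param criterion gamma-selection criterion (see [gamma_scan()]).
#' @param q FDR level.
#' @param seed master integer seed; all per-subject seeds derive from it.
#' @param full_evaluation when `FALSE`, skip the topology/energy evaluation
#'   and report gamma and prediction power only (fast).
#' @return an `evaluation_report` (with `per_subject`, `pp_by_sparsity`,
#'   and — when `full_evaluation` — the full group-statistics surface).
#' @export
run_study <- function(n_subjects = 20L, config = synthetic_config(),
                      indices = similarity_indices(),
                      grid = sparsity_grid(), reference_sparsity = 0.15,
                      distance_mode = "penalty",
                      criterion = "prediction_power", q = 0.05, seed = 1L,
                      full_evaluation = TRUE) {
  seed <- as.integer(seed)
  coords <- generate_coordinates(config$n_regions, seed = seed)
  dist <- euclidean_distance_matrix(coords)
  ref_i <- which.min(abs(grid - reference_sparsity))

  real_networks <- vector("list", n_subjects)
  predictions <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    sseed <- (seed + s * 1009L) %% .Machine$integer.max
    cfg <- config
    cfg$seed <- sseed
    truth <- generate_spatial_modular_network(coords, cfg)
    cfg$seed <- sseed + 1L
    ts <- generate_time_series(truth, cfg)
    corr <- pearson_correlation_matrix(ts)
    real_networks[[s]] <- lapply(grid, function(sp) {
      threshold_by_sparsity(corr, sp, tie_seed = sseed + 2L)
    })
    predictions[[s]] <- lapply(stats::setNames(indices, indices),
                               function(idx) {
      scan <- gamma_scan(real_networks[[s]][[ref_i]], dist, idx,
                         criterion = criterion,
                         distance_mode = distance_mode,
                         tie_seed = sseed + 3L)
      nets <- lapply(real_networks[[s]], function(real) {
        predict_network(real, dist, idx, scan$best_gamma,
                        distance_mode = distance_mode,
                        tie_seed = sseed + 3L)
      })
      list(networks = nets, gamma = scan$best_gamma)
    })
  }

  if (!full_evaluation) {
    rows <- list(); pp_rows <- list()
    for (s in seq_len(n_subjects)) {
      for (idx in indices) {
        pred <- predictions[[s]][[idx]]
        pp <- vapply(seq_along(grid), function(g) {
          prediction_power(pred$networks[[g]], real_networks[[s]][[g]])
        }, numeric(1))
        pp_rows[[length(pp_rows) + 1L]] <- data.frame(
          subject = s, index = idx, sparsity = grid, power_db = pp)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = s, index = idx, gamma = pred$gamma,
          energy = NA_real_, prediction_power = mean(pp))
      }
    }
    return(structure(list(per_subject = do.call(rbind, rows),
                          pp_by_sparsity = do.call(rbind, pp_rows),
                          settings = list(grid = grid, seed = seed,
                                          indices = indices)),
                     class = "evaluation_report"))
  }
  evaluate_models(real_networks, predictions, grid = grid,
                  reference_sparsity = reference_sparsity, q = q,
                  seed = seed)
}

#' Serialise an evaluation report to JSON
#'
#' @param report an `evaluation_report`.
#' @param path output path (`NULL` returns the JSON string).
#' @return the path, or the JSON string when `path` is `NULL`.
#' @export
report_to_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), dataframe = "columns",
                         auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  path
}
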