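# Simulation studies validating the pipeline's statistical properties:
# type-I calibration of the interaction classifier, power to recover
# injected distance-proportional synergy, best-null-model recovery, and
# recovery of number-of-factors / dissimilarity effects in the hierarchy.
# These run the same exported primitives as a real analysis, at problem
# sizes chosen for repeated simulation (documented in the vignette).

#' Type-I calibration of the interaction classifier
#'
#' Repeatedly generates experiments under a pure null world (no injected
#' interaction), classifies every multi-factor treatment under the
#' matching null model and tallies label frequencies. With the classifier
#' calibrated, "none" should appear at roughly the confidence level and
#' the synergistic/antagonistic remainder should split symmetrically.
#'
#' Group sizes mirror the reference design (20 controls, 8 replicates per
#' single factor); the multi-factor observed mean uses `multi_reps`
#' replicates so that its own sampling noise is negligible (under 1% of
#' the narrowest null prediction variance, reached around 400 replicates
#' for a two-factor treatment), isolating the calibration of the null
#' interval itself from observation noise.
#'
#' @param world Generating combination rule, `"additive"`,
#'   `"multiplicative"` or `"dominative"`.
#' @param n_rep Number of simulated experiments.
#' @param n_per_level Combinations drawn per level (levels 2, 5, 8).
#' @param multi_reps Replicates per multi-factor treatment.
#' @param sigma Unit noise standard deviation.
#' @param effect_sd Spread of true single-factor effects.
#' @param K Null-model bootstrap iterations.
#' @param ci_level Confidence level of the null interval.
#' @param seed Master seed.
#' @return List with `freq` (named label frequencies over all
#'   treatment-by-replicate cases), `by_level` (frequency matrix) and
#'   `n_cases`.
#' @export
null_calibration <- function(world = "additive", n_rep = 500,
                             n_per_level = 10, multi_reps = 400,
                             sigma = 1, effect_sd = 2, K = 1000,
                             ci_level = 0.95, seed = 1) {
  pool <- gcf_factors()
  labels <- c(); levels_out <- c()
  for (r in seq_len(n_rep)) {
    rs <- stage_seed(seed, paste0("calib_", world), r)
    design <- sample_design(
      pool, levels = c(2, 5, 8), n_per_level = n_per_level,
      replicate_plan = c(control = 20, water_control = 0, single = 8,
                         multi = multi_reps),
      seed = stage_seed(rs, "design"))
    truth <- make_ground_truth(
      pool, responses = "y", control_mean = 10, control_sd = sigma,
      effect_sd = effect_sd, world = world,
      directions = c(y = "positive"), seed = stage_seed(rs, "truth"))
    resp <- simulate_experiment(truth, design,
                                seed = stage_seed(rs, "sim"))
    np <- null_predictions(design, resp, models = world, K = K,
                           ci_level = ci_level,
                           seed = stage_seed(rs, "null"),
                           kinds = "multi")
    calls <- interaction_calls(np, resp, design, c(y = "positive"))
    labels <- c(labels, calls$label)
    levels_out <- c(levels_out, calls$level)
  }
  lv <- factor(labels, c("none", "synergistic", "antagonistic"))
  list(freq = table(lv) / length(lv),
       by_level = prop.table(table(lv, levels_out), margin = 2),
       n_cases = length(lv))
}

#' Power to recover injected distance-proportional synergy
#'
#' Generates experiments whose multi-factor treatments carry an injected
#' synergistic interaction proportional to the true pairwise factor
#' distances, then runs the full estimation path (bootstrap effect sizes,
#' estimated factor distances, dissimilarity indices, null predictions
#' under the generating additive rule, classification) and records, per
#' replicate, the fraction of treatments labeled synergistic and the
#' Spearman correlation between the rescaled deviation and the
#' normalized dissimilarity index.
#'
#' `gamma` defaults to `3 * sigma` divided by the mean off-diagonal true
#' factor distance, i.e. the average pairwise interaction term equals
#' three unit-noise standard deviations — three standard errors of a
#' single-replicate joint observation, the reference design's replication
#' of a multi-factor treatment.
#'
#' @param n_rep Number of simulated experiments.
#' @param n_per_level Combinations per level (levels 2, 5, 8).
#' @param multi_reps Replicates per multi-factor treatment.
#' @param sigma,effect_sd Unit noise and effect spread.
#' @param gamma Interaction magnitude per unit distance; `NULL` for the
#'   default calibration above.
#' @param B Effect-size bootstrap resamples (distance estimation).
#' @param K Null-model bootstrap iterations.
#' @param seed Master seed.
#' @return `data.frame`, one row per replicate: `frac_synergistic`,
#'   `frac_none`, the pooled correlation `rho` with its `p`, and the
#'   within-level summaries `rho_level_min` and `p_level_max` (worst
#'   level). The within-level statistics are the cleaner readout here:
#'   with distance-proportional injection the deviation scale grows with
#'   the number of pairs, so pooled rank correlations are diluted by
#'   between-level differences that the within-level correlations are
#'   immune to.
#' @export
interaction_recovery <- function(n_rep = 100, n_per_level = 50,
                                 multi_reps = 8, sigma = 1,
                                 effect_sd = 2, gamma = NULL, B = 500,
                                 K = 1000, seed = 1) {
  pool <- gcf_factors()
  responses <- gcf_responses()
  out <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    rs <- stage_seed(seed, "recov", r)
    em <- with_seed(stage_seed(rs, "em"),
                    matrix(rnorm(length(pool) * length(responses),
                                 0, effect_sd),
                           length(pool), length(responses),
                           dimnames = list(pool, responses)))
    d_true <- distance_matrix(standardize_effects(em))
    g <- gamma %||% (3 * sigma / mean(d_true[upper.tri(d_true)]))
    truth <- make_ground_truth(
      pool, responses, control_mean = 10, control_sd = sigma,
      effect_matrix = em, world = "additive",
      interaction = interaction_distance(g, sign = 1),
      directions = stats::setNames(rep("positive", length(responses)),
                                   responses))
    design <- sample_design(
      pool, levels = c(2, 5, 8), n_per_level = n_per_level,
      replicate_plan = c(control = 20, water_control = 0, single = 8,
                         multi = multi_reps),
      seed = stage_seed(rs, "design"))
    resp <- simulate_experiment(truth, design, seed = stage_seed(rs, "sim"))
    eff <- effects_table(design, resp, B = B,
                         seed = stage_seed(rs, "eff"), kinds = "single")
    dm <- distance_matrix(standardize_effects(
      single_effect_matrix(eff, design)))
    di <- di_table(design, dm)
    focal <- responses[1L]
    resp1 <- resp[resp$response == focal, ]
    np <- null_predictions(design, resp1, models = "additive", K = K,
                           seed = stage_seed(rs, "null"), kinds = "multi")
    calls <- interaction_calls(np, resp1, design,
                               stats::setNames("positive", focal))
    cr <- dn_vs_di_correlation(calls, di)
    cl <- dn_vs_di_correlation(calls, di, by_level = TRUE)
    out[[r]] <- data.frame(
      frac_synergistic = mean(calls$label == "synergistic"),
      frac_none = mean(calls$label == "none"),
      rho = cr$rho[1], p = cr$p[1],
      rho_level_min = min(cl$rho), p_level_max = max(cl$p))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Recovery of the generating null model by SSD selection
#'
#' Simulates low-noise experiments under each combination rule in turn,
#' computes bootstrap predictions under all three null models and checks
#' whether the smallest sum of squared deviations selects the generating
#' world.
#'
#' @param n_rep Number of simulated experiments (worlds cycle).
#' @param n_per_level Combinations per level (levels 2, 5, 8).
#' @param multi_reps Replicates per multi-factor treatment.
#' @param sigma Unit noise (small by construction of the study).
#' @param effect_sd Effect spread; sizable relative to the control mean
#'   of 10 so the additive and multiplicative rules separate.
#' @param K Null-model bootstrap iterations.
#' @param seed Master seed.
#' @return `data.frame`, one row per replicate: `world`, `selected`,
#'   `hit`.
#' @export
best_null_recovery <- function(n_rep = 99, n_per_level = 10,
                               multi_reps = 4, sigma = 0.1,
                               effect_sd = 2, K = 500, seed = 1) {
  pool <- gcf_factors()
  worlds <- c("additive", "multiplicative", "dominative")
  out <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    world <- worlds[(r - 1L) %% 3L + 1L]
    rs <- stage_seed(seed, "bestnull", r)
    truth <- make_ground_truth(
      pool, responses = "y", control_mean = 10, control_sd = sigma,
      effect_sd = effect_sd, world = world,
      directions = c(y = "positive"), seed = stage_seed(rs, "truth"))
    design <- sample_design(
      pool, levels = c(2, 5, 8), n_per_level = n_per_level,
      replicate_plan = c(control = 20, water_control = 0, single = 8,
                         multi = multi_reps),
      seed = stage_seed(rs, "design"))
    resp <- simulate_experiment(truth, design, seed = stage_seed(rs, "sim"))
    np <- null_predictions(design, resp, K = K,
                           seed = stage_seed(rs, "null"), kinds = "multi")
    calls <- interaction_calls(np, resp, design, c(y = "positive"))
    best <- select_best_null(calls)
    sel <- best$model[best$is_best]
    out[[r]] <- data.frame(world = world, selected = sel,
                           hit = sel == world, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Recovery of number-of-factors and dissimilarity effects
#'
#' Simulates additive-world experiments and, depending on `effect`, adds
#' to every multi-factor unit a term `beta * n_factors` (a joint-stress
#' surcharge growing with the number of co-acting factors), a term
#' `beta * di_norm`, or nothing. It then runs the estimation path and the
#' GLM hierarchy and reports, per replicate, the R-squared increment, AIC
#' difference and nested ANOVA p-value of the comparison targeting the
#' injected effect (Model 4 vs 1 for `n_factors`, Model 5 vs 1 for
#' `di_norm`; both reported for `"none"`).
#'
#' @param effect `"n_factors"`, `"di_norm"` or `"none"`.
#' @param beta Injected coefficient (response units per predictor unit).
#' @param n_rep Number of simulated experiments.
#' @param n_per_level Combinations per level (levels 2, 5, 8).
#' @param sigma,effect_sd Unit noise and effect spread.
#' @param B,K Bootstrap depths for effect sizes and null predictions.
#' @param importance Also compute forest permutation-importance p-values
#'   for `n_factors` and `di_norm` (`n_perm` permutations each)?
#' @param n_perm,num_trees Permutation-importance settings.
#' @param seed Master seed.
#' @return `data.frame`, one row per replicate, with columns
#'   `delta_r2_m4`, `aic_diff_m4`, `p_m4`, `delta_r2_m5`, `aic_diff_m5`,
#'   `p_m5` (and, with `importance = TRUE`, `p_imp_n_factors`,
#'   `p_imp_di_norm`).
#' @export
hierarchy_recovery <- function(effect = c("n_factors", "di_norm", "none"),
                               beta = NULL, n_rep = 20, n_per_level = 15,
                               sigma = 1, effect_sd = 2, B = 500,
                               K = 300, importance = FALSE, n_perm = 199,
                               num_trees = 150, seed = 1) {
  effect <- match.arg(effect)
  beta <- beta %||% switch(effect, n_factors = 1, di_norm = 3, none = 0)
  pool <- gcf_factors()
  out <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    rs <- stage_seed(seed, paste0("hier_", effect), r)
    truth <- make_ground_truth(
      pool, responses = c("y", "z"), control_mean = 10,
      control_sd = sigma, effect_sd = effect_sd, world = "additive",
      directions = c(y = "positive", z = "positive"),
      seed = stage_seed(rs, "truth"))
    design <- sample_design(
      pool, levels = c(2, 5, 8), n_per_level = n_per_level,
      replicate_plan = c(control = 20, water_control = 0, single = 8,
                         multi = 1),
      seed = stage_seed(rs, "design"))
    resp <- simulate_experiment(truth, design, seed = stage_seed(rs, "sim"))
    eff <- effects_table(design, resp, B = B, seed = stage_seed(rs, "eff"),
                         kinds = "single")
    dm <- distance_matrix(standardize_effects(
      single_effect_matrix(eff, design)))
    di <- di_table(design, dm)
    # inject the target effect into the multi-factor units of response y
    multi_ids <- design$treatment_id[design$kind == "multi"]
    sel <- resp$response == "y" & resp$treatment_id %in% multi_ids
    if (effect == "n_factors") {
      lev <- design$level[match(resp$treatment_id, design$treatment_id)]
      resp$value[sel] <- resp$value[sel] + beta * lev[sel]
    } else if (effect == "di_norm") {
      dn <- stats::setNames(di$di_norm, di$treatment_id)
      resp$value[sel] <- resp$value[sel] + beta * dn[resp$treatment_id[sel]]
    }
    np <- null_predictions(design, resp[resp$response == "y", ], K = K,
                           seed = stage_seed(rs, "null"))
    features <- build_feature_table(design, resp[resp$response == "y", ],
                                    np, di, pool)
    fit <- fit_hierarchy(features, "y", backend = "glm")
    cmp <- fit$comparisons
    row <- data.frame(
      delta_r2_m4 = cmp$delta_r2[cmp$model == "model4"],
      aic_diff_m4 = cmp$aic_diff[cmp$model == "model4"],
      p_m4 = cmp$anova_p[cmp$model == "model4"],
      delta_r2_m5 = cmp$delta_r2[cmp$model == "model5"],
      aic_diff_m5 = cmp$aic_diff[cmp$model == "model5"],
      p_m5 = cmp$anova_p[cmp$model == "model5"])
    if (importance) {
      pi <- permutation_importance(features, "y", n_perm = n_perm,
                                   num_trees = num_trees,
                                   seed = stage_seed(rs, "imp"))
      row$p_imp_n_factors <- pi$p_raw[pi$predictor == "n_factors"]
      row$p_imp_di_norm <- pi$p_raw[pi$predictor == "di_norm"]
    }
    out[[r]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
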