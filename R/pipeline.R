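#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis: the factor pool and
#' response set, the design shape (levels, combinations per level,
#' replicate plan), the bootstrap depths (`B` effect-size resamples, `K`
#' null-model iterations, `n_perm` importance permutations), the
#' confidence level and the response directions. Defaults mirror the
#' reference microcosm configuration: 12 factors, levels 2/5/8 with 50
#' combinations each, 20 controls, 10 water controls, 8 replicates per
#' single factor, `B = 10000`, `K = 1000`, `n_perm = 1000`,
#' `ci_level = 0.95`.
#'
#' @param factors,responses Factor pool and response names.
#' @param directions Named response directions.
#' @param levels,n_per_level,replicate_plan Design shape, see
#'   [sample_design()].
#' @param B,K,n_perm Bootstrap and permutation depths.
#' @param ci_level Confidence level in (0, 1).
#' @param backend Hierarchy backend, `"glm"` or `"forest"`.
#' @param num_trees Trees per forest.
#' @return List of class `gcf_config`.
#' @export
pipeline_config <- function(factors = gcf_factors(),
                            responses = gcf_responses(),
                            directions = gcf_directions(responses),
                            levels = c(2, 5, 8),
                            n_per_level = 50,
                            replicate_plan = c(control = 20,
                                               water_control = 10,
                                               single = 8, multi = 1),
                            B = 10000, K = 1000, n_perm = 1000,
                            ci_level = 0.95,
                            backend = c("glm", "forest"),
                            num_trees = 500) {
  validate_pool(factors)
  backend <- match.arg(backend)
  for (d in c("B", "K", "n_perm"))
    check_count(get(d), d)
  stopifnot(ci_level > 0, ci_level < 1)
  miss <- setdiff(responses, names(directions))
  if (length(miss))
    stop("no direction declared for response(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(directions[responses] %in% c("positive", "negative")))
    stop("directions must be 'positive' or 'negative'", call. = FALSE)
  structure(list(factors = factors, responses = responses,
                 directions = directions[responses], levels = levels,
                 n_per_level = n_per_level,
                 replicate_plan = replicate_plan, B = B, K = K,
                 n_perm = n_perm, ci_level = ci_level, backend = backend,
                 num_trees = num_trees),
            class = "gcf_config")
}

#' Run the full analysis pipeline
#'
#' Chains design sampling, (optional) synthetic data generation, bootstrap
#' effect sizes, factor dissimilarity, null-model predictions, net
#' interaction classification, best-null selection, per-level deviation
#' tests, within-level Spearman trends and the hierarchical model fits.
#' Every stochastic stage uses an independent seed stream derived from
#' `seed` by stable hashing of the stage name, so changing one stage's
#' depth never perturbs another stage's draws and identical
#' config + seed give identical manifests.
#'
#' @param config A [pipeline_config()].
#' @param responses Optional long-format response table; when omitted a
#'   synthetic experiment is generated from `truth` (or a default ground
#'   truth).
#' @param truth Optional [make_ground_truth()] object used when
#'   `responses` is omitted.
#' @param seed Master integer seed.
#' @param out_dir Optional directory; when given, stage outputs are
#'   written there as CSV (and the dendrogram as Newick).
#' @return List with all stage artifacts (`design`, `responses`,
#'   `effects`, `effect_matrix`, `dist`, `di`, `pcoa`, `clustering`,
#'   `newick`, `nullpred`, `calls`, `best_null`, `level_tests`,
#'   `dn_di_correlation`, `trend`, `features`, `hierarchy`) and a
#'   `manifest` recording seeds, depths and row counts.
#' @export
run_pipeline <- function(config = pipeline_config(), responses = NULL,
                         truth = NULL, seed = 1, out_dir = NULL) {
  stopifnot(inherits(config, "gcf_config"))
  design <- sample_design(config$factors, config$levels,
                          config$n_per_level, config$replicate_plan,
                          seed = stage_seed(seed, "design"))
  if (is.null(responses)) {
    truth <- truth %||% make_ground_truth(
      config$factors, config$responses,
      effect_mean = ifelse(config$directions == "negative", -1, 1),
      directions = config$directions,
      seed = stage_seed(seed, "truth"))
    responses <- simulate_experiment(truth, design,
                                     seed = stage_seed(seed, "simulate"))
  } else {
    validate_responses(responses, design)
  }
  effects <- effects_table(design, responses, B = config$B,
                           ci_level = config$ci_level,
                           seed = stage_seed(seed, "effects"))
  em <- single_effect_matrix(effects, design)
  dm <- distance_matrix(standardize_effects(em))
  di <- di_table(design, dm)
  ord <- pcoa(dm)
  hc <- hierarchical_cluster(dm)
  nullpred <- null_predictions(design, responses, K = config$K,
                               ci_level = config$ci_level,
                               seed = stage_seed(seed, "nullpred"))
  calls <- interaction_calls(nullpred, responses, design,
                             config$directions)
  best <- select_best_null(calls)
  best_calls <- merge(calls, best[best$is_best,
                                  c("response", "model")])
  level_tests <- deviation_group_tests(best_calls)
  dn_di <- dn_vs_di_correlation(best_calls, di)
  trend <- spearman_trend(responses, di)
  features <- build_feature_table(design, responses, nullpred, di,
                                  config$factors)
  hier <- lapply(config$responses, function(rn)
    fit_hierarchy(features, rn, backend = config$backend,
                  seed = stage_seed(seed, "hierarchy"),
                  num_trees = config$num_trees))
  names(hier) <- config$responses

  manifest <- list(
    seed = seed,
    depths = c(B = config$B, K = config$K, n_perm = config$n_perm),
    ci_level = config$ci_level,
    n_treatments = nrow(design),
    total_units = design_summary(design)$total_units,
    rows = c(responses = nrow(responses), effects = nrow(effects),
             nullpred = nrow(nullpred), calls = nrow(calls),
             features = nrow(features)),
    fingerprint = c(
      responses = round(sum(responses$value), 6),
      effects = round(sum(effects$effect), 6),
      dn = round(sum(calls$dn), 6)))

  out <- list(design = design, truth = truth, responses = responses,
              effects = effects, effect_matrix = em, dist = dm, di = di,
              pcoa = ord, clustering = hc, newick = cluster_newick(hc),
              nullpred = nullpred, calls = calls, best_null = best,
              level_tests = level_tests, dn_di_correlation = dn_di,
              trend = trend, features = features, hierarchy = hier,
              manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_design_csv(design, file.path(out_dir, "design.csv"))
    write_responses_csv(responses, file.path(out_dir, "responses.csv"))
    write.csv(effects, file.path(out_dir, "effects.csv"),
              row.names = FALSE)
    write_distance_csv(dm, file.path(out_dir, "distance.csv"))
    write.csv(di, file.path(out_dir, "di.csv"), row.names = FALSE)
    write.csv(nullpred, file.path(out_dir, "nullpred.csv"),
              row.names = FALSE)
    write.csv(calls, file.path(out_dir, "calls.csv"), row.names = FALSE)
    write.csv(trend, file.path(out_dir, "trend.csv"), row.names = FALSE)
    writeLines(out$newick, file.path(out_dir, "factors.nwk"))
  }
  out
}
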