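#' Feature table for the hierarchical modeling framework
#'
#' One row per non-control experimental unit and response, carrying the
#' unit's response value and the predictors of the seven-model hierarchy:
#' the three null-model predictions (`null_additive`,
#' `null_multiplicative`, `null_dominative`, joined verbatim from
#' [null_predictions()]), the number of factors, the normalized
#' dissimilarity index (`0` for single-factor treatments, which have no
#' factor pairs) and the binary factor-composition columns
#' (`comp_<factor>`, in pool order).
#'
#' @param design Design table.
#' @param responses Long-format response table.
#' @param nullpred Output of [null_predictions()] covering all three
#'   models for every single- and multi-factor treatment.
#' @param indices Dissimilarity table from [di_table()].
#' @param pool Factor pool (declaration order fixes the composition
#'   column order).
#' @return `data.frame` with columns `unit_id`, `treatment_id`,
#'   `response`, `value`, `null_additive`, `null_multiplicative`,
#'   `null_dominative`, `n_factors`, `di_norm`, `comp_*`.
#' @export
build_feature_table <- function(design, responses, nullpred, indices,
                                pool = NULL) {
  validate_design(design)
  validate_responses(responses, design)
  keep <- design$kind %in% c("single", "multi")
  trts <- design[keep, ]
  if (is.null(pool))
    pool <- unique(unlist(design_members(trts[trts$kind == "single", ])))
  orphan <- setdiff(trts$treatment_id, unique(nullpred$treatment_id))
  if (length(orphan))
    stop("null predictions missing for treatment(s): ",
         paste(orphan, collapse = ", "), call. = FALSE)

  units <- responses[responses$treatment_id %in% trts$treatment_id, ]
  units$n_factors <- trts$level[match(units$treatment_id,
                                      trts$treatment_id)]
  di <- stats::setNames(indices$di_norm, indices$treatment_id)
  units$di_norm <- ifelse(units$treatment_id %in% names(di),
                          di[units$treatment_id], 0)
  for (mo in c("additive", "multiplicative", "dominative")) {
    np <- nullpred[nullpred$model == mo, ]
    key <- paste(np$treatment_id, np$response)
    v <- stats::setNames(np$pred_mean, key)
    units[[paste0("null_", mo)]] <-
      as.numeric(v[paste(units$treatment_id, units$response)])
  }
  if (anyNA(units[, c("null_additive", "null_multiplicative",
                      "null_dominative")]))
    stop("null predictions incomplete for some treatment x response",
         call. = FALSE)
  members <- design_members(trts)
  comp <- vapply(pool, function(f)
    vapply(members, function(mm) as.numeric(f %in% mm), numeric(1)),
    numeric(nrow(trts)))
  comp <- comp[match(units$treatment_id, trts$treatment_id), , drop = FALSE]
  colnames(comp) <- paste0("comp_", pool)
  out <- cbind(units[, c("unit_id", "treatment_id", "response", "value",
                         "null_additive", "null_multiplicative",
                         "null_dominative", "n_factors", "di_norm")],
               comp)
  rownames(out) <- NULL
  out
}

#' Predictor sets of the seven hierarchical models
#'
#' Model 1 (baseline, factor identity): the three null-model predictions.
#' Model 2: number of factors alone. Model 3: dissimilarity alone.
#' Models 4/5: baseline plus number of factors / plus dissimilarity.
#' Model 6: baseline plus both. Model 7: Model 6 plus the binary factor
#' composition.
#'
#' @param features A feature table (used for the composition column
#'   names).
#' @return Named list of 7 character vectors of predictor columns.
#' @export
hierarchy_model_specs <- function(features) {
  nulls <- c("null_additive", "null_multiplicative", "null_dominative")
  comp <- grep("^comp_", names(features), value = TRUE)
  list(model1 = nulls,
       model2 = "n_factors",
       model3 = "di_norm",
       model4 = c(nulls, "n_factors"),
       model5 = c(nulls, "di_norm"),
       model6 = c(nulls, "n_factors", "di_norm"),
       model7 = c(nulls, "n_factors", "di_norm", comp))
}

# comparisons reported along the hierarchy
hierarchy_comparisons <- function() {
  data.frame(model = c("model4", "model5", "model6", "model7"),
             base = c("model1", "model1", "model1", "model6"),
             stringsAsFactors = FALSE)
}

#' Fit the seven-model hierarchy for one response
#'
#' Fits Models 1-7 for a single response with either a Gaussian
#' identity-link GLM or a random forest. The GLM reports in-sample
#' R-squared, AIC and nested ANOVA (F-test) p-values for the comparisons
#' 4 vs 1, 5 vs 1, 6 vs 1 and 7 vs 6; the forest reports the out-of-bag
#' R-squared (in-sample forest fits are optimistically biased) and the
#' same R-squared increments.
#'
#' @param features Feature table from [build_feature_table()].
#' @param response Which response to model.
#' @param backend `"glm"` or `"forest"`.
#' @param seed Integer seed (forest backend).
#' @param num_trees Trees per forest (default 500).
#' @param min_rows Minimum number of rows required (default 30).
#' @return List of class `gcf_hierarchy` with elements `response`,
#'   `backend`, `models` (per-model `r2` and `aic`), `comparisons`
#'   (`delta_r2`, `aic_diff`, `anova_p`) and `fits` (glm backend only).
#' @export
fit_hierarchy <- function(features, response, backend = c("glm", "forest"),
                          seed = 1, num_trees = 500, min_rows = 30) {
  backend <- match.arg(backend)
  dat <- features[features$response == response, ]
  if (nrow(dat) < min_rows)
    stop(sprintf("only %d rows for response '%s' (min_rows = %d)",
                 nrow(dat), response, min_rows), call. = FALSE)
  specs <- hierarchy_model_specs(features)
  fits <- vector("list", length(specs))
  names(fits) <- names(specs)
  r2 <- aic <- stats::setNames(rep(NA_real_, length(specs)), names(specs))
  for (mi in names(specs)) {
    x <- dat[, specs[[mi]], drop = FALSE]
    if (backend == "glm") {
      fit <- lm(dat$value ~ ., data = x)
      if (anyNA(coef(fit)))
        warning("rank-deficient design in ", mi,
                ": aliased columns dropped", call. = FALSE)
      fits[[mi]] <- fit
      r2[mi] <- summary(fit)$r.squared
      aic[mi] <- AIC(fit)
    } else {
      fit <- ranger::ranger(y = dat$value, x = x, num.trees = num_trees,
                            seed = stage_seed(seed, paste0("rf_", mi)))
      r2[mi] <- fit$r.squared
    }
  }
  cmp <- hierarchy_comparisons()
  cmp$delta_r2 <- r2[cmp$model] - r2[cmp$base]
  cmp$aic_diff <- if (backend == "glm") aic[cmp$model] - aic[cmp$base]
                  else NA_real_
  cmp$anova_p <- NA_real_
  if (backend == "glm") {
    for (i in seq_len(nrow(cmp))) {
      a <- anova(fits[[cmp$base[i]]], fits[[cmp$model[i]]])
      cmp$anova_p[i] <- a[["Pr(>F)"]][2]
    }
  }
  rownames(cmp) <- NULL
  structure(list(response = response, backend = backend,
                 models = data.frame(model = names(specs), r2 = unname(r2),
                                     aic = unname(aic),
                                     stringsAsFactors = FALSE),
                 comparisons = cmp,
                 fits = if (backend == "glm") fits else NULL),
            class = "gcf_hierarchy")
}

#' @export
print.gcf_hierarchy <- function(x, ...) {
  cat("Hierarchical model report (", x$backend, "), response: ",
      x$response, "\n", sep = "")
  print(x$models, row.names = FALSE)
  cat("comparisons:\n")
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' Permutation importance of hierarchy predictors
#'
#' Random-forest permutation importance with response-permutation
#' (Altmann-style) p-values: the observed importance of each predictor is
#' its mean out-of-bag loss increase under column permutation; the null
#' distribution is obtained by refitting the forest `n_perm` times with a
#' permuted response and recording the importances. Reported importances
#' are floored at zero; p-values are
#' `(1 + #(null >= observed)) / (1 + n_perm)`, Benjamini-Hochberg adjusted
#' across predictors.
#'
#' @param features Feature table from [build_feature_table()].
#' @param response Which response to model.
#' @param predictors Character vector of predictor columns (default:
#'   Model 6's set).
#' @param n_perm Number of response permutations (default 1000).
#' @param seed Integer seed.
#' @param num_trees Trees per forest (default 200; every permutation
#'   refits a forest).
#' @return `data.frame` with columns `predictor`, `importance`, `p_raw`,
#'   `p_adj`.
#' @export
permutation_importance <- function(features, response, predictors = NULL,
                                   n_perm = 1000, seed = 1,
                                   num_trees = 200) {
  n_perm <- check_count(n_perm, "n_perm")
  dat <- features[features$response == response, ]
  predictors <- predictors %||% hierarchy_model_specs(features)$model6
  x <- dat[, predictors, drop = FALSE]
  imp_of <- function(y, s)
    ranger::ranger(y = y, x = x, num.trees = num_trees,
                   importance = "permutation",
                   seed = s)$variable.importance
  obs <- imp_of(dat$value, stage_seed(seed, "pi_obs"))
  null_ge <- rep(0L, length(obs))
  perm <- with_seed(stage_seed(seed, "pi_perm"), {
    counts <- null_ge
    for (b in seq_len(n_perm)) {
      ib <- imp_of(sample(dat$value), stage_seed(seed, "pi_fit", b))
      counts <- counts + (ib >= obs)
    }
    counts
  })
  p <- (1 + perm) / (1 + n_perm)
  data.frame(predictor = names(obs),
             importance = pmax(unname(obs), 0),
             p_raw = unname(p),
             p_adj = adjust_pvalues_bh(unname(p)),
             stringsAsFactors = FALSE)
}
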