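#' Rescaled deviation from a null prediction
#'
#' Standardized, dimensionless deviation of an observed joint response
#' from a bootstrap null-prediction distribution:
#' `(observed - mean(draws)) / sd(draws)`. The z-like scaling makes
#' deviations comparable across responses with different units.
#'
#' @param observed Observed joint response (treatment group mean).
#' @param pred_mean,pred_sd Mean and standard deviation of the prediction
#'   distribution. A zero spread is an error unless the observation
#'   equals the mean (then the deviation is 0).
#' @return The rescaled deviation `DN`.
#' @export
rescaled_deviation <- function(observed, pred_mean, pred_sd) {
  stopifnot(is.finite(observed), is.finite(pred_mean), pred_sd >= 0)
  if (pred_sd == 0) {
    if (observed == pred_mean) return(0)
    stop("prediction distribution has zero spread", call. = FALSE)
  }
  (observed - pred_mean) / pred_sd
}

#' Classify the net interaction of one observation
#'
#' Observations inside the 95% interval of the null prediction
#' distribution are "none". Outside the interval the label depends on the
#' response's direction: for positive-direction responses a deviation
#' above the null (`DN > 0`) is synergistic and below antagonistic; for
#' negative-direction responses (decomposition rate, WSA) the rule is
#' mirrored, `DN < 0` is synergistic.
#'
#' @param observed Observed joint response.
#' @param ci_low,ci_high Percentile bounds of the prediction distribution.
#' @param dn Rescaled deviation from [rescaled_deviation()].
#' @param direction `"positive"` or `"negative"`.
#' @return `"synergistic"`, `"antagonistic"` or `"none"`.
#' @export
classify_interaction <- function(observed, ci_low, ci_high, dn, direction) {
  if (!direction %in% c("positive", "negative"))
    stop("direction must be 'positive' or 'negative'", call. = FALSE)
  if (observed >= ci_low && observed <= ci_high) return("none")
  up <- dn > 0
  if (direction == "negative") up <- !up
  if (up) "synergistic" else "antagonistic"
}

#' Interaction calls for all multi-factor treatments
#'
#' Joins the observed treatment group means with the null prediction table
#' and classifies every multi-factor treatment x response x model as
#' synergistic, antagonistic or no net interaction.
#'
#' @param nullpred Output of [null_predictions()].
#' @param responses Long-format response table.
#' @param design Design table.
#' @param directions Named character vector of response directions;
#'   defaults to [gcf_directions()] over the responses present.
#' @return `data.frame` with columns `treatment_id`, `response`, `model`,
#'   `level`, `observed`, `pred_mean`, `pred_sd`, `ci_low`, `ci_high`,
#'   `dn`, `label`, `direction`.
#' @export
interaction_calls <- function(nullpred, responses, design,
                              directions = NULL) {
  validate_design(design)
  validate_responses(responses, design)
  multi_ids <- design$treatment_id[design$kind == "multi"]
  np <- nullpred[nullpred$treatment_id %in% multi_ids, ]
  if (nrow(np) == 0L)
    stop("null prediction table has no multi-factor treatments",
         call. = FALSE)
  resp_names <- unique(np$response)
  directions <- directions %||% gcf_directions(resp_names)
  miss <- setdiff(resp_names, names(directions))
  if (length(miss))
    stop("no direction declared for response(s): ",
         paste(miss, collapse = ", "), call. = FALSE)

  obs_key <- paste(responses$treatment_id, responses$response)
  obs <- tapply(responses$value, obs_key, mean)
  np$observed <- as.numeric(obs[paste(np$treatment_id, np$response)])
  if (anyNA(np$observed))
    stop("missing observed values for some treatment x response",
         call. = FALSE)
  np$dn <- mapply(rescaled_deviation, np$observed, np$pred_mean, np$pred_sd)
  np$direction <- unname(directions[np$response])
  np$label <- mapply(classify_interaction, np$observed, np$ci_low,
                     np$ci_high, np$dn, np$direction)
  rownames(np) <- NULL
  np
}

#' Select the best-fitting null model per response
#'
#' For each response, sums the squared deviations of the observed joint
#' responses from each null model's prediction means across all
#' multi-factor treatments; the model with the smallest sum (SSD) is the
#' best-fitting null. Ties break deterministically in the order additive,
#' multiplicative, dominative.
#'
#' @param calls Output of [interaction_calls()] containing all models.
#' @return `data.frame` with columns `response`, `model`, `ssd`,
#'   `is_best`.
#' @export
select_best_null <- function(calls) {
  model_order <- c("additive", "multiplicative", "dominative")
  models <- intersect(model_order, unique(calls$model))
  if (length(models) == 0L) stop("no null models in calls", call. = FALSE)
  out <- do.call(rbind, lapply(unique(calls$response), function(rn) {
    sub <- calls[calls$response == rn, ]
    ssd <- vapply(models, function(mo) {
      s <- sub[sub$model == mo, ]
      if (nrow(s) == 0L)
        stop("missing model '", mo, "' for response ", rn, call. = FALSE)
      sum((s$observed - s$pred_mean)^2)
    }, numeric(1))
    data.frame(response = rn, model = models, ssd = unname(ssd),
               is_best = seq_along(models) == which.min(ssd),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Per-level one-sample t-tests on rescaled deviations
#'
#' Tests, within each response and number-of-factors level, whether the
#' mean rescaled deviation differs from zero (two-sided one-sample t),
#' with Benjamini-Hochberg adjustment across all level x response tests.
#' Typically run on calls filtered to the best-fitting null model.
#'
#' @param calls Interaction calls (usually one model per response).
#' @return `data.frame` with columns `response`, `model`, `level`, `n`,
#'   `mean_dn`, `t`, `df`, `p_raw`, `p_adj`. Degenerate groups (fewer than
#'   two calls or zero variance) report `NA`.
#' @export
deviation_group_tests <- function(calls) {
  grp <- unique(calls[, c("response", "model", "level")])
  res <- do.call(rbind, lapply(seq_len(nrow(grp)), function(i) {
    sel <- calls$response == grp$response[i] &
      calls$model == grp$model[i] & calls$level == grp$level[i]
    dn <- calls$dn[sel]
    if (length(dn) >= 2L && sd(dn) == 0 && dn[1] == 0) {
      # all deviations exactly at the null: no evidence either way
      tt <- list(statistic = 0, parameter = length(dn) - 1, p.value = 1)
    } else if (length(dn) < 2L || sd(dn) == 0) {
      tt <- list(statistic = NA_real_, parameter = NA_real_,
                 p.value = NA_real_)
    } else {
      tt <- t.test(dn, mu = 0)
    }
    data.frame(response = grp$response[i], model = grp$model[i],
               level = grp$level[i], n = length(dn), mean_dn = mean(dn),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p_raw = tt$p.value, stringsAsFactors = FALSE)
  }))
  ok <- !is.na(res$p_raw)
  res$p_adj <- NA_real_
  res$p_adj[ok] <- adjust_pvalues_bh(res$p_raw[ok])
  rownames(res) <- NULL
  res
}

#' Spearman correlation of deviations against dissimilarity
#'
#' Rank correlation between the rescaled deviation from null prediction
#' and the normalized dissimilarity index across multi-factor treatments,
#' per response (optionally within each level). A positive correlation
#' indicates that more dissimilar factor combinations deviate further
#' from the null in the synergistic direction.
#'
#' @param calls Interaction calls (typically best model per response).
#' @param indices Dissimilarity table from [di_table()].
#' @param by_level Split the correlation by number-of-factors level?
#' @return `data.frame` with columns `response`, (`level`,) `rho`, `p`,
#'   `n`.
#' @export
dn_vs_di_correlation <- function(calls, indices, by_level = FALSE) {
  m <- merge(calls, indices[, c("treatment_id", "di_norm")],
             by = "treatment_id")
  split_cols <- if (by_level) c("response", "model", "level")
                else c("response", "model")
  grp <- unique(m[, split_cols, drop = FALSE])
  out <- do.call(rbind, lapply(seq_len(nrow(grp)), function(i) {
    sel <- rep(TRUE, nrow(m))
    for (cc in split_cols) sel <- sel & m[[cc]] == grp[[cc]][i]
    x <- m$dn[sel]; y <- m$di_norm[sel]
    if (length(x) < 3L)
      stop("fewer than 3 matched treatments for a correlation",
           call. = FALSE)
    ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                    exact = FALSE))
    cbind(grp[i, , drop = FALSE],
          data.frame(rho = unname(ct$estimate), p = ct$p.value,
                     n = length(x)))
  }))
  rownames(out) <- NULL
  out
}
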