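#' Null-model point predictions of joint multi-factor effects
#'
#' Predicted joint effect size of a factor combination from its members'
#' single-factor effect sizes, assuming no interaction:
#'
#' * additive — the joint effect is the sum of the single effects
#'   (factor sensitivities negatively correlated);
#' * multiplicative — effects combine as proportional changes of the
#'   control level `CT`: `CT * prod(1 + ES_i/CT) - CT` (sensitivities
#'   uncorrelated);
#' * dominative — the factor with the largest absolute effect overrides
#'   the others and the signed maximal-magnitude effect is returned
#'   (sensitivities positively correlated). Magnitude ties go to the
#'   first occurrence.
#'
#' All three rules coincide on a single factor.
#'
#' @param es_list Numeric vector of single-factor effect sizes (length
#'   >= 1).
#' @param ct Control response level; must be nonzero for the
#'   multiplicative rule. If some bracket `1 + ES_i/ct <= 0` the
#'   prediction flips sign relative to the control; this is allowed but
#'   flagged with a warning.
#' @return Predicted joint effect size (a single number).
#' @export
#' @examples
#' predict_additive(c(2, 3))            # 5
#' predict_multiplicative(c(2, 3), 10)  # 5.6
#' predict_dominative(c(2, -5, 1))      # -5
predict_additive <- function(es_list) {
  stopifnot(is.numeric(es_list), length(es_list) >= 1L)
  sum(es_list)
}

#' @rdname predict_additive
#' @export
predict_multiplicative <- function(es_list, ct) {
  stopifnot(is.numeric(es_list), length(es_list) >= 1L,
            is.numeric(ct), length(ct) == 1L)
  if (ct == 0)
    stop("multiplicative prediction undefined for a zero control level",
         call. = FALSE)
  brackets <- 1 + es_list / ct
  if (any(brackets <= 0))
    warning("bracket 1 + ES/CT <= 0: multiplicative prediction flips sign",
            call. = FALSE)
  ct * prod(brackets) - ct
}

#' @rdname predict_additive
#' @export
predict_dominative <- function(es_list) {
  stopifnot(is.numeric(es_list), length(es_list) >= 1L)
  es_list[which.max(abs(es_list))]
}

combine_effects <- function(es, model, ct) {
  switch(model,
         additive = predict_additive(es),
         multiplicative = predict_multiplicative(es, ct),
         dominative = predict_dominative(es),
         stop("unknown null model: ", model, call. = FALSE))
}

# Vectorized combination over a K-column matrix of per-member effect
# draws (rows = members); `ct` is the K-vector of control means.
combine_effects_matrix <- function(Z, model, ct) {
  switch(model,
         additive = .colSums(Z, nrow(Z), ncol(Z)),
         multiplicative = {
           out <- rep(1, ncol(Z))
           for (i in seq_len(nrow(Z))) out <- out * (1 + Z[i, ] / ct)
           ct * out - ct
         },
         dominative = {
           best <- Z[1L, ]
           if (nrow(Z) > 1L) for (i in 2:nrow(Z)) {
             swap <- abs(Z[i, ]) > abs(best)
             best[swap] <- Z[i, swap]
           }
           best
         },
         stop("unknown null model: ", model, call. = FALSE))
}

#' Bootstrap distribution of a null-model joint-response prediction
#'
#' Builds the prediction distribution of the joint response of one
#' multi-factor treatment under a null model. Each iteration resamples
#' the control group and every member's single-factor group with
#' replacement (the control resample is shared across members within an
#' iteration), computes the resampled group means, derives the signed
#' effect sizes `Z = mean(single*) - mean(control*)`, combines them under
#' the model (using the resampled control mean as `CT` for the
#' multiplicative rule) and adds the resampled control mean back to give
#' one predicted joint response. Iterations where a multiplicative
#' control mean is exactly zero are redrawn and counted.
#'
#' @param control_values Numeric vector of control replicates.
#' @param single_values List of numeric vectors, one per member factor.
#' @param model `"additive"`, `"multiplicative"` or `"dominative"`.
#' @param K Number of bootstrap iterations (default 1000).
#' @param ci_level Confidence level of the percentile interval.
#' @param seed Optional integer seed.
#' @return List with `model`, `draws` (length `K`), `mean`, `sd`,
#'   `ci_low`, `ci_high`, `n_draws` and `n_flagged` (redrawn iterations).
#' @export
bootstrap_null_distribution <- function(control_values, single_values,
                                        model = "additive", K = 1000,
                                        ci_level = 0.95, seed = NULL) {
  if (length(control_values) == 0L ||
      any(lengths(single_values) == 0L) || length(single_values) == 0L)
    stop("all groups must be non-empty", call. = FALSE)
  K <- check_count(K, "K")
  stopifnot(ci_level > 0, ci_level < 1)
  res <- with_seed(seed, {
    nc <- length(control_values)
    draw_block <- function(k) {
      ci <- .colMeans(sample(control_values, nc * k, replace = TRUE), nc, k)
      Z <- do.call(rbind, lapply(single_values, function(s) {
        ns <- length(s)
        .colMeans(sample(s, ns * k, replace = TRUE), ns, k) - ci
      }))
      list(ci = ci, Z = Z)
    }
    b <- draw_block(K)
    n_flagged <- 0L
    if (model == "multiplicative") {
      bad <- b$ci == 0
      tries <- 0L
      while (any(bad) && tries < 100L) {
        n_flagged <- n_flagged + sum(bad)
        nb <- draw_block(sum(bad))
        b$ci[bad] <- nb$ci
        b$Z[, bad] <- nb$Z
        bad <- b$ci == 0
        tries <- tries + 1L
      }
      if (any(bad))
        stop("control resamples keep producing a zero mean", call. = FALSE)
    }
    list(draws = b$ci + combine_effects_matrix(b$Z, model, b$ci),
         n_flagged = n_flagged)
  })
  alpha <- 1 - ci_level
  ci <- unname(quantile(res$draws, c(alpha / 2, 1 - alpha / 2)))
  list(model = model, draws = res$draws, mean = mean(res$draws),
       sd = sd(res$draws), ci_low = ci[1], ci_high = ci[2],
       n_draws = K, n_flagged = res$n_flagged)
}

#' Null-model prediction table for a design
#'
#' Runs [bootstrap_null_distribution()] for every single- and multi-factor
#' treatment, response and requested null model. The bootstrap seed is
#' derived per treatment and response but shared across models, so the
#' three models see identical resamples (and coincide exactly on
#' single-factor treatments).
#'
#' @param design Design table with a control group.
#' @param responses Long-format response table.
#' @param models Character vector of null models to evaluate.
#' @param K,ci_level,seed See [bootstrap_null_distribution()].
#' @param kinds Treatment kinds to predict for (default singles and
#'   multis).
#' @return `data.frame` with columns `treatment_id`, `response`, `model`,
#'   `level`, `pred_mean`, `pred_sd`, `ci_low`, `ci_high`, `n_draws`,
#'   `n_flagged`.
#' @export
null_predictions <- function(design, responses,
                             models = c("additive", "multiplicative",
                                        "dominative"),
                             K = 1000, ci_level = 0.95, seed = 1,
                             kinds = c("single", "multi")) {
  validate_design(design)
  validate_responses(responses, design)
  if (!any(design$kind == "control"))
    stop("design has no control group", call. = FALSE)
  target <- design[design$kind %in% kinds, ]
  members <- design_members(target)
  resp_names <- unique(responses$response)
  rows <- vector("list", nrow(target) * length(resp_names) * length(models))
  pos <- 0L
  for (rn in resp_names) {
    ctrl <- group_values(responses, "control", rn)
    if (length(ctrl) == 0L)
      stop("no control values for response ", rn, call. = FALSE)
    singles_cache <- new.env(parent = emptyenv())
    get_single <- function(f) {
      if (is.null(singles_cache[[f]])) {
        v <- group_values(responses, paste0("single_", f), rn)
        if (length(v) == 0L)
          stop("no single-factor values for ", f, " (response ", rn, ")",
               call. = FALSE)
        singles_cache[[f]] <- v
      }
      singles_cache[[f]]
    }
    for (i in seq_len(nrow(target))) {
      sv <- lapply(members[[i]], get_single)
      sd_i <- stage_seed(seed, paste0("null_", rn), i)
      for (mo in models) {
        bn <- bootstrap_null_distribution(ctrl, sv, model = mo, K = K,
                                          ci_level = ci_level, seed = sd_i)
        pos <- pos + 1L
        rows[[pos]] <- data.frame(
          treatment_id = target$treatment_id[i], response = rn, model = mo,
          level = target$level[i], pred_mean = bn$mean, pred_sd = bn$sd,
          ci_low = bn$ci_low, ci_high = bn$ci_high, n_draws = bn$n_draws,
          n_flagged = bn$n_flagged, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows[seq_len(pos)])
  rownames(out) <- NULL
  out
}
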