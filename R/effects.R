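#' Bootstrap effect size of a treatment group versus control
#'
#' Nonparametric bootstrap of the mean difference between one treatment
#' group and the control group. Each iteration resamples both groups
#' independently with replacement and records
#' `mean(treatment*) - mean(control*)`; the reported effect is the mean of
#' the bootstrap distribution, the confidence interval its percentile
#' bounds, and the two-sided p-value the sign-based bootstrap p
#' `2 * min(Pr(stat <= 0), Pr(stat >= 0))`, clipped to `[2/B, 1]`.
#'
#' @param treatment_values,control_values Non-empty numeric vectors.
#' @param B Number of bootstrap resamples (default 10000).
#' @param ci_level Confidence level in (0, 1), default 0.95.
#' @param seed Optional integer seed.
#' @return List with `effect`, `ci_low`, `ci_high`, `p_raw`, `B`.
#' @export
#' @examples
#' bootstrap_effect_size(rnorm(8, 2), rnorm(20), B = 1000, seed = 1)
bootstrap_effect_size <- function(treatment_values, control_values,
                                  B = 10000, ci_level = 0.95, seed = NULL) {
  if (length(treatment_values) == 0L || length(control_values) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  if (anyNA(treatment_values) || anyNA(control_values))
    stop("groups must not contain missing values", call. = FALSE)
  B <- check_count(B, "B")
  stopifnot(ci_level > 0, ci_level < 1)
  stats <- with_seed(seed, {
    nt <- length(treatment_values); nc <- length(control_values)
    tm <- .colMeans(sample(treatment_values, nt * B, replace = TRUE), nt, B)
    cm <- .colMeans(sample(control_values, nc * B, replace = TRUE), nc, B)
    tm - cm
  })
  alpha <- 1 - ci_level
  ci <- unname(quantile(stats, c(alpha / 2, 1 - alpha / 2)))
  p <- 2 * min(mean(stats <= 0), mean(stats >= 0))
  list(effect = mean(stats), ci_low = ci[1], ci_high = ci[2],
       p_raw = min(1, max(2 / B, p)), B = B)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment with monotonicity enforcement,
#' mapped back to the input order and clipped at 1.
#'
#' @param p_raw Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as the input.
#' @export
adjust_pvalues_bh <- function(p_raw) {
  if (!is.numeric(p_raw) || anyNA(p_raw) ||
      any(p_raw < 0) || any(p_raw > 1))
    stop("p-values must be numbers in [0, 1]", call. = FALSE)
  p.adjust(p_raw, method = "BH")
}

#' Effect sizes of all treatment groups versus control
#'
#' Runs [bootstrap_effect_size()] for every non-control treatment and
#' response, with Benjamini-Hochberg adjustment applied within each
#' response family across treatments. Water-control units are carried in
#' the design only as a solvent check and are excluded by default.
#'
#' @param design Design table with a `control` row.
#' @param responses Long-format response table.
#' @param B,ci_level,seed Passed to [bootstrap_effect_size()]; per-group
#'   seeds are derived deterministically from `seed`.
#' @param include_water_control Logical; include the solvent control as a
#'   treatment group?
#' @param kinds Treatment kinds to estimate (default singles and multis).
#' @return `data.frame` with columns `treatment_id`, `response`, `effect`,
#'   `ci_low`, `ci_high`, `p_raw`, `p_adj`.
#' @export
effects_table <- function(design, responses, B = 10000, ci_level = 0.95,
                          seed = 1, include_water_control = FALSE,
                          kinds = c("single", "multi")) {
  validate_design(design)
  validate_responses(responses, design)
  if (!any(design$kind == "control"))
    stop("design has no control group", call. = FALSE)
  keep <- design$kind %in% kinds |
    (include_water_control & design$kind == "water_control")
  trts <- design$treatment_id[keep]
  resp_names <- unique(responses$response)
  out <- vector("list", length(resp_names))
  for (r in seq_along(resp_names)) {
    rn <- resp_names[r]
    ctrl <- group_values(responses, "control", rn)
    if (length(ctrl) == 0L)
      stop("no control values for response ", rn, call. = FALSE)
    est <- lapply(seq_along(trts), function(i) {
      tv <- group_values(responses, trts[i], rn)
      if (length(tv) == 0L)
        stop("no values for treatment ", trts[i], ", response ", rn,
             call. = FALSE)
      bootstrap_effect_size(tv, ctrl, B = B, ci_level = ci_level,
                            seed = stage_seed(seed, paste0("es_", rn), i))
    })
    df <- data.frame(
      treatment_id = trts, response = rn,
      effect = vapply(est, `[[`, numeric(1), "effect"),
      ci_low = vapply(est, `[[`, numeric(1), "ci_low"),
      ci_high = vapply(est, `[[`, numeric(1), "ci_high"),
      p_raw = vapply(est, `[[`, numeric(1), "p_raw"),
      stringsAsFactors = FALSE)
    df$p_adj <- adjust_pvalues_bh(df$p_raw)
    out[[r]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Single-factor effect matrix
#'
#' Extracts the factors-by-responses matrix of single-factor effect sizes
#' from an effects table, the input to [standardize_effects()] and
#' [distance_matrix()].
#'
#' @param effects Output of [effects_table()].
#' @param design The matching design table.
#' @return Numeric matrix, rows = factors in pool order, columns =
#'   responses.
#' @export
single_effect_matrix <- function(effects, design) {
  validate_design(design)
  singles <- design[design$kind == "single", ]
  if (nrow(singles) == 0L)
    stop("design has no single-factor treatments", call. = FALSE)
  resp_names <- unique(effects$response)
  m <- matrix(NA_real_, nrow(singles), length(resp_names),
              dimnames = list(singles$factors, resp_names))
  for (i in seq_len(nrow(singles))) {
    sub <- effects[effects$treatment_id == singles$treatment_id[i], ]
    m[i, sub$response] <- sub$effect
  }
  if (anyNA(m))
    stop("effects table lacks estimates for some single factors",
         call. = FALSE)
  m
}
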