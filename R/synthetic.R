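#' Interaction rules for the synthetic generator
#'
#' Describe how pairwise interaction terms are injected on top of the
#' null-world combination rule when simulating multi-factor treatments.
#'
#' * `interaction_none()` — purely null world, no interaction;
#' * `interaction_fixed(gamma, sign)` — every unordered member pair of a
#'   combination contributes `sign * gamma`;
#' * `interaction_distance(gamma, sign)` — each pair `(i, j)` contributes
#'   `sign * gamma * d_ij`, where `d_ij` is the Euclidean distance between
#'   the factors' standardized true effect profiles. This emulates the
#'   hypothesis that more dissimilar factors interact more strongly.
#'
#' `sign` is `+1` or `-1`, scalar or one value per response; with `-1` the
#' injected interaction pushes against the response's positive direction.
#'
#' @param gamma Nonnegative interaction magnitude.
#' @param sign `+1` or `-1`, recycled over responses.
#' @return List describing the rule, for [make_ground_truth()].
#' @export
interaction_none <- function() list(type = "none")

#' @rdname interaction_none
#' @export
interaction_fixed <- function(gamma, sign = 1) {
  stopifnot(is.numeric(gamma), gamma >= 0, all(abs(sign) == 1))
  list(type = "fixed", gamma = gamma, sign = sign)
}

#' @rdname interaction_none
#' @export
interaction_distance <- function(gamma, sign = 1) {
  stopifnot(is.numeric(gamma), gamma >= 0, all(abs(sign) == 1))
  list(type = "distance_proportional", gamma = gamma, sign = sign)
}

#' Ground truth for a synthetic multi-factor experiment
#'
#' Assembles the generative model that [simulate_experiment()] draws from:
#' control means and unit noise per response, a factors-by-responses matrix
#' of true single-factor effects, the combination rule ("world") that joint
#' effects follow in the absence of interaction, and an optional injected
#' interaction rule.
#'
#' If `effect_matrix` is not supplied, effects are drawn independently as
#' `N(effect_mean[r], effect_sd[r]^2)` per response `r`; passing
#' `effect_mean` aligned with the response directions (negative means for
#' negative-direction responses) exercises the direction-dependent branch
#' of the interaction classifier.
#'
#' @param factors Character vector of factor names.
#' @param responses Character vector of response names.
#' @param control_mean,control_sd Numeric, recycled over responses; the
#'   control-level mean and the homoscedastic Gaussian unit noise sigma.
#'   A multiplicative world requires a nonzero `control_mean`.
#' @param effect_matrix Optional numeric matrix (factors x responses) of
#'   true single-factor effects, used verbatim.
#' @param effect_mean,effect_sd Mean and sd of the effect distribution per
#'   response, used when `effect_matrix` is `NULL`.
#' @param world Combination rule per response: `"additive"`,
#'   `"multiplicative"` or `"dominative"`, recycled.
#' @param interaction An interaction rule, see [interaction_none()].
#' @param directions Named character vector of response directions;
#'   defaults to [gcf_directions()] over `responses`.
#' @param seed Integer seed for drawing the effect matrix.
#' @return Object of class `gcf_truth`.
#' @export
make_ground_truth <- function(factors = gcf_factors(),
                              responses = gcf_responses(),
                              control_mean = 10,
                              control_sd = 1,
                              effect_matrix = NULL,
                              effect_mean = 0,
                              effect_sd = 1,
                              world = "additive",
                              interaction = interaction_none(),
                              directions = NULL,
                              seed = NULL) {
  validate_pool(factors)
  if (anyDuplicated(responses))
    stop("response names must be unique", call. = FALSE)
  nr <- length(responses)
  control_mean <- rep_len(control_mean, nr)
  control_sd <- rep_len(control_sd, nr)
  if (any(control_sd < 0)) stop("control_sd must be >= 0", call. = FALSE)
  world <- rep_len(world, nr)
  bad <- setdiff(world, c("additive", "multiplicative", "dominative"))
  if (length(bad)) stop("unknown world: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (any(world == "multiplicative" & control_mean == 0))
    stop("a multiplicative world needs a nonzero control_mean",
         call. = FALSE)
  if (is.null(effect_matrix)) {
    effect_mean <- rep_len(effect_mean, nr)
    effect_sd <- rep_len(effect_sd, nr)
    effect_matrix <- with_seed(seed, vapply(
      seq_len(nr),
      function(r) rnorm(length(factors), effect_mean[r], effect_sd[r]),
      numeric(length(factors))))
  } else {
    effect_matrix <- as.matrix(effect_matrix)
    if (nrow(effect_matrix) != length(factors) ||
        ncol(effect_matrix) != nr)
      stop(sprintf("effect_matrix must be %d x %d (factors x responses)",
                   length(factors), nr), call. = FALSE)
  }
  dimnames(effect_matrix) <- list(factors, responses)
  directions <- directions %||% gcf_directions(responses)
  miss <- setdiff(responses, names(directions))
  if (length(miss))
    stop("no direction declared for response(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(directions %in% c("positive", "negative")))
    stop("directions must be 'positive' or 'negative'", call. = FALSE)

  truth <- list(factors = factors, responses = responses,
                control_mean = stats::setNames(control_mean, responses),
                control_sd = stats::setNames(control_sd, responses),
                effect_matrix = effect_matrix,
                world = stats::setNames(world, responses),
                interaction = interaction,
                directions = directions[responses])
  # true factor distances on standardized effect profiles, used by the
  # distance-proportional interaction rule
  if (identical(interaction$type, "distance_proportional"))
    truth$distance <- distance_matrix(
      suppressWarnings(standardize_effects(effect_matrix)))
  class(truth) <- "gcf_truth"
  truth
}

#' @export
print.gcf_truth <- function(x, ...) {
  cat("Ground truth:", length(x$factors), "factors x",
      length(x$responses), "responses\n")
  cat("  worlds:", paste(unique(x$world), collapse = ", "), "\n")
  cat("  interaction:", x$interaction$type, "\n")
  invisible(x)
}

# Noiseless expected value of one treatment for one response.
true_treatment_value <- function(truth, members, response) {
  ct <- truth$control_mean[[response]]
  if (length(members) == 0L || identical(members, "")) return(ct)
  es <- truth$effect_matrix[members, response]
  joint <- combine_effects(es, truth$world[[response]], ct)
  inter <- 0
  rule <- truth$interaction
  if (length(members) >= 2L && rule$type != "none") {
    sgn <- rep_len(rule$sign, length(truth$responses))[
      match(response, truth$responses)]
    pairs <- utils::combn(members, 2L)
    if (rule$type == "fixed") {
      inter <- sgn * rule$gamma * ncol(pairs)
    } else {
      d <- truth$distance[cbind(pairs[1L, ], pairs[2L, ])]
      inter <- sgn * rule$gamma * sum(d)
    }
  }
  ct + joint + inter
}

#' Simulate a response table from ground truth and a design
#'
#' Draws one value per experimental unit and response: the control mean,
#' plus the members' true effects combined under the response's world rule
#' (exactly the rule the null models assume), plus any injected pairwise
#' interaction term, plus Gaussian unit noise. Control and water-control
#' units carry no treatment effect.
#'
#' @param truth A `gcf_truth` object from [make_ground_truth()].
#' @param design A design table; its factors must all exist in `truth`.
#' @param seed Integer seed for the noise draws.
#' @return A long-format `data.frame` of class `gcf_responses` with columns
#'   `unit_id`, `treatment_id`, `response`, `value`.
#' @export
#' @examples
#' tr <- make_ground_truth(seed = 1)
#' de <- sample_design(gcf_factors(), seed = 1)
#' head(simulate_experiment(tr, de, seed = 2))
simulate_experiment <- function(truth, design, seed = NULL) {
  stopifnot(inherits(truth, "gcf_truth"))
  validate_design(design)
  members <- design_members(design)
  unknown <- setdiff(unlist(members), c(truth$factors, ""))
  if (length(unknown))
    stop("design uses factors unknown to the ground truth: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  reps <- design$n_replicates
  unit_trt <- rep(design$treatment_id, reps)
  unit_id <- paste0(unit_trt, "_u",
                    unlist(lapply(reps, seq_len), use.names = FALSE))
  # noiseless treatment value per design row x response
  mu <- vapply(truth$responses, function(r)
    vapply(members, true_treatment_value, numeric(1),
           truth = truth, response = r), numeric(nrow(design)))
  mu_units <- mu[rep(seq_len(nrow(design)), reps), , drop = FALSE]
  n_units <- length(unit_id)
  noise <- with_seed(seed, vapply(
    truth$responses,
    function(r) rnorm(n_units, 0, truth$control_sd[[r]]),
    numeric(n_units)))
  out <- data.frame(
    unit_id = rep(unit_id, times = length(truth$responses)),
    treatment_id = rep(unit_trt, times = length(truth$responses)),
    response = rep(truth$responses, each = n_units),
    value = as.vector(mu_units + noise),
    stringsAsFactors = FALSE)
  class(out) <- c("gcf_responses", "data.frame")
  out
}

validate_responses <- function(responses, design = NULL) {
  need <- c("unit_id", "treatment_id", "response", "value")
  miss <- setdiff(need, names(responses))
  if (length(miss))
    stop("response table is missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!is.null(design)) {
    orphan <- setdiff(unique(responses$treatment_id), design$treatment_id)
    if (length(orphan))
      stop("response table has treatment_ids absent from the design: ",
           paste(orphan, collapse = ", "), call. = FALSE)
  }
  invisible(responses)
}

# values of one treatment group for one response
group_values <- function(responses, treatment_id, response) {
  responses$value[responses$treatment_id == treatment_id &
                    responses$response == response]
}
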