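#' Enumerate all factor combinations of a given size
#'
#' Generates the complete set of unordered size-`k` subsets of the factor
#' pool, each exactly once, in lexicographic order with respect to the
#' pool's declaration order. For the default 12-factor pool and `k = 5`
#' this yields the full set of 792 candidate combinations from which a
#' design samples.
#'
#' @param pool Character vector of unique factor names.
#' @param k Combination size, `1 <= k <= length(pool)`.
#' @return List of character vectors, each a combination in pool order.
#' @export
#' @examples
#' length(enumerate_combinations(gcf_factors(), 5))  # 792
enumerate_combinations <- function(pool, k) {
  validate_pool(pool)
  k <- check_count(k, "k")
  if (k > length(pool))
    stop(sprintf("cannot choose k = %d factors from a pool of %d",
                 k, length(pool)), call. = FALSE)
  idx <- utils::combn(seq_along(pool), k, simplify = FALSE)
  lapply(idx, function(i) pool[i])
}

#' Sample a randomized multi-factor experimental design
#'
#' Builds the skeleton of a randomized factor-pool experiment: a control
#' group, an optional solvent (water) control, single-factor treatments for
#' every pool member, and, per number-of-factors level, `n_per_level`
#' distinct factor combinations drawn without replacement from the
#' enumerated complete set. Sampling is a seeded shuffle of the complete
#' set followed by taking the first `n_per_level` entries, so draws are
#' exact and fully reproducible.
#'
#' The default replicate plan mirrors a 276-unit soil microcosm layout:
#' 20 controls, 10 water controls, 8 replicates per single factor and one
#' unit per sampled combination at levels 2, 5 and 8.
#'
#' @param pool Character vector of unique factor names.
#' @param levels Integer vector of number-of-factors levels (default
#'   `c(2, 5, 8)`).
#' @param n_per_level Number of combinations to draw at each level; scalar
#'   or one value per level. Must not exceed `choose(length(pool), k)`.
#' @param replicate_plan Named vector with replicate counts for kinds
#'   `control`, `water_control`, `single` and `multi`. A count of zero
#'   drops that kind.
#' @param seed Integer seed; the same seed yields an identical design.
#' @return A `data.frame` of class `gcf_design` with columns
#'   `treatment_id`, `kind`, `level`, `factors` (semicolon-joined members
#'   in pool order) and `n_replicates`.
#' @export
#' @examples
#' d <- sample_design(gcf_factors(), seed = 1)
#' design_summary(d)$total_units  # 276
sample_design <- function(pool,
                          levels = c(2, 5, 8),
                          n_per_level = 50,
                          replicate_plan = c(control = 20, water_control = 10,
                                             single = 8, multi = 1),
                          seed = NULL) {
  validate_pool(pool)
  if (length(n_per_level) == 1L)
    n_per_level <- rep(n_per_level, length(levels))
  if (length(n_per_level) != length(levels))
    stop("'n_per_level' must have length 1 or length(levels)", call. = FALSE)
  plan <- c(control = 0, water_control = 0, single = 0, multi = 1)
  plan[names(replicate_plan)] <- replicate_plan
  if (any(plan < 0) || any(plan != floor(plan)))
    stop("replicate counts must be nonnegative integers", call. = FALSE)

  rows <- list()
  add <- function(id, kind, level, factors, n)
    rows[[length(rows) + 1L]] <<- data.frame(
      treatment_id = id, kind = kind, level = level,
      factors = factors, n_replicates = as.integer(n),
      stringsAsFactors = FALSE)

  if (plan[["control"]] > 0)
    add("control", "control", 0L, "", plan[["control"]])
  if (plan[["water_control"]] > 0)
    add("water_control", "water_control", 0L, "", plan[["water_control"]])
  if (plan[["single"]] > 0)
    for (f in pool) add(paste0("single_", f), "single", 1L, f, plan[["single"]])

  multis <- with_seed(seed, {
    out <- list()
    for (i in seq_along(levels)) {
      k <- check_count(levels[i], "level")
      n <- check_count(n_per_level[i], "n_per_level", min = 1)
      all_k <- enumerate_combinations(pool, k)
      if (n > length(all_k))
        stop(sprintf(
          "infeasible design: %d combinations requested at level %d but only %d exist",
          n, k, length(all_k)), call. = FALSE)
      chosen <- all_k[sample.int(length(all_k))][seq_len(n)]
      out[[i]] <- list(level = k, chosen = chosen)
    }
    out
  })
  for (m in multis)
    for (j in seq_along(m$chosen))
      add(sprintf("N%d_%02d", m$level, j), "multi", m$level,
          paste(m$chosen[[j]], collapse = ";"), plan[["multi"]])

  design <- do.call(rbind, rows)
  rownames(design) <- NULL
  class(design) <- c("gcf_design", "data.frame")
  validate_design(design, pool)
  design
}

# Split the semicolon-joined factors column back into member vectors.
design_members <- function(design) {
  strsplit(design$factors, ";", fixed = TRUE)
}

validate_design <- function(design, pool = NULL) {
  need <- c("treatment_id", "kind", "level", "factors", "n_replicates")
  miss <- setdiff(need, names(design))
  if (length(miss))
    stop("design table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(design$treatment_id))
    stop("duplicated treatment_id in design", call. = FALSE)
  if (any(design$n_replicates < 1))
    stop("replicate counts must be positive", call. = FALSE)
  members <- design_members(design)
  multi <- design$kind == "multi"
  ids <- vapply(members[multi], combination_id, character(1))
  if (any(tapply(ids, design$level[multi], anyDuplicated) > 0))
    stop("duplicated factor combination within a level", call. = FALSE)
  if (!is.null(pool)) {
    unknown <- setdiff(unlist(members[design$kind %in% c("single", "multi")]),
                       pool)
    if (length(unknown))
      stop("design uses factors absent from the pool: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  invisible(design)
}

#' Summarize an experimental design
#'
#' @param design A design table from [sample_design()] or
#'   [read_design_csv()].
#' @return List with `n_treatments`, `units_by_kind` (named vector of unit
#'   counts per kind) and `total_units` (sum of all replicate counts).
#' @export
design_summary <- function(design) {
  validate_design(design)
  by_kind <- tapply(design$n_replicates, design$kind, sum)
  list(n_treatments = nrow(design),
       units_by_kind = by_kind[order(names(by_kind))],
       total_units = sum(design$n_replicates))
}
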