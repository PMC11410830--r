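#' Within-level Spearman trend of responses against dissimilarity
#'
#' Rank correlation between raw treatment-level responses (group means)
#' and the normalized dissimilarity index, within each number-of-factors
#' level. Ties are handled by average ranks and p-values use the
#' two-sided t approximation. This trend is descriptive: a within-level
#' correlation alone cannot separate a dissimilarity effect from factor
#' identity; [fit_hierarchy()] is the inferential surface for that
#' question.
#'
#' @param responses Long-format response table.
#' @param indices Dissimilarity table from [di_table()].
#' @param levels Optional subset of levels to test (default: all levels
#'   present in `indices`).
#' @return `data.frame` with columns `response`, `level`, `rho`, `p`,
#'   `n`. Constant vectors give `NA` with a warning.
#' @export
spearman_trend <- function(responses, indices, levels = NULL) {
  validate_responses(responses)
  levels <- levels %||% sort(unique(indices$level))
  resp_names <- unique(responses$response)
  key <- paste(responses$treatment_id, responses$response)
  means <- tapply(responses$value, key, mean)
  out <- list()
  for (lv in levels) {
    idx <- indices[indices$level == lv, ]
    if (nrow(idx) < 3L)
      stop("fewer than 3 treatments at level ", lv, call. = FALSE)
    for (rn in resp_names) {
      y <- as.numeric(means[paste(idx$treatment_id, rn)])
      ok <- !is.na(y)
      if (sum(ok) < 3L)
        stop("fewer than 3 matched treatments at level ", lv,
             " for response ", rn, call. = FALSE)
      x <- idx$di_norm[ok]; y <- y[ok]
      if (sd(x) == 0 || sd(y) == 0) {
        warning("constant vector at level ", lv, ", response ", rn,
                "; correlation undefined", call. = FALSE)
        rho <- NA_real_; p <- NA_real_
      } else {
        ct <- suppressWarnings(cor.test(y, x, method = "spearman",
                                        exact = FALSE))
        rho <- unname(ct$estimate); p <- ct$p.value
      }
      out[[length(out) + 1L]] <- data.frame(
        response = rn, level = lv, rho = rho, p = p, n = length(y),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
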