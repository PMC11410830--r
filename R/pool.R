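#' Default global change factor pool
#'
#' The twelve anthropogenic factors making up the default factor pool:
#' salinity, drought, microplastic, fungicide, herbicide, antibiotic,
#' insecticide, surfactant, nitrogen deposition, heavy metal, PFAS and
#' lithium. The declaration order is fixed: it defines the order of
#' composition columns and all lexicographic tie-breaking downstream.
#'
#' @return Character vector of 12 factor names.
#' @export
#' @examples
#' gcf_factors()
gcf_factors <- function() {
  c("salinity", "drought", "microplastic", "fungicide", "herbicide",
    "antibiotic", "insecticide", "surfactant", "nitrogen_deposition",
    "heavy_metal", "pfas", "lithium")
}

#' Default soil response variables
#'
#' The seven soil properties and functions tracked by the default
#' configuration: litter decomposition rate, soil pH, water-stable
#' aggregates (WSA) and four extracellular enzyme activities (cellulase,
#' beta-glucosidase, phosphatase, N-acetyl-glucosaminidase).
#'
#' @return Character vector of 7 response names.
#' @export
gcf_responses <- function() {
  c("decomposition_rate", "ph", "wsa", "cellulase", "beta_glucosidase",
    "phosphatase", "nag")
}

#' Default response directions
#'
#' Expected direction of each soil response under multi-factor stress,
#' used by the interaction classifier: deviations beyond the null interval
#' are synergistic when they push the response further in its expected
#' direction. Decomposition rate and WSA respond negatively; pH and the
#' four enzyme activities positively.
#'
#' @param responses Character vector of response names; defaults to
#'   [gcf_responses()]. Unknown names default to `"positive"`.
#' @return Named character vector, values `"positive"` or `"negative"`.
#' @export
gcf_directions <- function(responses = gcf_responses()) {
  dir <- rep("positive", length(responses))
  names(dir) <- responses
  dir[names(dir) %in% c("decomposition_rate", "wsa")] <- "negative"
  dir
}

validate_pool <- function(pool) {
  if (!is.character(pool) || length(pool) < 1L || anyNA(pool))
    stop("factor pool must be a non-empty character vector", call. = FALSE)
  if (anyDuplicated(pool))
    stop("factor pool contains duplicated names: ",
         paste(unique(pool[duplicated(pool)]), collapse = ", "),
         call. = FALSE)
  pool
}

#' Stable combination identifier
#'
#' @param members Character vector of factor names.
#' @return Single string: the sorted member names joined by `";"`,
#'   invariant under member order.
#' @export
combination_id <- function(members) {
  paste(sort(members), collapse = ";")
}
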