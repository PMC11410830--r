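# CSV contracts for the typed tables. Round-trips are lossless for the
# columns each schema declares; schema mismatches fail naming the columns.

check_schema <- function(df, need, what) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(df)
}

#' Read and write design tables as CSV
#'
#' Columns: `treatment_id`, `kind`, `level`, `factors` (semicolon-joined
#' member names) and `n_replicates`.
#'
#' @param design A design table.
#' @param path File path.
#' @return `read_design_csv()` returns a validated `gcf_design`
#'   `data.frame`; `write_design_csv()` returns `path` invisibly.
#' @export
write_design_csv <- function(design, path) {
  validate_design(design)
  write.csv(as.data.frame(design), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, c("treatment_id", "kind", "level", "factors",
                     "n_replicates"), "design CSV")
  df$factors[is.na(df$factors)] <- ""
  class(df) <- c("gcf_design", "data.frame")
  validate_design(df)
  df
}

#' Read and write long-format response tables as CSV
#'
#' Columns: `unit_id`, `treatment_id`, `response`, `value`.
#'
#' @param responses A response table.
#' @param path File path.
#' @return `read_responses_csv()` returns a `gcf_responses` `data.frame`;
#'   `write_responses_csv()` returns `path` invisibly.
#' @export
write_responses_csv <- function(responses, path) {
  validate_responses(responses)
  write.csv(as.data.frame(responses), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_responses_csv
#' @export
read_responses_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, c("unit_id", "treatment_id", "response", "value"),
               "response CSV")
  class(df) <- c("gcf_responses", "data.frame")
  df
}

#' Read and write labeled square distance matrices as CSV
#'
#' The matrix is stored with row labels in the first column and matching
#' column labels; symmetry is checked on read.
#'
#' @param dm Symmetric labeled matrix.
#' @param path File path.
#' @return `read_distance_csv()` returns the matrix;
#'   `write_distance_csv()` returns `path` invisibly.
#' @export
write_distance_csv <- function(dm, path) {
  dm <- as.matrix(dm)
  stopifnot(nrow(dm) == ncol(dm))
  write.csv(dm, path, row.names = TRUE)
  invisible(path)
}

#' @rdname write_distance_csv
#' @export
read_distance_csv <- function(path) {
  df <- read.csv(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m)))
    stop("distance CSV is not a labeled square matrix", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-8)
    stop("distance matrix is not symmetric", call. = FALSE)
  m
}
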