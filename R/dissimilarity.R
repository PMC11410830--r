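#' Standardize single-factor effect profiles
#'
#' Centers each response column of an effect matrix to mean zero and
#' scales it to unit standard deviation across factors, so that every
#' response contributes equally to factor-factor distances. Zero-variance
#' columns are mapped to all zeros with a warning.
#'
#' @param effect_matrix Numeric matrix, factors x responses, no missing
#'   cells, at least two factors.
#' @return Standardized matrix with the same dimnames.
#' @export
standardize_effects <- function(effect_matrix) {
  m <- as.matrix(effect_matrix)
  if (nrow(m) < 2L)
    stop("need at least two factors to standardize across", call. = FALSE)
  if (anyNA(m)) stop("effect matrix has missing cells", call. = FALSE)
  sds <- apply(m, 2, sd)
  zero <- sds == 0
  if (any(zero)) {
    warning("zero-variance response column(s) set to 0: ",
            paste(colnames(m)[zero], collapse = ", "), call. = FALSE)
    sds[zero] <- 1
  }
  out <- scale(m, center = TRUE, scale = sds)
  out[, zero] <- 0
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

#' Euclidean factor-factor distance matrix
#'
#' @param standardized Matrix of (standardized) effect profiles, one row
#'   per factor.
#' @return Symmetric numeric matrix with zero diagonal and factor names as
#'   labels.
#' @export
distance_matrix <- function(standardized) {
  as.matrix(dist(standardized, method = "euclidean"))
}

#' Dissimilarity index of one factor combination
#'
#' Sum of the Euclidean distances between every two component factors of
#' the combination (its `choose(N, 2)` unordered pairs). A single-member
#' combination has no pairs and index 0.
#'
#' @param members Character vector of factor names.
#' @param dm Distance matrix with all members among its labels.
#' @return Nonnegative number, the raw dissimilarity index.
#' @export
dissimilarity_index <- function(members, dm) {
  unknown <- setdiff(members, rownames(dm))
  if (length(unknown))
    stop("unknown factor(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (length(members) < 2L) return(0)
  pairs <- utils::combn(members, 2L)
  sum(dm[cbind(pairs[1L, ], pairs[2L, ])])
}

#' Range-normalize dissimilarity indices within each level
#'
#' The raw index grows mechanically with the number of pairs
#' (1 pair at level 2, 28 at level 8), so comparisons across levels use a
#' within-level range normalization: subtract the level minimum and divide
#' by the level range, mapping each level onto `[0, 1]`.
#'
#' @param indices `data.frame` with columns `level` and `di_raw`.
#' @return The input with a `di_norm` column filled. A level with zero
#'   range gets all zeros with a warning.
#' @export
normalize_within_level <- function(indices) {
  stopifnot(all(c("level", "di_raw") %in% names(indices)))
  indices$di_norm <- NA_real_
  for (lv in unique(indices$level)) {
    sel <- indices$level == lv
    x <- indices$di_raw[sel]
    rng <- max(x) - min(x)
    if (rng == 0) {
      warning("zero dissimilarity range at level ", lv,
              "; normalized indices set to 0", call. = FALSE)
      indices$di_norm[sel] <- 0
    } else {
      indices$di_norm[sel] <- (x - min(x)) / rng
    }
  }
  indices
}

#' Dissimilarity index table for a design
#'
#' Computes the raw dissimilarity index of every multi-factor treatment
#' and its within-level range normalization.
#'
#' @param design Design table.
#' @param dm Factor distance matrix from [distance_matrix()].
#' @return `data.frame` with columns `treatment_id`, `level`, `di_raw`,
#'   `di_norm`.
#' @export
di_table <- function(design, dm) {
  validate_design(design)
  multi <- design[design$kind == "multi", ]
  members <- design_members(multi)
  out <- data.frame(
    treatment_id = multi$treatment_id,
    level = multi$level,
    di_raw = vapply(members, dissimilarity_index, numeric(1), dm = dm),
    stringsAsFactors = FALSE)
  normalize_within_level(out)
}

#' Principal coordinate analysis of a factor distance matrix
#'
#' Classical (Torgerson) scaling: eigendecomposition of the
#' double-centered Gram matrix. Axes are ordered by eigenvalue and the
#' variance fraction of an axis is its eigenvalue divided by the sum of
#' the positive eigenvalues; negative eigenvalues are reported but
#' excluded from that denominator.
#'
#' @param dm Symmetric distance matrix.
#' @param n_axes Number of coordinate axes to return.
#' @return List with `points` (labels x axes), `eig` (all eigenvalues) and
#'   `variance_explained` (fraction per returned axis).
#' @export
pcoa <- function(dm, n_axes = 2) {
  n_axes <- check_count(n_axes, "n_axes")
  n_axes <- min(n_axes, nrow(as.matrix(dm)) - 1L)
  fit <- cmdscale(as.dist(dm), k = n_axes, eig = TRUE)
  pos <- fit$eig[fit$eig > 0]
  colnames(fit$points) <- paste0("PCoA", seq_len(ncol(fit$points)))
  list(points = fit$points,
       eig = fit$eig,
       variance_explained = fit$eig[seq_len(n_axes)] / sum(pos))
}

#' Hierarchical clustering of factors
#'
#' Agglomerative clustering of the factor distance matrix; the default
#' linkage is UPGMA (average). Ties are resolved by the deterministic
#' merge order of [stats::hclust()] on the matrix as labeled, i.e. by the
#' pool's declaration order.
#'
#' @param dm Factor distance matrix (at least two factors).
#' @param linkage Agglomeration method, see [stats::hclust()].
#' @return An `hclust` object.
#' @export
hierarchical_cluster <- function(dm, linkage = "average") {
  dm <- as.matrix(dm)
  if (nrow(dm) < 2L) stop("need at least two factors", call. = FALSE)
  hclust(as.dist(dm), method = linkage)
}

#' Serialize a dendrogram to Newick
#'
#' @param hc An `hclust` object, e.g. from [hierarchical_cluster()].
#' @return Single Newick string (with branch lengths).
#' @export
cluster_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}
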