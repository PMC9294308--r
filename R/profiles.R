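#' Vertex-wise functional profiles
#'
#' A vertices x conditions matrix of activity estimates (or time points).
#' The Pearson correlation between two rows is the functional similarity of
#' the two vertices used by every evaluation criterion.  Vertices whose row
#' contains a non-finite value, and vertices with zero variance across
#' conditions (their correlation is undefined), are flagged invalid and
#' excluded from all pair sets.
#'
#' @param values Numeric matrix, vertices in rows, conditions in columns
#'   (at least 2 columns).
#' @param valid Optional logical vector marking usable vertices; rows with
#'   non-finite values or zero variance are forced invalid regardless.
#' @return Object of class `functional_profiles`: list with `values` and
#'   logical `valid`.
#' @export
functional_profiles <- function(values, valid = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) < 2L)
    stop("profiles need at least 2 conditions for Pearson correlation")
  if (is.null(valid)) valid <- rep(TRUE, nrow(values))
  stopifnot(length(valid) == nrow(values))
  finite <- rowSums(!is.finite(values)) == 0L
  vr <- rep(FALSE, nrow(values))
  vr[finite] <- apply(values[finite, , drop = FALSE], 1,
                      function(r) stats::var(r) > 0)
  structure(list(values = values, valid = as.logical(valid) & vr),
            class = "functional_profiles")
}

#' @export
print.functional_profiles <- function(x, ...) {
  cat("functional_profiles:", nrow(x$values), "vertices x",
      ncol(x$values), "conditions;", sum(!x$valid), "invalid\n")
  invisible(x)
}

#' @export
n_vertices.functional_profiles <- function(x) nrow(x$values)

# rows centred and scaled to unit norm so that tcrossprod gives Pearson r;
# invalid rows set to NA
standardize_profiles <- function(profiles) {
  z <- profiles$values - rowMeans(profiles$values)
  nrm <- sqrt(rowSums(z^2))
  z <- z / nrm
  z[!profiles$valid | nrm == 0, ] <- NA_real_
  z
}

#' Pearson correlation between two vertices' profiles
#'
#' @param profiles A [functional_profiles()].
#' @param i,j Vertex indices.
#' @return Correlation in `[-1, 1]`.
#' @export
pairwise_correlation <- function(profiles, i, j) {
  stopifnot(inherits(profiles, "functional_profiles"))
  if (!profiles$valid[i] || !profiles$valid[j])
    stop("masked or zero-variance vertex has no defined correlation")
  stats::cor(profiles$values[i, ], profiles$values[j, ])
}

#' Pearson correlations for all stored distance pairs
#'
#' Computes the profile correlation for every vertex pair present in a
#' sparse distance matrix, aligned with its pair order.  Precomputing this
#' vector once lets several criteria (different parcellations, bin widths)
#' reuse it.
#'
#' @param profiles A [functional_profiles()].
#' @param dist A `sparse_dist` over the same vertices.
#' @return Numeric vector, `NA` for pairs with an invalid vertex.
#' @export
pair_correlations <- function(profiles, dist) {
  stopifnot(inherits(profiles, "functional_profiles"),
            inherits(dist, "sparse_dist"))
  if (nrow(profiles$values) != dist$n_vertices)
    stop("profiles and distances have different vertex counts")
  z <- standardize_profiles(profiles)
  rowSums(z[dist$i, , drop = FALSE] * z[dist$j, , drop = FALSE])
}
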