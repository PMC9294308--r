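#' Distance-binned pair counts for a parcellation
#'
#' Classifies every stored vertex pair as within-parcel or between-parcel
#' and assigns it to a spatial distance bin.  Only pairs with both vertices
#' valid, both labels non-zero and distance in `(0, max_dist]` are used.
#' Bins are half-open `(lo, hi]`: a distance exactly on a bin edge falls in
#' the lower bin.
#'
#' @param parc A [parcellation()].
#' @param dist A `sparse_dist`.
#' @param bin_width Bin width in mm (default 1).
#' @param max_dist Largest distance evaluated, mm (default 35); must not
#'   exceed the distance-matrix cutoff.
#' @param valid Optional logical vertex mask (e.g. from
#'   [functional_profiles()]).
#' @return Object of class `binned_pairs`: data.frame with columns `bin`,
#'   `lo`, `hi`, `n_within`, `n_between`.
#' @export
classify_and_bin_pairs <- function(parc, dist, bin_width = 1,
                                   max_dist = 35, valid = NULL) {
  bp <- binned_pair_stats(parc, dist, r = NULL, bin_width = bin_width,
                          max_dist = max_dist, valid = valid)
  structure(bp[c("bin", "lo", "hi", "n_within", "n_between")],
            class = c("binned_pairs", "data.frame"))
}

# shared core: per-bin counts and (when r is given) correlation sums
binned_pair_stats <- function(parc, dist, r = NULL, bin_width = 1,
                              max_dist = 35, valid = NULL) {
  stopifnot(inherits(parc, "parcellation"), inherits(dist, "sparse_dist"))
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("`bin_width` must be positive")
  if (max_dist > dist$cutoff + 1e-9)
    stop("`max_dist` exceeds the distance-matrix cutoff")
  labels <- unclass(parc)
  if (length(labels) != dist$n_vertices)
    stop("parcellation and distances have different vertex counts")
  if (is.null(valid)) valid <- rep(TRUE, length(labels))
  li <- labels[dist$i]; lj <- labels[dist$j]
  keep <- dist$d <= max_dist & li > 0L & lj > 0L &
    valid[dist$i] & valid[dist$j]
  if (!is.null(r)) keep <- keep & !is.na(r)
  n_bins <- ceiling(max_dist / bin_width)
  bin <- ceiling(dist$d[keep] / bin_width)
  within <- li[keep] == lj[keep]
  agg <- function(x) {
    out <- numeric(n_bins)
    if (length(x)) {
      s <- rowsum(x, bin)
      out[as.integer(rownames(s))] <- s
    }
    out
  }
  res <- data.frame(
    bin = seq_len(n_bins),
    lo = (seq_len(n_bins) - 1) * bin_width,
    hi = seq_len(n_bins) * bin_width,
    n_within = agg(as.numeric(within)),
    n_between = agg(as.numeric(!within)))
  if (!is.null(r)) {
    rk <- r[keep]
    res$sum_within <- agg(rk * within)
    res$sum_between <- agg(rk * !within)
  }
  res
}

#' Precision weights for distance bins
#'
#' Under independence of vertex pairs, the variance of the per-bin
#' within-minus-between correlation difference is
#' \eqn{1/n_{w,i} + 1/n_{b,i}}.  Each usable bin gets a weight proportional
#' to the precision (inverse variance), i.e. to
#' \eqn{n_{w,i} n_{b,i} / (n_{w,i} + n_{b,i})}, normalised to sum to one.
#' Bins missing either within- or between-parcel pairs carry no information
#' about the difference and are excluded.
#'
#' @param n_within,n_between Per-bin pair counts.
#' @return List with `weights` (over included bins, summing to 1),
#'   `included` and `excluded` (bin indices).
#' @export
compute_weights <- function(n_within, n_between) {
  stopifnot(length(n_within) == length(n_between))
  ok <- n_within > 0 & n_between > 0
  if (!any(ok))
    stop("evaluation impossible: no bin has both within- and ",
         "between-parcel pairs")
  prec <- n_within[ok] * n_between[ok] / (n_within[ok] + n_between[ok])
  list(weights = prec / sum(prec),
       included = which(ok), excluded = which(!ok))
}

#' Distance-controlled boundary coefficient (DCBC)
#'
#' Evaluates how sharply a parcellation's boundaries separate functional
#' profiles, controlling for spatial autocorrelation.  Vertex pairs are
#' binned by geodesic distance; within each bin the mean within-parcel
#' correlation minus the mean between-parcel correlation is computed; the
#' DCBC is the precision-weighted average of these per-bin differences
#' (see [compute_weights()]).  The simple un-weighted bin mean is also
#' returned for comparison.  For a parcellation unrelated to the functional
#' boundaries of the data the expected DCBC is zero; positive values mean
#' that correlations drop across parcel boundaries beyond what distance
#' alone predicts.
#'
#' @param profiles A [functional_profiles()].
#' @param parc A [parcellation()] with at least two non-empty parcels.
#' @param dist A `sparse_dist` of geodesic distances.
#' @param bin_width Bin width in mm (default 1).
#' @param max_dist Evaluation range in mm (default 35).
#' @param pair_cor Optional precomputed [pair_correlations()] vector (reused
#'   across calls with different parcellations or bin widths).
#' @return Object of class `dcbc`: list with elements `dcbc` (weighted
#'   coefficient), `dcbc_unweighted`, `binned` (per-bin data.frame with
#'   counts, mean correlations, difference `d`, `weight`, `included`),
#'   `excluded_bins`, `bin_width`, `max_dist`, `n_pairs`.
#' @examples
#' sph <- geodesic_sphere(4)
#' dm <- geodesic_distances(sph, cutoff = 50)
#' pr <- white_noise_map(sph, n_conditions = 10, seed = 1)
#' pc <- icosahedron_parcellation(sph, 42)
#' compute_dcbc(pr, pc, dm, bin_width = 5, max_dist = 35)
#' @export
compute_dcbc <- function(profiles, parc, dist, bin_width = 1,
                         max_dist = 35, pair_cor = NULL) {
  stopifnot(inherits(profiles, "functional_profiles"))
  labels <- unclass(parc)
  if (length(unique(labels[labels > 0L & profiles$valid])) < 2L)
    stop("evaluation impossible: fewer than 2 non-empty parcels ",
         "intersect the valid vertices")
  if (is.null(pair_cor)) pair_cor <- pair_correlations(profiles, dist)
  bp <- binned_pair_stats(parc, dist, r = pair_cor, bin_width = bin_width,
                          max_dist = max_dist, valid = profiles$valid)
  w <- compute_weights(bp$n_within, bp$n_between)
  ok <- bp$bin %in% w$included
  bp$mean_within <- ifelse(bp$n_within > 0, bp$sum_within / bp$n_within, NA)
  bp$mean_between <- ifelse(bp$n_between > 0,
                            bp$sum_between / bp$n_between, NA)
  bp$d <- ifelse(ok, bp$mean_within - bp$mean_between, NA)
  bp$weight <- NA_real_
  bp$weight[ok] <- w$weights
  bp$included <- ok
  structure(list(
    dcbc = sum(w$weights * bp$d[ok]),
    dcbc_unweighted = mean(bp$d[ok]),
    binned = bp[c("bin", "lo", "hi", "n_within", "n_between",
                  "mean_within", "mean_between", "d", "weight",
                  "included")],
    excluded_bins = w$excluded,
    bin_width = bin_width, max_dist = max_dist,
    n_pairs = sum(bp$n_within + bp$n_between)),
    class = "dcbc")
}

#' @export
print.dcbc <- function(x, digits = 4, ...) {
  cat("DCBC (", x$bin_width, " mm bins, 0-", x$max_dist, " mm, ",
      sum(x$binned$included), "/", nrow(x$binned), " bins used)\n",
      sep = "")
  cat("  weighted:   ", signif(x$dcbc, digits), "\n")
  cat("  un-weighted:", signif(x$dcbc_unweighted, digits), "\n")
  invisible(x)
}

#' @export
summary.dcbc <- function(object, ...) {
  print(object)
  b <- object$binned[object$binned$included, ]
  cat("per-bin correlation difference: range [",
      signif(min(b$d), 3), ", ", signif(max(b$d), 3),
      "]; pairs used ", object$n_pairs, "\n", sep = "")
  if (length(object$excluded_bins))
    cat("excluded bins:",
        paste(object$excluded_bins, collapse = ", "), "\n")
  invisible(object)
}

#' @export
coef.dcbc <- function(object, ...) {
  c(dcbc = object$dcbc, dcbc_unweighted = object$dcbc_unweighted)
}

#' Plot within/between correlation curves of a DCBC evaluation
#'
#' Draws the mean within-parcel and between-parcel correlation per distance
#' bin; the DCBC is the precision-weighted average vertical gap between the
#' curves.
#'
#' @param x A `dcbc` object.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.dcbc <- function(x, ...) {
  b <- x$binned
  ctr <- (b$lo + b$hi) / 2
  graphics::matplot(ctr, cbind(b$mean_within, b$mean_between),
                    type = "l", lty = 1, col = c("black", "red"),
                    xlab = "spatial distance (mm)",
                    ylab = "mean correlation", ...)
  graphics::legend("topright", c("within", "between"),
                   col = c("black", "red"), lty = 1, bty = "n")
  invisible(x)
}

#' Un-binned average correlation difference (ACD)
#'
#' Mean within-parcel correlation minus mean between-parcel correlation
#' over all qualifying vertex pairs up to `max_dist`, ignoring distance
#' matching.  Because within-parcel pairs are on average closer together
#' and correlation decays with distance, this criterion is biased positive
#' on spatially smooth data; it is provided as the comparison baseline for
#' the binned DCBC.
#'
#' @inheritParams compute_dcbc
#' @return Scalar correlation difference.
#' @export
unbinned_acd <- function(profiles, parc, dist, max_dist = 35,
                         pair_cor = NULL) {
  stopifnot(inherits(profiles, "functional_profiles"))
  labels <- unclass(parc)
  if (length(unique(labels[labels > 0L & profiles$valid])) < 2L)
    stop("evaluation impossible: fewer than 2 non-empty parcels ",
         "intersect the valid vertices")
  if (is.null(pair_cor)) pair_cor <- pair_correlations(profiles, dist)
  bp <- binned_pair_stats(parc, dist, r = pair_cor, bin_width = max_dist,
                          max_dist = max_dist, valid = profiles$valid)
  if (bp$n_within[1] == 0 || bp$n_between[1] == 0)
    stop("evaluation impossible: no within- or no between-parcel pairs")
  bp$sum_within[1] / bp$n_within[1] - bp$sum_between[1] / bp$n_between[1]
}

#' Global Homogeneity of a parcellation
#'
#' Average pairwise Pearson correlation of functional profiles within each
#' parcel, then averaged across parcels.  Parcels with fewer than two
#' valid vertices are excluded.  By default every qualifying parcel counts
#' equally; `size_weighted = TRUE` weights parcels by their number of
#' vertex pairs instead.
#'
#' Homogeneity is biased by spatial smoothness: smaller parcels contain
#' only nearby (hence more correlated) vertex pairs, so finer parcellations
#' score higher even on structureless data.
#'
#' @inheritParams compute_dcbc
#' @param size_weighted Weight parcels by pair count instead of equally.
#' @return Scalar mean within-parcel correlation.
#' @export
compute_homogeneity <- function(profiles, parc, size_weighted = FALSE) {
  stopifnot(inherits(profiles, "functional_profiles"),
            inherits(parc, "parcellation"))
  labels <- unclass(parc)
  if (length(labels) != nrow(profiles$values))
    stop("parcellation and profiles have different vertex counts")
  z <- standardize_profiles(profiles)
  use <- labels > 0L & profiles$valid
  if (!any(use)) stop("evaluation impossible: no valid labelled vertices")
  zs <- rowsum(z[use, , drop = FALSE], labels[use])
  m <- as.vector(table(labels[use]))
  qual <- m >= 2L
  if (!any(qual))
    stop("evaluation impossible: no parcel has 2+ valid vertices")
  # sum of pairwise correlations within parcel k: (||sum z||^2 - m) / 2
  pair_sum <- (rowSums(zs^2) - m)[qual] / 2
  n_pairs <- (m[qual] * (m[qual] - 1)) / 2
  per_parcel <- pair_sum / n_pairs
  if (size_weighted) sum(pair_sum) / sum(n_pairs) else mean(per_parcel)
}

#' Silhouette coefficient of a parcellation
#'
#' Per vertex: \eqn{w_i} is the mean dissimilarity (\eqn{1 - R}) to the
#' other vertices of its own parcel, \eqn{b_i} the mean dissimilarity to
#' all vertices of all neighbouring parcels pooled together, and
#' \eqn{S_i = (b_i - w_i) / \max(w_i, b_i)}.  Vertices in singleton parcels
#' or in parcels without neighbours are skipped and reported.  Dissimilarity
#' is taken literally as `1 - R` and may exceed 1 for negative
#' correlations.
#'
#' Like Homogeneity, the Silhouette coefficient is biased by spatial
#' smoothness, because within-parcel pairs are spatially closer than pairs
#' from neighbouring parcels.
#'
#' @inheritParams compute_dcbc
#' @param adjacency A `parcel_adjacency`, or `NULL` to derive it from
#'   `mesh`.
#' @param mesh Optional [surface_mesh()] used when `adjacency` is `NULL`.
#' @return List with per-vertex `values` (`NA` for skipped vertices),
#'   `mean` over evaluated vertices, and `n_skipped`.
#' @export
compute_silhouette <- function(profiles, parc, adjacency = NULL,
                               mesh = NULL) {
  stopifnot(inherits(profiles, "functional_profiles"),
            inherits(parc, "parcellation"))
  if (is.null(adjacency)) {
    if (is.null(mesh)) stop("give `adjacency` or `mesh`")
    adjacency <- parcel_adjacency(parc, mesh)
  }
  labels <- unclass(parc)
  z <- standardize_profiles(profiles)
  use <- labels > 0L & profiles$valid
  zs <- rowsum(z[use, , drop = FALSE], labels[use])
  m <- as.vector(table(labels[use]))
  labs <- as.integer(rownames(zs))
  s <- rep(NA_real_, length(labels))
  for (k in seq_along(labs)) {
    if (m[k] < 2L) next
    nb <- adjacency[[as.character(labs[k])]]
    nb <- nb[nb %in% labs]             # neighbours with valid vertices
    if (is.null(nb) || !length(nb)) next
    idx <- which(labels == labs[k] & use)
    nbk <- match(nb, labs)
    pn <- colSums(zs[nbk, , drop = FALSE])
    N <- sum(m[nbk])
    wi <- 1 - (as.vector(z[idx, , drop = FALSE] %*% zs[k, ]) - 1) /
      (m[k] - 1)
    bi <- 1 - as.vector(z[idx, , drop = FALSE] %*% pn) / N
    s[idx] <- (bi - wi) / pmax(wi, bi)
  }
  evaluated <- !is.na(s)
  if (!any(evaluated))
    stop("evaluation impossible: no vertex could be evaluated")
  list(values = s, mean = mean(s[evaluated]),
       n_skipped = sum(use) - sum(evaluated))
}

#' Group-level summary of per-subject criterion values
#'
#' Mean, standard error and one-sample t test against zero across
#' subjects.  A degenerate case with zero variance is reported with an
#' infinite t statistic (p = 0 for a non-zero mean, p = 1 for all-zero
#' values) rather than as an error.
#'
#' @param values Numeric vector of per-subject values (length >= 2).
#' @return List with `mean`, `se`, `t`, `p`, `n`.
#' @export
group_summary <- function(values) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2L) stop("need at least 2 values")
  m <- mean(values)
  se <- stats::sd(values) / sqrt(n)
  if (se == 0) {
    t <- if (m == 0) 0 else Inf * sign(m)
    p <- if (m == 0) 1 else 0
  } else {
    t <- m / se
    p <- 2 * stats::pt(-abs(t), df = n - 1)
  }
  list(mean = m, se = se, t = t, p = p, n = n)
}

#' Subject-level DCBC across hemispheres
#'
#' The boundary criterion is computed separately per hemisphere (vertex
#' pairs never span hemispheres at the distances considered) and the two
#' values are averaged with equal weight.  A single hemisphere may be
#' supplied alone.
#'
#' @param left,right Each a list with elements `profiles`, `parcellation`
#'   and `dist` for that hemisphere; `right` may be `NULL`.
#' @param bin_width,max_dist Passed to [compute_dcbc()].
#' @return Scalar subject-level DCBC (weighted).
#' @export
evaluate_subject <- function(left, right = NULL, bin_width = 1,
                             max_dist = 35) {
  one <- function(h)
    compute_dcbc(h$profiles, h$parcellation, h$dist,
                 bin_width = bin_width, max_dist = max_dist)$dcbc
  v <- one(left)
  if (!is.null(right)) v <- mean(c(v, one(right)))
  v
}
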