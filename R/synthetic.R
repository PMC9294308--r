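#' White-noise functional map
#'
#' Draws independent standard-normal activity values for every vertex and
#' condition: a functional map with no spatial structure, the raw material
#' for smooth random map simulation.
#'
#' @param mesh A [surface_mesh()].
#' @param n_conditions Number of conditions (default 34).
#' @param seed Integer seed.
#' @return A [functional_profiles()].
#' @export
white_noise_map <- function(mesh, n_conditions = 34, seed) {
  stopifnot(inherits(mesh, "surface_mesh"), n_conditions >= 2)
  n <- nrow(mesh$vertices)
  vals <- withr_seed(seed,
    matrix(stats::rnorm(n * n_conditions), n, n_conditions))
  functional_profiles(vals)
}

#' Smoothing specification
#'
#' Iterative neighbour-averaging on the mesh edge graph: each iteration
#' replaces a vertex value with `self_weight` times its own value plus
#' `1 - self_weight` times the mean of its edge-neighbours, per condition.
#' Repeated iterations approximate diffusion on the surface and induce
#' spatial autocorrelation with a range growing with the iteration count.
#'
#' @param n_iterations Non-negative integer; 0 is the identity.
#' @param self_weight Scalar in `[0, 1]` (default 0.5).
#' @return Object of class `smoothing_spec`.
#' @export
smoothing_spec <- function(n_iterations, self_weight = 0.5) {
  if (length(n_iterations) != 1 || n_iterations < 0 ||
        n_iterations != round(n_iterations))
    stop("`n_iterations` must be a non-negative integer")
  if (self_weight < 0 || self_weight > 1)
    stop("`self_weight` must lie in [0, 1]")
  structure(list(n_iterations = as.integer(n_iterations),
                 self_weight = self_weight),
            class = "smoothing_spec")
}

# sparse one-iteration smoothing operator
smoothing_operator <- function(mesh, self_weight) {
  eg <- build_edge_graph(mesh)
  n <- eg$n_vertices
  A <- Matrix::sparseMatrix(
    i = c(eg$edges[, 1], eg$edges[, 2]),
    j = c(eg$edges[, 2], eg$edges[, 1]),
    x = 1, dims = c(n, n))
  deg <- Matrix::rowSums(A)
  Matrix::Diagonal(n, self_weight) +
    Matrix::Diagonal(n, (1 - self_weight) / deg) %*% A
}

#' Smooth functional profiles on a mesh
#'
#' @param mesh A [surface_mesh()].
#' @param profiles A [functional_profiles()] on the same mesh.
#' @param spec A [smoothing_spec()], or an integer iteration count.
#' @return Smoothed [functional_profiles()].
#' @export
smooth_on_mesh <- function(mesh, profiles, spec) {
  stopifnot(inherits(mesh, "surface_mesh"),
            inherits(profiles, "functional_profiles"))
  if (!inherits(spec, "smoothing_spec")) spec <- smoothing_spec(spec)
  if (nrow(profiles$values) != nrow(mesh$vertices))
    stop("profiles and mesh have different vertex counts")
  x <- profiles$values
  if (spec$n_iterations > 0L) {
    S <- smoothing_operator(mesh, spec$self_weight)
    for (k in seq_len(spec$n_iterations)) x <- as.matrix(S %*% x)
  }
  functional_profiles(x, valid = profiles$valid)
}

#' Smooth random functional map
#'
#' Convenience wrapper: white noise followed by surface smoothing.
#'
#' @inheritParams white_noise_map
#' @param spec A [smoothing_spec()] or iteration count.
#' @return A [functional_profiles()].
#' @export
random_smooth_map <- function(mesh, spec, n_conditions = 34, seed) {
  smooth_on_mesh(mesh, white_noise_map(mesh, n_conditions, seed), spec)
}

#' Spatial autocorrelation curve
#'
#' Mean pairwise Pearson correlation of functional profiles per distance
#' bin; its decay with distance quantifies the spatial smoothness of a
#' map.  Empty bins are reported as `NA`.
#'
#' @param profiles A [functional_profiles()].
#' @param dist A `sparse_dist`.
#' @param bin_width,max_dist Bin specification in mm.
#' @param pair_cor Optional precomputed [pair_correlations()].
#' @return Object of class `autocorrelation_curve`: data.frame with
#'   `center` (bin centre, mm) and `correlation`.
#' @export
autocorrelation_curve <- function(profiles, dist, bin_width = 1,
                                  max_dist = 35, pair_cor = NULL) {
  stopifnot(inherits(dist, "sparse_dist"))
  if (max_dist > dist$cutoff + 1e-9)
    stop("`max_dist` exceeds the distance-matrix cutoff")
  if (is.null(pair_cor)) pair_cor <- pair_correlations(profiles, dist)
  keep <- dist$d <= max_dist & !is.na(pair_cor)
  n_bins <- ceiling(max_dist / bin_width)
  bin <- ceiling(dist$d[keep] / bin_width)
  corr <- rep(NA_real_, n_bins)
  if (any(keep)) {
    s <- rowsum(pair_cor[keep], bin)
    cnt <- rowsum(rep(1, sum(keep)), bin)
    corr[as.integer(rownames(s))] <- s / cnt
  }
  structure(data.frame(center = (seq_len(n_bins) - 0.5) * bin_width,
                       correlation = corr),
            class = c("autocorrelation_curve", "data.frame"))
}

#' Half-distance of an autocorrelation curve
#'
#' The distance at which the curve first drops below half its first
#' (non-empty) bin value; `Inf` if it never does within the curve's
#' range.  Summarises the spatial range of a map's autocorrelation with a
#' single number, the quantity targeted by [calibrate_smoothing()].
#'
#' @param curve An [autocorrelation_curve()].
#' @return Scalar distance in mm (possibly `Inf`).
#' @export
half_distance <- function(curve) {
  ok <- which(!is.na(curve$correlation))
  if (!length(ok)) return(NA_real_)
  c0 <- curve$correlation[ok[1]]
  below <- ok[curve$correlation[ok] < c0 / 2]
  if (!length(below)) Inf else curve$center[below[1]]
}

#' Calibrate smoothing to a target autocorrelation range
#'
#' Finds the smallest iteration count whose realised autocorrelation curve
#' has a half-distance (distance at which correlation drops to half its
#' first-bin value) of at least `target_half_distance`, by doubling search
#' followed by bisection on a single seeded noise map.  This reproduces a
#' stated smoothness goal ("similar spatial autocorrelation as real data")
#' without committing to any particular smoothing-kernel parameterisation.
#'
#' @param mesh A [surface_mesh()].
#' @param dist A `sparse_dist` on the mesh.
#' @param target_half_distance Target half-distance in mm (default 15,
#'   mimicking the decay of task-based cortical profiles).
#' @param seed Seed for the calibration noise map.
#' @param n_conditions Conditions in the calibration map (default 34).
#' @param self_weight Smoothing self-weight (default 0.5).
#' @param max_iterations Search cap (default 512).
#' @param bin_width,max_dist Binning of the realised curve.
#' @return A [smoothing_spec()] with attributes `realized_curve` (the
#'   curve at the returned iteration count) and `half_distance`.
#' @export
calibrate_smoothing <- function(mesh, dist, target_half_distance = 15,
                                seed, n_conditions = 34,
                                self_weight = 0.5, max_iterations = 512,
                                bin_width = 1, max_dist = 35) {
  if (target_half_distance <= 0 || target_half_distance >= max_dist)
    stop("`target_half_distance` must lie in (0, max_dist)")
  noise <- white_noise_map(mesh, n_conditions, seed)
  S <- smoothing_operator(mesh, self_weight)
  curves <- new.env()
  hd <- function(k) {
    key <- as.character(k)
    if (is.null(curves[[key]])) {
      x <- noise$values
      for (it in seq_len(k)) x <- as.matrix(S %*% x)
      curves[[key]] <- autocorrelation_curve(
        functional_profiles(x), dist, bin_width, max_dist)
    }
    half_distance(curves[[key]])
  }
  k <- 1L
  while (hd(k) < target_half_distance && k < max_iterations) k <- 2L * k
  if (hd(k) < target_half_distance)
    stop("calibration failed: half-distance ", signif(hd(k), 4),
         " mm at the iteration cap (", max_iterations,
         ") is below the target ", target_half_distance, " mm")
  lo <- k %/% 2L; hi <- k
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (hd(mid) >= target_half_distance) hi <- mid else lo <- mid
  }
  spec <- smoothing_spec(hi, self_weight)
  attr(spec, "realized_curve") <- curves[[as.character(hi)]]
  attr(spec, "half_distance") <- hd(hi)
  spec
}
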