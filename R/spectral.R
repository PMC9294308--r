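#' Spectral-clustering parcellation of functional profiles
#'
#' Derives a data-driven parcellation: (1) profiles are pooled onto the
#' vertices of a coarser geodesic sphere (nearest-centre map, frequency 20
#' by default, i.e. 4002 nodes), (2) spectral clustering with `k` clusters
#' is run on the affinity between pooled profiles, (3) labels are
#' propagated back to full resolution through the same nearest-centre map.
#' Clustering at reduced resolution keeps the resulting parcels spatially
#' compact.
#'
#' The affinity is the Pearson correlation between pooled profiles with
#' negative values clipped to zero and a zero diagonal.  Clustering uses
#' k-means (seeded, multiple restarts) on the row-normalised leading
#' eigenvectors of the symmetric normalised graph Laplacian.  Cluster label
#' numbering is arbitrary; compare solutions with a permutation-invariant
#' index.
#'
#' @param profiles A [functional_profiles()] on `mesh`.
#' @param mesh A spherical [surface_mesh()].
#' @param k Number of clusters.
#' @param downsample_frequency Geodesic-sphere frequency of the clustering
#'   grid (default 20, giving 4002 nodes).
#' @param seed Seed for k-means initialisation.
#' @return A [parcellation()] at full mesh resolution.
#' @export
spectral_parcellation <- function(profiles, mesh, k,
                                  downsample_frequency = 20, seed = 1) {
  stopifnot(inherits(profiles, "functional_profiles"),
            inherits(mesh, "surface_mesh"))
  if (nrow(profiles$values) != nrow(mesh$vertices))
    stop("profiles and mesh have different vertex counts")
  if (k < 1) stop("`k` must be at least 1")
  r <- check_sphere(mesh)
  centers <- geodesic_sphere(downsample_frequency, radius = r)$vertices
  to_center <- nearest_center_labels(mesh$vertices, centers)

  # pool valid profiles onto centres; drop centres with no valid vertex
  use <- profiles$valid
  pooled <- rowsum(profiles$values[use, , drop = FALSE], to_center[use])
  cnt <- as.vector(table(to_center[use]))
  pooled <- pooled / cnt
  node_ids <- as.integer(rownames(pooled))
  if (k > nrow(pooled))
    stop("`k` exceeds the number of occupied downsampled vertices")

  aff <- stats::cor(t(pooled))
  aff[aff < 0] <- 0
  diag(aff) <- 0
  cl <- spectral_cluster(aff, k, seed)

  labels <- integer(nrow(mesh$vertices))
  node_label <- stats::setNames(cl, node_ids)
  assigned <- to_center %in% node_ids & use
  labels[assigned] <- node_label[as.character(to_center[assigned])]
  parcellation(labels, name = sprintf("spectral-k%d", k), n_parcels = k)
}

# Ng-Jordan-Weiss spectral clustering on a symmetric affinity matrix
spectral_cluster <- function(aff, k, seed) {
  n <- nrow(aff)
  if (k == 1L) return(rep(1L, n))
  deg <- rowSums(aff)
  deg[deg == 0] <- 1e-12
  dh <- 1 / sqrt(deg)
  M <- aff * outer(dh, dh)          # D^{-1/2} A D^{-1/2}
  ev <- eigen(M, symmetric = TRUE)
  U <- ev$vectors[, seq_len(k), drop = FALSE]
  nrm <- sqrt(rowSums(U^2))
  nrm[nrm == 0] <- 1
  U <- U / nrm
  withr_seed(seed,
    stats::kmeans(U, centers = k, nstart = 20, iter.max = 100)$cluster)
}

#' Adjusted Rand index between two label vectors
#'
#' Permutation-invariant agreement between two clusterings; 1 means
#' identical partitions, 0 is chance level.
#'
#' @param a,b Integer label vectors of equal length.
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- si * sj / n2
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}
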