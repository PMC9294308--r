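# shared fixtures and independent brute-force oracles

single_triangle <- function() {
  surface_mesh(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 4, 0)),
               matrix(c(1L, 2L, 3L), 1))
}

two_triangles <- function() {
  # two triangles sharing edge 2-3
  surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)),
               rbind(c(1L, 2L, 3L), c(2L, 4L, 3L)))
}

# small sphere mesh with jittered (non-spherical) coordinates so edge
# lengths are irregular; still a valid connected triangulation
jittered_mesh <- function(frequency = 2, seed = 7) {
  m <- geodesic_sphere(frequency, radius = 10)
  set.seed(seed)
  v <- m$vertices + matrix(stats::rnorm(length(m$vertices), sd = 0.3),
                           ncol = 3)
  surface_mesh(v, m$faces)
}

# Floyd-Warshall all-pairs shortest paths; independent of igraph
floyd_warshall <- function(mesh) {
  eg <- build_edge_graph(mesh)
  n <- eg$n_vertices
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (r in seq_len(nrow(eg$edges))) {
    i <- eg$edges[r, 1]; j <- eg$edges[r, 2]
    D[i, j] <- D[j, i] <- min(D[i, j], eg$lengths[r])
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# dense lookup matrix from a sparse_dist (NA where absent)
dense_dist <- function(sd) {
  D <- matrix(NA_real_, sd$n_vertices, sd$n_vertices)
  D[cbind(sd$i, sd$j)] <- sd$d
  D[cbind(sd$j, sd$i)] <- sd$d
  D
}

# brute-force DCBC / ACD by explicit pair enumeration (double loop)
brute_dcbc <- function(profiles, parc, dist, bin_width, max_dist) {
  D <- dense_dist(dist)
  labels <- unclass(parc)
  n <- length(labels)
  n_bins <- ceiling(max_dist / bin_width)
  nw <- nb <- sw <- sb <- numeric(n_bins)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- D[i, j]
    if (is.na(d) || d > max_dist) next
    if (labels[i] == 0 || labels[j] == 0) next
    if (!profiles$valid[i] || !profiles$valid[j]) next
    r <- stats::cor(profiles$values[i, ], profiles$values[j, ])
    b <- ceiling(d / bin_width)
    if (labels[i] == labels[j]) {
      nw[b] <- nw[b] + 1; sw[b] <- sw[b] + r
    } else {
      nb[b] <- nb[b] + 1; sb[b] <- sb[b] + r
    }
  }
  ok <- nw > 0 & nb > 0
  di <- sw[ok] / nw[ok] - sb[ok] / nb[ok]
  prec <- nw[ok] * nb[ok] / (nw[ok] + nb[ok])
  w <- prec / sum(prec)
  list(weighted = sum(w * di), unweighted = mean(di),
       acd = sum(sw) / sum(nw) - sum(sb) / sum(nb),
       n_within = nw, n_between = nb)
}

brute_homogeneity <- function(profiles, parc) {
  labels <- unclass(parc)
  vals <- c()
  for (k in sort(unique(labels[labels > 0]))) {
    idx <- which(labels == k & profiles$valid)
    if (length(idx) < 2) next
    rs <- c()
    for (a in seq_along(idx)[-length(idx)])
      for (b in (a + 1):length(idx))
        rs <- c(rs, stats::cor(profiles$values[idx[a], ],
                               profiles$values[idx[b], ]))
    vals <- c(vals, mean(rs))
  }
  mean(vals)
}

brute_silhouette <- function(profiles, parc, mesh) {
  labels <- unclass(parc)
  adj <- parcel_adjacency(parc, mesh)
  s <- rep(NA_real_, length(labels))
  for (i in seq_along(labels)) {
    if (labels[i] == 0 || !profiles$valid[i]) next
    own <- which(labels == labels[i] & profiles$valid)
    own <- setdiff(own, i)
    if (!length(own)) next
    nb <- adj[[as.character(labels[i])]]
    others <- which(labels %in% nb & profiles$valid)
    if (!length(others)) next
    wi <- mean(sapply(own, function(j)
      1 - stats::cor(profiles$values[i, ], profiles$values[j, ])))
    bi <- mean(sapply(others, function(j)
      1 - stats::cor(profiles$values[i, ], profiles$values[j, ])))
    s[i] <- (bi - wi) / max(wi, bi)
  }
  list(values = s, mean = mean(s, na.rm = TRUE))
}
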