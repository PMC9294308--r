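test_that("pairwise correlation is Pearson across conditions", {
  pr <- functional_profiles(rbind(c(1, 2, 3), c(1, 3, 2), c(3, 2, 1),
                                  c(2, 4, 6)))
  expect_equal(pairwise_correlation(pr, 1, 4), 1)      # identical shape
  expect_equal(pairwise_correlation(pr, 1, 3), -1)     # negation
  expect_equal(pairwise_correlation(pr, 1, 2), 0.5)    # hand-computed
  pr2 <- functional_profiles(rbind(c(1, 2, 3), c(5, 5, 5)))
  expect_false(pr2$valid[2])                           # zero variance
  expect_error(pairwise_correlation(pr2, 1, 2), "masked")
})

test_that("pairs are binned half-open with boundary in the lower bin", {
  parc <- parcellation(c(1L, 1L, 2L, 2L))
  d <- sparse_dist(c(1, 1, 3), c(2, 3, 4), c(0.5, 1.0, 1.2),
                   cutoff = 10, n_vertices = 4)
  bp <- classify_and_bin_pairs(parc, d, bin_width = 1, max_dist = 3)
  expect_equal(bp$n_within[1], 1)    # d = 0.5, within (1,1)
  expect_equal(bp$n_between[1], 1)   # d = 1.0 exactly -> bin 1
  expect_equal(bp$n_within[2], 1)    # d = 1.2, within (2,2)
  # vertex labelled 0 excluded from all counts
  parc0 <- parcellation(c(1L, 1L, 0L, 2L))
  bp0 <- classify_and_bin_pairs(parc0, d, bin_width = 1, max_dist = 3)
  expect_equal(sum(bp0$n_within + bp0$n_between), 1)
  expect_error(classify_and_bin_pairs(parc, d, max_dist = 50), "cutoff")
})

test_that("bin counts equal exhaustive enumeration on a toy mesh", {
  mesh <- jittered_mesh(2, seed = 21)
  d <- geodesic_distances(mesh, cutoff = 20)
  parc <- parcellation(rep_len(1:4, n_vertices(mesh)))
  set.seed(22)
  pr <- functional_profiles(matrix(rnorm(n_vertices(mesh) * 6), ncol = 6))
  oracle <- brute_dcbc(pr, parc, d, bin_width = 4, max_dist = 16)
  bp <- classify_and_bin_pairs(parc, d, bin_width = 4, max_dist = 16)
  expect_equal(bp$n_within, oracle$n_within)
  expect_equal(bp$n_between, oracle$n_between)
})

test_that("precision weights follow the inverse-variance formula", {
  w <- compute_weights(c(2, 8), c(2, 8))
  expect_equal(w$weights, c(0.2, 0.8))   # precisions 1 and 4
  w2 <- compute_weights(c(5, 5, 5), c(3, 3, 3))
  expect_equal(w2$weights, rep(1 / 3, 3))
  w3 <- compute_weights(c(4, 0), c(4, 5))
  expect_equal(w3$weights, 1)
  expect_equal(w3$excluded, 2L)
  expect_error(compute_weights(c(0, 0), c(1, 1)), "impossible")
})

test_that("DCBC equals a full hand enumeration on small fixtures", {
  mesh <- jittered_mesh(2, seed = 31)
  d <- geodesic_distances(mesh, cutoff = 25)
  set.seed(32)
  n <- n_vertices(mesh)
  pr <- functional_profiles(matrix(rnorm(n * 8), ncol = 8))
  parc <- parcellation(1L + (seq_len(n) %% 3L))
  res <- compute_dcbc(pr, parc, d, bin_width = 5, max_dist = 20)
  oracle <- brute_dcbc(pr, parc, d, bin_width = 5, max_dist = 20)
  expect_equal(res$dcbc, oracle$weighted, tolerance = 1e-12)
  expect_equal(res$dcbc_unweighted, oracle$unweighted, tolerance = 1e-12)
  # invariants of the returned object
  w <- res$binned$weight[res$binned$included]
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_equal(res$dcbc,
               sum(w * res$binned$d[res$binned$included]),
               tolerance = 1e-12)
})

test_that("a shared profile at all vertices gives zero DCBC and ACD", {
  mesh <- geodesic_sphere(3, radius = 100)
  d <- geodesic_distances(mesh, cutoff = 60)
  common <- matrix(rep(c(1, 3, 2, 5), each = n_vertices(mesh)), ncol = 4)
  pr <- functional_profiles(common)
  parc <- icosahedron_parcellation(mesh, 12)
  res <- compute_dcbc(pr, parc, d, bin_width = 10, max_dist = 50)
  expect_equal(res$dcbc, 0, tolerance = 1e-12)
  expect_equal(unbinned_acd(pr, parc, d, max_dist = 50), 0,
               tolerance = 1e-12)
})

test_that("single-parcel input signals an evaluation-impossible error", {
  mesh <- geodesic_sphere(2, radius = 100)
  d <- geodesic_distances(mesh, cutoff = 60)
  set.seed(5)
  pr <- functional_profiles(matrix(rnorm(42 * 5), ncol = 5))
  expect_error(compute_dcbc(pr, parcellation(rep(1L, 42)), d),
               "impossible")
  expect_error(unbinned_acd(pr, parcellation(rep(1L, 42)), d, 35),
               "impossible")
})

test_that("unbinned ACD equals single-bin DCBC and brute enumeration", {
  mesh <- jittered_mesh(2, seed = 41)
  d <- geodesic_distances(mesh, cutoff = 25)
  set.seed(42)
  n <- n_vertices(mesh)
  pr <- functional_profiles(matrix(rnorm(n * 8), ncol = 8))
  parc <- parcellation(1L + (seq_len(n) %% 4L))
  acd <- unbinned_acd(pr, parc, d, max_dist = 20)
  one_bin <- compute_dcbc(pr, parc, d, bin_width = 20, max_dist = 20)
  expect_equal(acd, one_bin$dcbc)
  expect_equal(one_bin$binned$weight[one_bin$binned$included], 1)
  expect_equal(acd, brute_dcbc(pr, parc, d, 20, 20)$acd,
               tolerance = 1e-12)
})

test_that("homogeneity averages within-parcel correlations across parcels", {
  # two parcels with known internal mean correlations average unweighted
  pr <- functional_profiles(rbind(
    c(1, 2, 3), c(1, 2, 3),          # parcel 1: r = 1
    c(1, 3, 2), c(2, 6, 4), c(3, 2, 1)))  # parcel 2: rs = 1, -0.5, -0.5
  parc <- parcellation(c(1L, 1L, 2L, 2L, 2L))
  expect_equal(compute_homogeneity(pr, parc), mean(c(1, 0)))

  same <- functional_profiles(matrix(rep(c(2, 5, 3, 7), each = 6),
                                     ncol = 4))
  expect_equal(compute_homogeneity(same, parcellation(rep(1:2, 3))), 1)

  mesh <- jittered_mesh(2, seed = 51)
  set.seed(52)
  n <- n_vertices(mesh)
  prn <- functional_profiles(matrix(rnorm(n * 7), ncol = 7))
  parcn <- parcellation(1L + (seq_len(n) %% 5L))
  expect_equal(compute_homogeneity(prn, parcn),
               brute_homogeneity(prn, parcn), tolerance = 1e-12)
})

test_that("silhouette matches its formula, oracle and range", {
  mesh <- geodesic_sphere(4, radius = 100)
  n <- n_vertices(mesh)
  set.seed(61)
  pr <- functional_profiles(matrix(rnorm(n * 6), ncol = 6))
  parc <- icosahedron_parcellation(mesh, 12)
  sil <- compute_silhouette(pr, parc, mesh = mesh)
  oracle <- brute_silhouette(pr, parc, mesh)
  expect_equal(sil$values, oracle$values, tolerance = 1e-10)
  expect_equal(sil$mean, oracle$mean, tolerance = 1e-10)

  # S in [-1, 1]: dissimilarity 1 - R is non-negative, so the normalised
  # contrast is bounded
  ok <- !is.na(sil$values)
  expect_true(all(sil$values[ok] <= 1 + 1e-12))
  expect_true(all(sil$values[ok] >= -1 - 1e-12))

  # perfect within-correlation (R = 1), zero between-correlation -> S = 1
  tiny <- two_triangles()
  two <- parcellation(c(1L, 1L, 2L, 2L))
  u <- c(1, 2, 3)          # centred (-1, 0, 1)
  v <- c(2, -1, 2)         # centred (1, -2, 1), orthogonal to u
  prs <- functional_profiles(rbind(u, u, v, v))
  sil1 <- compute_silhouette(prs, two, mesh = tiny)
  expect_equal(sil1$values, rep(1, 4))
})

test_that("singleton parcels are skipped and reported by silhouette", {
  mesh <- geodesic_sphere(2, radius = 100)
  labels <- unclass(icosahedron_parcellation(mesh, 12))
  labels[1] <- 13L   # singleton parcel
  set.seed(62)
  pr <- functional_profiles(matrix(rnorm(42 * 5), ncol = 5))
  sil <- compute_silhouette(pr, parcellation(labels), mesh = mesh)
  expect_true(is.na(sil$values[1]))
  expect_gte(sil$n_skipped, 1)
})

test_that("group summary gives mean, SE and one-sample t against zero", {
  g <- group_summary(c(0.1, 0.2, 0.3))
  expect_equal(g$mean, 0.2)
  expect_equal(g$se, sd(c(0.1, 0.2, 0.3)) / sqrt(3))
  expect_equal(g$se, 0.05773503, tolerance = 1e-6)
  expect_equal(g$t, g$mean / g$se)
  z <- group_summary(c(0, 0, 0))
  expect_equal(z$mean, 0); expect_equal(z$t, 0)
  degen <- group_summary(c(1, 1, 1, 1))
  expect_equal(degen$se, 0)
  expect_true(is.infinite(degen$t))
  expect_equal(degen$p, 0)
  expect_error(group_summary(1), "at least 2")
})

test_that("subject evaluation averages hemispheres with equal weight", {
  mesh <- geodesic_sphere(4, radius = 100)
  d <- geodesic_distances(mesh, cutoff = 50)
  parc <- icosahedron_parcellation(mesh, 42)
  h1 <- list(profiles = random_smooth_map(mesh, smoothing_spec(3),
                                          n_conditions = 8, seed = 71),
             parcellation = parc, dist = d)
  h2 <- list(profiles = random_smooth_map(mesh, smoothing_spec(3),
                                          n_conditions = 8, seed = 72),
             parcellation = parc, dist = d)
  v1 <- evaluate_subject(h1, bin_width = 2.5)
  v2 <- evaluate_subject(h2, bin_width = 2.5)
  both <- evaluate_subject(h1, h2, bin_width = 2.5)
  expect_equal(both, mean(c(v1, v2)))
  expect_equal(evaluate_subject(h1, h1, bin_width = 2.5), v1)
})

test_that("criteria are invariant to condition permutation and affine rescaling", {
  mesh <- jittered_mesh(2, seed = 81)
  d <- geodesic_distances(mesh, cutoff = 25)
  n <- n_vertices(mesh)
  set.seed(82)
  vals <- matrix(rnorm(n * 9), ncol = 9)
  parc <- parcellation(1L + (seq_len(n) %% 4L))
  pr <- functional_profiles(vals)
  base <- compute_dcbc(pr, parc, d, bin_width = 5, max_dist = 20)

  perm <- functional_profiles(vals[, sample(9)])
  scaled <- functional_profiles(vals * runif(n, 0.5, 3) +
                                  rnorm(n))   # per-vertex affine
  for (variant in list(perm, scaled)) {
    v <- compute_dcbc(variant, parc, d, bin_width = 5, max_dist = 20)
    expect_equal(v$dcbc, base$dcbc, tolerance = 1e-10)
    expect_equal(compute_homogeneity(variant, parc),
                 compute_homogeneity(pr, parc), tolerance = 1e-10)
    expect_equal(compute_silhouette(variant, parc, mesh = mesh)$mean,
                 compute_silhouette(pr, parc, mesh = mesh)$mean,
                 tolerance = 1e-10)
  }
})
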