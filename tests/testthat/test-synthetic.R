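test_that("white noise maps are seeded, centred and uncorrelated", {
  mesh <- geodesic_sphere(4, radius = 100)
  a <- white_noise_map(mesh, n_conditions = 10, seed = 3)
  b <- white_noise_map(mesh, n_conditions = 10, seed = 3)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values,
                         white_noise_map(mesh, 10, seed = 4)$values))
  n <- n_vertices(mesh)
  expect_true(all(abs(colMeans(a$values)) < 4 / sqrt(n)))
  # mean off-diagonal profile correlation near zero
  cm <- stats::cor(t(a$values))
  off <- cm[upper.tri(cm)]
  expect_lt(abs(mean(off)), 3 * stats::sd(off) / sqrt(length(off)) + 0.02)
})

test_that("smoothing is the identity at 0 iterations and fixes constants", {
  mesh <- geodesic_sphere(3, radius = 100)
  set.seed(8)
  pr <- functional_profiles(matrix(rnorm(n_vertices(mesh) * 5), ncol = 5))
  expect_equal(smooth_on_mesh(mesh, pr, smoothing_spec(0))$values,
               pr$values)
  const <- functional_profiles(matrix(rep(c(1, 5, 2, 4, 3),
                                          each = n_vertices(mesh)),
                                      ncol = 5))
  sm <- smooth_on_mesh(mesh, const, smoothing_spec(7))
  expect_equal(sm$values, const$values, tolerance = 1e-12)
  expect_error(smoothing_spec(-1), "non-negative")
  expect_error(smoothing_spec(2, self_weight = 1.5), "\\[0, 1\\]")
})

test_that("smoothing contracts per-condition variance", {
  mesh <- geodesic_sphere(5, radius = 100)
  pr <- white_noise_map(mesh, n_conditions = 6, seed = 13)
  v_prev <- apply(pr$values, 2, var)
  for (k in c(1, 2, 4, 8)) {
    v <- apply(smooth_on_mesh(mesh, pr, smoothing_spec(k))$values, 2, var)
    expect_true(all(v <= v_prev + 1e-12))
    v_prev <- v
  }
})

test_that("smoothing commutes with condition permutation and sign flip", {
  mesh <- geodesic_sphere(3, radius = 100)
  pr <- white_noise_map(mesh, n_conditions = 6, seed = 17)
  sm <- smooth_on_mesh(mesh, pr, smoothing_spec(5))
  perm <- c(4, 1, 6, 2, 5, 3)
  sm_perm <- smooth_on_mesh(
    mesh, functional_profiles(pr$values[, perm]), smoothing_spec(5))
  expect_equal(sm_perm$values, sm$values[, perm], tolerance = 1e-12)
  sm_neg <- smooth_on_mesh(
    mesh, functional_profiles(-pr$values), smoothing_spec(5))
  expect_equal(sm_neg$values, -sm$values, tolerance = 1e-12)
})

test_that("autocorrelation decays under smoothing and is 1 for shared profiles", {
  mesh <- geodesic_sphere(8, radius = 100)
  dist <- sphere_arc_distances(mesh, cutoff = 36)
  noise <- white_noise_map(mesh, n_conditions = 20, seed = 23)
  ac0 <- autocorrelation_curve(noise, dist, bin_width = 5, max_dist = 35)
  ok <- !is.na(ac0$correlation)
  expect_true(all(abs(ac0$correlation[ok]) < 0.1))

  sm <- smooth_on_mesh(mesh, noise, smoothing_spec(16))
  ac <- autocorrelation_curve(sm, dist, bin_width = 5, max_dist = 35)
  first <- which(!is.na(ac$correlation))[1]
  last <- rev(which(!is.na(ac$correlation)))[1]
  expect_gt(ac$correlation[first], ac$correlation[last])

  shared <- functional_profiles(
    matrix(rep(c(1, 3, 2, 5), each = n_vertices(mesh)), ncol = 4))
  ac1 <- autocorrelation_curve(shared, dist, bin_width = 5, max_dist = 35)
  ok1 <- !is.na(ac1$correlation)
  expect_equal(ac1$correlation[ok1], rep(1, sum(ok1)))
})

test_that("heavy smoothing drives short-range correlation towards 1", {
  mesh <- geodesic_sphere(8, radius = 100)
  dist <- sphere_arc_distances(mesh, cutoff = 36)
  sm <- random_smooth_map(mesh, smoothing_spec(64), n_conditions = 20,
                          seed = 29)
  ac <- autocorrelation_curve(sm, dist, bin_width = 2, max_dist = 30)
  first <- which(!is.na(ac$correlation))[1]
  expect_gt(ac$correlation[first], 0.9)
})

test_that("calibration finds the smallest sufficient iteration count", {
  mesh <- geodesic_sphere(8, radius = 100)
  dist <- sphere_arc_distances(mesh, cutoff = 36)
  spec <- calibrate_smoothing(mesh, dist, target_half_distance = 12,
                              seed = 31, n_conditions = 20)
  expect_gte(attr(spec, "half_distance"), 12)
  # one fewer iteration misses the target: realised curve check
  if (spec$n_iterations > 1) {
    prev <- random_smooth_map(mesh, smoothing_spec(spec$n_iterations - 1L),
                              n_conditions = 20, seed = 31)
    hd_prev <- half_distance(
      autocorrelation_curve(prev, dist, bin_width = 1, max_dist = 35))
    expect_lt(hd_prev, 12)
  }
  # determinism
  spec2 <- calibrate_smoothing(mesh, dist, target_half_distance = 12,
                               seed = 31, n_conditions = 20)
  expect_equal(spec$n_iterations, spec2$n_iterations)
  # unreachable target errors with diagnostics
  expect_error(calibrate_smoothing(mesh, dist, target_half_distance = 34,
                                   seed = 31, n_conditions = 8,
                                   max_iterations = 4),
               "calibration failed")
  expect_error(calibrate_smoothing(mesh, dist, target_half_distance = 40,
                                   seed = 1), "must lie in")
})
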