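test_that("LV geometry matches its analytic construction", {
  ph <- small_phantom()
  spec <- ph$spec
  geom <- ph$geom

  # annular wall volume on cavity slices vs analytic annulus volume
  n_ann <- sum(geom$mask[, , geom$cavity_slices])
  vol_analytic <- pi * (spec$r_outer^2 - spec$r_inner^2) *
    spec$n_cavity_slices * spec$voxel_size
  n_expected <- vol_analytic / spec$voxel_size^3
  expect_lt(abs(n_ann - n_expected) / n_expected, 0.05)

  # depth is 0.5 (within half a voxel) on the mid-wall ring
  r_mid <- (spec$r_inner + spec$r_outer) / 2
  z <- geom$cavity_slices[3]
  idx <- which(geom$mask[, , z], arr.ind = TRUE)
  r <- sqrt((idx[, 1] - geom$centers[z, 1])^2 +
              (idx[, 2] - geom$centers[z, 2])^2) * spec$voxel_size
  on_mid <- abs(r - r_mid) < spec$voxel_size / 2
  d <- geom$depth[, , z][geom$mask[, , z]][on_mid]
  half_voxel_depth <- 0.5 * spec$voxel_size / (spec$r_outer - spec$r_inner)
  expect_true(all(abs(d - 0.5) <= half_voxel_depth + 1e-12))

  # wall thinner than a voxel is rejected
  expect_error(make_lv_geometry(small_spec(r_inner = 13.9, r_outer = 14)),
               "degenerate wall")
  expect_error(small_spec(r_inner = 14, r_outer = 14), "r_outer > r_inner")
})

test_that("fiber field realizes the helix rule with orthonormal triads", {
  ph <- small_phantom()
  fib <- ph$fibers
  m <- fib$valid
  e <- lapply(list(fib$e1, fib$e2, fib$e3), function(a)
    sapply(1:3, function(k) a[, , , k][m]))

  for (i in 1:3)
    expect_lt(max(abs(sqrt(rowSums(e[[i]]^2)) - 1)), 1e-10)
  expect_lt(max(abs(rowSums(e[[1]] * e[[2]]))), 1e-10)
  expect_lt(max(abs(rowSums(e[[1]] * e[[3]]))), 1e-10)
  expect_lt(max(abs(rowSums(e[[2]] * e[[3]]))), 1e-10)

  # the helix angle recomputed from E1 reproduces the linear rule at every
  # voxel: +60 at depth 0, 0 at depth 0.5, -60 at depth 1
  ha <- helix_angle(fib$e1, ph$geom)
  rule <- 60 - 120 * ph$geom$depth
  expect_lt(max(abs(ha$ha[ha$valid] - rule[ha$valid])), 0.5)
})

test_that("constructed tensors have the prescribed invariants", {
  ph <- small_phantom()
  m <- ph$tensors$valid
  d6 <- sapply(1:6, function(k) ph$tensors$d[, , , k][m])

  # FA and ADC of the default eigenvalue triple (hand-evaluated closed
  # forms: FA = sqrt(1.5 * 0.2016667 / 1.405), ADC = 1.9e-3 / 3)
  expect_equal(compute_fa(ph$spec$evals), 0.4640070, tolerance = 1e-6)
  expect_equal(compute_adc(ph$spec$evals), 1.9e-3 / 3, tolerance = 1e-12)
  eig <- eigendecompose(ph$tensors)
  lam <- sapply(1:3, function(k) eig$values[, , , k][m])
  expect_lt(max(abs(lam[, 1] - ph$spec$evals[1])), 1e-15)
  expect_lt(max(abs(lam[, 3] - ph$spec$evals[3])), 1e-15)

  # an isotropic eigenvalue triple gives D = d I exactly
  iso <- small_spec(evals = rep(1e-3, 3))
  tf <- make_tensor_field(ph$fibers, iso)
  di <- sapply(1:6, function(k) tf$d[, , , k][tf$valid])
  expect_lt(max(abs(di[, 1:3] - 1e-3)), 1e-18)
  expect_lt(max(abs(di[, 4:6])), 1e-18)

  expect_error(make_tensor_field(ph$fibers,
                                 small_spec(evals = c(1, 0.5, -0.1) * 1e-3)),
               "positive")
})

test_that("simulated signals follow the Stejskal-Tanner model", {
  ph <- small_phantom()
  iso_spec <- small_spec(evals = rep(1e-3, 3))
  iso <- make_tensor_field(ph$fibers, iso_spec)
  proto <- small_protocol()
  dwi <- simulate_dwi(iso, proto, noise_model("none"), s0 = 100)

  m <- iso$valid
  b0 <- dwi$data[, , , 1][m]
  expect_true(all(b0 == 100))                 # b = 0 volumes are exactly S0
  for (j in proto$n_b0 + c(1L, 17L, 35L - proto$n_b0)) {
    s <- dwi$data[, , , j][m]
    expect_equal(max(abs(s / 100 - exp(-0.7))), 0, tolerance = 1e-12)
  }
})

test_that("noiseless simulate -> fit roundtrip is exact", {
  ph <- small_phantom()
  nf <- small_noiseless_fit()
  scale <- max(abs(ph$tensors$d), na.rm = TRUE)
  err <- abs(nf$fit$d - ph$tensors$d) / scale
  expect_lt(max(err, na.rm = TRUE), 1e-9)
  expect_true(all(nf$fit$valid == ph$tensors$valid))
})

test_that("replicate stacks are reproducible and validated", {
  s0 <- array(50, c(12, 12, 2))
  none <- simulate_replicate_stack(s0, noise_model("none"), n_rep = 5)
  expect_true(all(none == 50))

  a <- simulate_replicate_stack(s0, noise_model("rician", 40, seed = 3), 4)
  b <- simulate_replicate_stack(s0, noise_model("rician", 40, seed = 3), 4)
  expect_identical(a, b)
  expect_false(identical(a[, , , 1], a[, , , 2]))

  expect_error(simulate_replicate_stack(s0, noise_model("none"), 1), ">= 2")
})

test_that("Rician noise bias is small at moderate SNR", {
  # at target SNR >= 20 the Rician mean exceeds truth by < 1 %
  s0 <- array(100, c(40, 40, 10))
  st <- simulate_replicate_stack(s0, noise_model("rician", 20, seed = 9), 30)
  bias <- mean(st) / 100 - 1
  expect_gt(bias, 0)
  expect_lt(bias, 0.01)
})

test_that("direction tables are well-spread, unit norm and deterministic", {
  g6 <- generate_directions(6, seed = 4)
  expect_lt(g6$condition_number, 10)
  expect_lt(max(abs(sqrt(rowSums(g6$directions^2)) - 1)), 1e-8)

  g30 <- generate_directions(30, seed = 4)
  expect_identical(g30$directions, generate_directions(30, seed = 4)$directions)
  expect_lt(max(abs(sqrt(rowSums(g30$directions^2)) - 1)), 1e-8)

  # repulsion beats random placement in minimum angular separation
  min_sep_random <- function(seed) {
    set.seed(seed)
    v <- matrix(stats::rnorm(90), ncol = 3)
    v <- v / sqrt(rowSums(v^2))
    co <- abs(v %*% t(v)); diag(co) <- 0
    min(acos(pmin(1, co[upper.tri(co)]))) * 180 / pi
  }
  random_med <- stats::median(vapply(1:100, min_sep_random, numeric(1)))
  expect_gt(g30$min_separation, random_med)

  expect_error(generate_directions(5), "underdetermined")
})

test_that("relaxometry simulation inverts exactly when noiseless", {
  tes <- seq(2.07, 18, length.out = 9)
  sim <- simulate_relaxometry(array(1000, c(6, 6)), array(20.45, c(6, 6)),
                              flip_angles = c(15, 30, 45), tes = tes, tr = 10)
  t2 <- fit_t2star(sim$echo_series, tes)
  expect_lt(max(abs(t2$t2star - 20.45) / 20.45), 1e-3)
  t1 <- fit_despot1(sim$vfa_series, c(15, 30, 45), tr = 10)
  expect_lt(max(abs(t1$t1 - 1000) / 1000), 1e-3)

  expect_error(simulate_relaxometry(1000, 20, c(15, 30), tes, tr = 0), "TR")
  expect_error(simulate_relaxometry(1000, 20, c(0, 30), tes, tr = 10),
               "flip angles")
})

test_that("EPI distortion shifts along phase encode as modelled", {
  vol <- array(0, c(8, 16, 2))
  vol[4, 8, ] <- 1
  proto <- acquisition_protocol(n_directions = 6, seed = 1,
                                bandwidth_pe = 1000, accel = 1)

  expect_identical(apply_epi_distortion(vol, 0, proto), vol)

  shifted <- apply_epi_distortion(vol, 100, proto)   # 0.1 pixel
  expect_equal(shifted[4, 8, 1], 0.9, tolerance = 1e-12)
  expect_equal(shifted[4, 9, 1], 0.1, tolerance = 1e-12)

  proto2 <- acquisition_protocol(n_directions = 6, seed = 1,
                                 bandwidth_pe = 1000, accel = 2)
  half <- apply_epi_distortion(vol, 100, proto2)     # 0.05 pixel
  expect_equal(half[4, 9, 1], 0.05, tolerance = 1e-12)
})
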