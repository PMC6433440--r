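# Shared fixtures, built once per test run and cached.
#
# The "small" phantom keeps unit tests fast; the "study" phantom uses the
# full default geometry (1.3 mm voxels, 30 cavity slices, 4 cap slices)
# and the reference acquisition (b = 700, 30 directions + 5 b = 0).

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

small_spec <- function(...) {
  args <- utils::modifyList(
    list(dims = c(32L, 32L, 13L), voxel_size = 1.3,
         r_inner = 8, r_outer = 14,
         n_cavity_slices = 9L, n_cap_slices = 2L),
    list(...))
  do.call(phantom_spec, args)
}

small_phantom <- function() fixture("small_phantom", function() {
  spec <- small_spec()
  geom <- make_lv_geometry(spec)
  fibers <- make_fiber_field(geom, spec)
  tensors <- make_tensor_field(fibers, spec)
  list(spec = spec, geom = geom, fibers = fibers, tensors = tensors)
})

small_protocol <- function() fixture("small_protocol", function()
  acquisition_protocol(seed = 2L))

# noiseless simulate -> fit -> eigendecompose on the small phantom
small_noiseless_fit <- function() fixture("small_noiseless_fit", function() {
  ph <- small_phantom()
  dwi <- simulate_dwi(ph$tensors, small_protocol(), noise_model("none"))
  fit <- fit_tensor(dwi)
  eig <- eigendecompose(fit)
  list(dwi = dwi, fit = fit, eig = eig)
})

# full-size phantom with the default helix rule, Rician noise at SNR 40
study_noisy_run <- function() fixture("study_noisy_run", function() {
  spec <- phantom_spec()
  geom <- make_lv_geometry(spec)
  fibers <- make_fiber_field(geom, spec)
  tensors <- make_tensor_field(fibers, spec)
  dwi <- simulate_dwi(tensors, acquisition_protocol(seed = 2L),
                      noise_model("rician", snr = 40, seed = 11L))
  fit <- fit_tensor(dwi)
  eig <- eigendecompose(fit)
  fa <- compute_fa(eig$values)
  keep <- fa_mask(fa)
  ha <- helix_angle(eig$vectors[, , , , 1], geom, valid = keep)
  seg <- aha_segment(geom)
  list(spec = spec, geom = geom, fibers = fibers, fit = fit, eig = eig,
       fa = fa, keep = keep, ha = ha, seg = seg)
})

# random symmetric positive-definite tensor, eigenvalues ~ U[lo, hi]
random_spd_tensor <- function(lo = 0.2e-3, hi = 2e-3) {
  lam <- sort(stats::runif(3, lo, hi), decreasing = TRUE)
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  d <- q %*% diag(lam) %*% t(q)
  list(d = d, dbar = c(d[1, 1], d[2, 2], d[3, 3], d[1, 2], d[1, 3], d[2, 3]),
       lambda = lam, q = q)
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
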