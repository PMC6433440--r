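#' Generate the myocyte orientation (eigenvector) fields of the phantom
#'
#' At every myocardial voxel the primary direction `E1` is placed in the
#' wall-tangent plane (spanned by the local circumferential and longitudinal
#' axes) at the helix angle prescribed by the linear transmural rule of the
#' phantom spec.  The secondary direction `E2` is placed at the prescribed
#' secondary eigenvector angle (E2A) within the cross-myocyte plane
#' perpendicular to `E1`, and `E3 = E1 x E2` completes a right-handed
#' orthonormal triad.
#'
#' @param geom an `lv_geometry` from [make_lv_geometry()].
#' @param spec the [phantom_spec()] that produced `geom` (defaults to the
#'   spec stored in `geom`).
#' @return list with `e1`, `e2`, `e3` (arrays `dim(mask) x 3`), the true
#'   `helix_angle` and `e2a` maps (degrees), and `valid` (logical array;
#'   voxels with an undefined local frame are flagged).
#' @export
make_fiber_field <- function(geom, spec = geom$spec) {
  stopifnot(inherits(geom, "lv_geometry"), inherits(spec, "phantom_spec"))
  if (!identical(dim(geom$mask), spec$dims))
    stop("geometry and spec do not share a grid")
  mask <- geom$mask & geom$frame_valid
  dims <- dim(geom$mask)
  n <- sum(mask)
  pick <- function(a) {
    m <- matrix(NA_real_, n, 3)
    for (k in 1:3) m[, k] <- a[, , , k][mask]
    m
  }
  ec <- pick(geom$frames$e_c)
  el <- pick(geom$frames$e_l)
  er <- pick(geom$frames$e_r)
  depth <- geom$depth[mask]

  ha <- spec$ha_endo + (spec$ha_epi - spec$ha_endo) * depth
  e2a <- if (is.function(spec$e2a)) spec$e2a(depth) else rep(spec$e2a, n)

  har <- deg2rad(ha)
  e1 <- cos(har) * ec + sin(har) * el
  # cross-myocyte direction: in-wall-tangent-plane normal to E1
  xhat <- row_unit(row_cross(er, e1))
  rhat <- row_cross(e1, xhat)           # radially oriented, normal to E1
  e2ar <- deg2rad(e2a)
  e2 <- cos(e2ar) * xhat + sin(e2ar) * rhat
  e3 <- row_cross(e1, e2)

  to_field <- function(m) {
    a <- array(NA_real_, c(dims, 3))
    for (k in 1:3) {
      v <- array(NA_real_, dims)
      v[mask] <- m[, k]
      a[, , , k] <- v
    }
    a
  }
  ha_map <- array(NA_real_, dims); ha_map[mask] <- ha
  e2a_map <- array(NA_real_, dims); e2a_map[mask] <- e2a
  list(e1 = to_field(e1), e2 = to_field(e2), e3 = to_field(e3),
       helix_angle = ha_map, e2a = e2a_map, valid = mask)
}

#' Assemble the per-voxel diffusion tensor field of the phantom
#'
#' Builds `D = lambda1 E1 E1' + lambda2 E2 E2' + lambda3 E3 E3'` at every
#' valid voxel, stored in the 6-component lower-triangular convention
#' (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz).
#'
#' @param fibers fiber field from [make_fiber_field()].
#' @param spec a [phantom_spec()] supplying the eigenvalue triple.
#' @return an object of class `tensor_field`: list with `d` (array
#'   `dims x 6`, mm^2/s), `valid` (logical array), `dims`.
#' @export
make_tensor_field <- function(fibers, spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (any(spec$evals <= 0)) stop("eigenvalues must be strictly positive")
  mask <- fibers$valid
  dims <- dim(mask)
  n <- sum(mask)
  pick <- function(a) {
    m <- matrix(NA_real_, n, 3)
    for (k in 1:3) m[, k] <- a[, , , k][mask]
    m
  }
  ev <- list(pick(fibers$e1), pick(fibers$e2), pick(fibers$e3))
  d6 <- matrix(0, n, 6)
  for (i in 1:3) {
    v <- ev[[i]]
    lam <- spec$evals[i]
    d6[, 1] <- d6[, 1] + lam * v[, 1]^2
    d6[, 2] <- d6[, 2] + lam * v[, 2]^2
    d6[, 3] <- d6[, 3] + lam * v[, 3]^2
    d6[, 4] <- d6[, 4] + lam * v[, 1] * v[, 2]
    d6[, 5] <- d6[, 5] + lam * v[, 1] * v[, 3]
    d6[, 6] <- d6[, 6] + lam * v[, 2] * v[, 3]
  }
  d <- array(NA_real_, c(dims, 6))
  for (k in 1:6) {
    v <- array(NA_real_, dims)
    v[mask] <- d6[, k]
    d[, , , k] <- v
  }
  structure(list(d = d, valid = mask, dims = dims), class = "tensor_field")
}

#' Simulate a diffusion-weighted acquisition of a tensor field
#'
#' Evaluates the Stejskal-Tanner signal `S_k = S0 exp(-b g_k' D g_k)` for
#' every gradient direction and appends the requested number of b = 0
#' reference volumes, then applies the configured magnitude noise.
#' Background voxels contain pure noise (zero signal plus the noise model's
#' magnitude noise).
#'
#' @param tensors a `tensor_field` (e.g. from [make_tensor_field()]).
#' @param protocol an [acquisition_protocol()].
#' @param noise a [noise_model()].
#' @param s0 noiseless b = 0 signal amplitude on the myocardium.
#' @param voxel_size voxel edge length in mm recorded with the dataset.
#' @return an object of class `dwi_dataset`: list with `data` (4-D array,
#'   b = 0 volumes first), `bvals`, `bvecs` (3 x K, FSL convention, zero
#'   columns for b = 0), `mask`, `voxel_size`, `protocol`.
#' @export
simulate_dwi <- function(tensors, protocol, noise = noise_model("none"),
                         s0 = 100, voxel_size = 1.3) {
  stopifnot(inherits(tensors, "tensor_field"),
            inherits(protocol, "acquisition_protocol"))
  dims <- tensors$dims
  mask <- tensors$valid
  n <- sum(mask)
  d6 <- matrix(NA_real_, n, 6)
  for (k in 1:6) d6[, k] <- tensors$d[, , , k][mask]

  g <- protocol$directions
  # quadratic form g' D g expressed through the 6-component tensor
  gbar <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
                2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3],
                2 * g[, 2] * g[, 3])
  expo <- -protocol$bvalue * (d6 %*% t(gbar))    # n x n_dir
  if (any(expo > 700)) {
    warning("signal exponent overflow; clipping")
    expo[expo > 700] <- 700
  }
  sig <- s0 * exp(expo)

  n_vol <- protocol$n_b0 + protocol$n_directions
  data <- array(0, c(dims, n_vol))
  for (j in seq_len(protocol$n_b0)) {
    v <- array(0, dims); v[mask] <- s0
    data[, , , j] <- v
  }
  for (j in seq_len(protocol$n_directions)) {
    v <- array(0, dims); v[mask] <- sig[, j]
    data[, , , protocol$n_b0 + j] <- v
  }

  if (noise$family != "none") {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(noise$seed)
    data <- apply_noise(data, noise, s0)
  }

  bvals <- c(rep(0, protocol$n_b0), rep(protocol$bvalue,
                                        protocol$n_directions))
  bvecs <- cbind(matrix(0, 3, protocol$n_b0), t(g))
  structure(list(data = data, bvals = bvals, bvecs = bvecs, mask = mask,
                 voxel_size = rep(voxel_size, 3),
                 protocol = protocol),
            class = "dwi_dataset")
}

#' Simulate a replicate (pseudo-time) image stack
#'
#' Generates `n_rep` independent noisy realizations of the same noiseless
#' image, emulating repeated b = 0 acquisitions used for multiple-acquisition
#' SNR estimation.
#'
#' @param s0_field noiseless image (3-D array, or 2-D for a single slice).
#' @param noise a [noise_model()]; replicate `i` uses seed `seed + i - 1`.
#' @param n_rep number of replicates (>= 2, otherwise the temporal SD is
#'   undefined).
#' @param s0_ref reference amplitude defining the noise scale; defaults to
#'   the maximum of `s0_field`.
#' @return array with one extra trailing dimension of size `n_rep`.
#' @export
simulate_replicate_stack <- function(s0_field, noise, n_rep = 30L,
                                     s0_ref = max(s0_field)) {
  n_rep <- as.integer(n_rep)
  if (n_rep < 2L) stop("n_rep must be >= 2 (temporal SD undefined)")
  s0_field <- as.array(s0_field)
  dims <- dim(s0_field)
  out <- array(NA_real_, c(dims, n_rep))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  idx <- slice.index(out, length(dims) + 1L)
  for (i in seq_len(n_rep)) {
    set.seed(noise$seed + i - 1L)
    out[idx == i] <- apply_noise(s0_field, noise, s0_ref)
  }
  out
}

#' Simulate relaxometry series
#'
#' Produces a multi-echo gradient-echo magnitude series
#' `S(TE) = S0 exp(-TE / T2*)` and a spoiled gradient-echo variable flip
#' angle series `S(alpha) = M0 sin(alpha) (1 - E1) / (1 - E1 cos(alpha))`
#' with `E1 = exp(-TR / T1)`, optionally scaling the nominal flip angles by
#' a B1 map.
#'
#' @param t1_map,t2star_map T1 / T2* in ms (arrays or scalars; scalars are
#'   promoted to 1-voxel arrays).
#' @param flip_angles nominal flip angles in degrees, in (0, 90].
#' @param tes echo times in ms, strictly ascending.
#' @param tr repetition time in ms (> 0).
#' @param noise a [noise_model()].
#' @param m0 equilibrium signal amplitude.
#' @param b1_map relative transmit field (actual/nominal flip angle);
#'   default 1 everywhere.
#' @return list with `echo_series` (dims x length(tes)), `vfa_series`
#'   (dims x length(flip_angles)), plus the inputs echoed back.
#' @export
simulate_relaxometry <- function(t1_map, t2star_map, flip_angles, tes, tr,
                                 noise = noise_model("none"), m0 = 100,
                                 b1_map = 1) {
  if (tr <= 0) stop("TR must be positive")
  if (any(flip_angles <= 0 | flip_angles > 90))
    stop("flip angles must lie in (0, 90] degrees")
  if (is.unsorted(tes, strictly = TRUE)) stop("TEs must be ascending")
  t1 <- as.array(t1_map); t2s <- as.array(t2star_map)
  dims <- dim(t2s)
  b1 <- if (length(b1_map) == 1L) array(b1_map, dim(t1)) else as.array(b1_map)

  echo <- array(NA_real_, c(dims, length(tes)))
  for (j in seq_along(tes))
    echo[slice.index(echo, length(dims) + 1L) == j] <- m0 * exp(-tes[j] / t2s)

  e1 <- exp(-tr / t1)
  vfa <- array(NA_real_, c(dim(t1), length(flip_angles)))
  for (j in seq_along(flip_angles)) {
    a <- deg2rad(flip_angles[j]) * b1
    vfa[slice.index(vfa, length(dim(t1)) + 1L) == j] <-
      m0 * sin(a) * (1 - e1) / (1 - e1 * cos(a))
  }

  if (noise$family != "none") {
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
    set.seed(noise$seed)
    # SNR is defined against each series' peak signal: the VFA signal of a
    # short-TR spoiled acquisition is a small fraction of M0, and scaling
    # noise to M0 would swamp it at any realistic target SNR
    echo <- apply_noise(echo, noise, max(echo))
    vfa <- apply_noise(vfa, noise, max(vfa))
  }
  list(echo_series = echo, vfa_series = vfa, tes = tes,
       flip_angles = flip_angles, tr = tr, m0 = m0)
}

#' Apply a simplified EPI off-resonance distortion
#'
#' Shifts image content along the phase-encode axis by
#' `offres / (bandwidth_pe * R)` pixels (linear interpolation), the
#' first-order model of susceptibility-induced geometric distortion in EPI:
#' the shift scales with local off-resonance and inversely with the
#' per-pixel phase-encode bandwidth and the parallel-imaging acceleration
#' factor.  Content shifted past the volume edge is clipped.
#'
#' @param volume 3-D array.
#' @param offres_map off-resonance in Hz (array matching `volume`, or a
#'   scalar).
#' @param protocol an [acquisition_protocol()] supplying `bandwidth_pe` and
#'   `accel`.
#' @param pe_axis phase-encode axis (1 or 2).
#' @return distorted volume, same dimensions.
#' @export
apply_epi_distortion <- function(volume, offres_map, protocol, pe_axis = 2L) {
  volume <- as.array(volume)
  dims <- dim(volume)
  if (length(offres_map) == 1L) offres_map <- array(offres_map, dims)
  if (!identical(dim(as.array(offres_map)), dims))
    stop("off-resonance map must match the volume grid")
  shift <- offres_map / (protocol$bandwidth_pe * protocol$accel)  # pixels
  out <- array(0, dims)
  npe <- dims[pe_axis]
  idx <- slice.index(volume, pe_axis)
  # sample the source at (destination - shift) with linear interpolation
  src <- idx - shift
  lo <- floor(src)
  w <- src - lo
  ok_lo <- lo >= 1 & lo <= npe
  ok_hi <- (lo + 1) >= 1 & (lo + 1) <= npe
  gather <- function(which_idx, ok) {
    v <- array(0, dims)
    pos <- which(ok)
    if (!length(pos)) return(v)
    coord <- arrayInd(pos, dims)
    coord[, pe_axis] <- which_idx[pos]
    v[pos] <- volume[coord]
    v
  }
  out <- (1 - w) * gather(lo, ok_lo) + w * gather(lo + 1L, ok_hi)
  out
}
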