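#' Phantom specification for the synthetic left ventricle
#'
#' Describes an idealized left ventricle used by the simulation layer: an
#' annular myocardial wall per short-axis slice, closed by a filled cap on
#' the apical end, with a prescribed transmural helix-angle rule and a
#' prolate diffusion tensor at every myocardial voxel.
#'
#' Defaults emulate the ex vivo porcine acquisition the package targets:
#' 1.3 mm isotropic voxels, 30 short-axis slices containing the LV cavity,
#' 4 apical-cap slices, a linear helix-angle rule running from +60 deg at
#' the endocardium to -60 deg at the epicardium, and eigenvalues
#' (1.0, 0.45, 0.45) x 1e-3 mm^2/s giving FA ~ 0.46 and
#' ADC ~ 0.63 x 1e-3 mm^2/s (unfixed-myocardium values).
#'
#' @param dims integer grid shape (nx, ny, nz) in voxels.
#' @param voxel_size isotropic voxel edge length in mm.
#' @param r_inner,r_outer endocardial / epicardial wall radii in mm.
#' @param n_cavity_slices number of slices containing the LV cavity.
#' @param n_cap_slices number of closed apical-cap slices below the cavity.
#' @param ha_endo,ha_epi helix angle (degrees) at transmural depth 0
#'   (endocardium) and 1 (epicardium); the rule is linear in depth.
#' @param e2a secondary eigenvector angle rule: either a constant (degrees)
#'   or a function of transmural depth returning degrees.
#' @param evals eigenvalue triple in mm^2/s, sorted descending.  Note the
#'   default has a degenerate second/third eigenvalue; pass a triple with
#'   distinct second and third eigenvalues when the sheetlet (E2A) geometry
#'   must be recoverable from simulated data.
#' @param aha_origin angular origin (degrees) used as the reference for
#'   AHA sector boundaries.
#' @param s0 noiseless b = 0 myocardial signal amplitude (arbitrary units).
#' @param seed integer seed controlling any randomness tied to the phantom.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(40L, 40L, 36L),
                         voxel_size = 1.3,
                         r_inner = 12,
                         r_outer = 20,
                         n_cavity_slices = 30L,
                         n_cap_slices = 4L,
                         ha_endo = 60,
                         ha_epi = -60,
                         e2a = 0,
                         evals = c(1.0, 0.45, 0.45) * 1e-3,
                         aha_origin = 0,
                         s0 = 100,
                         seed = 1L) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L))
    stop("'dims' must be three positive integers")
  stopifnot_scalar(voxel_size, "voxel_size", positive = TRUE)
  stopifnot_scalar(r_inner, "r_inner")
  stopifnot_scalar(r_outer, "r_outer")
  if (!(r_outer > r_inner && r_inner > 0))
    stop("wall radii must satisfy r_outer > r_inner > 0")
  if (length(evals) != 3L || any(evals <= 0))
    stop("'evals' must be three strictly positive eigenvalues")
  if (is.unsorted(rev(evals)))
    stop("'evals' must be sorted descending")
  if (abs(ha_endo) > 90 || abs(ha_epi) > 90)
    stop("helix angles must lie in [-90, 90] degrees")
  if (!is.function(e2a)) stopifnot_scalar(e2a, "e2a")
  structure(list(dims = dims, voxel_size = voxel_size,
                 r_inner = r_inner, r_outer = r_outer,
                 n_cavity_slices = as.integer(n_cavity_slices),
                 n_cap_slices = as.integer(n_cap_slices),
                 ha_endo = ha_endo, ha_epi = ha_epi, e2a = e2a,
                 evals = as.numeric(evals), aha_origin = aha_origin,
                 s0 = s0, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Diffusion acquisition protocol
#'
#' Bundles the acquisition parameters of one diffusion-weighted protocol:
#' diffusion weighting, gradient table, and the EPI readout descriptors
#' (echo train length / effective phase-encode count, per-pixel bandwidth,
#' parallel-imaging acceleration factor) needed for SNR normalization.
#'
#' Defaults reproduce the reference protocol: b = 700 s/mm^2, 30 diffusion
#' directions plus 5 b = 0 reference images, echo train length 55,
#' readout bandwidth 1302 Hz/pixel, no acceleration (R = 1).
#'
#' @param bvalue diffusion weighting in s/mm^2.
#' @param n_directions number of diffusion-weighted directions.
#' @param n_b0 number of b = 0 reference images.
#' @param directions optional n x 3 matrix of unit gradient directions; when
#'   `NULL` a repulsion-optimized table is generated (see
#'   [generate_directions()]) using `seed`.
#' @param te,tr echo / repetition time in ms.
#' @param n_pe effective number of phase-encode steps (echo train length).
#' @param bandwidth readout bandwidth per pixel in Hz.
#' @param bandwidth_pe phase-encode bandwidth per pixel in Hz.
#' @param accel parallel-imaging (GRAPPA) acceleration factor R.
#' @param seed seed used when generating the direction table.
#' @return an object of class `acquisition_protocol`.
#' @export
acquisition_protocol <- function(bvalue = 700,
                                 n_directions = 30L,
                                 n_b0 = 5L,
                                 directions = NULL,
                                 te = 55,
                                 tr = 15000,
                                 n_pe = 55,
                                 bandwidth = 1302,
                                 bandwidth_pe = 1000,
                                 accel = 1,
                                 seed = 1L) {
  if (bvalue < 0) stop("'bvalue' must be non-negative")
  if (n_pe < 1) stop("'n_pe' must be >= 1")
  n_directions <- as.integer(n_directions)
  if (is.null(directions)) {
    directions <- generate_directions(n_directions, seed = seed)$directions
  } else {
    directions <- as.matrix(directions)
    if (ncol(directions) != 3L) stop("'directions' must be an n x 3 matrix")
    if (nrow(directions) != n_directions)
      n_directions <- nrow(directions)
    dev <- abs(row_norm(directions) - 1)
    if (any(dev > 1e-8))
      stop("direction vectors must be unit norm within 1e-8")
  }
  structure(list(bvalue = bvalue, n_directions = n_directions,
                 n_b0 = as.integer(n_b0), directions = directions,
                 te = te, tr = tr, n_pe = n_pe, bandwidth = bandwidth,
                 bandwidth_pe = bandwidth_pe, accel = accel,
                 seed = as.integer(seed)),
            class = "acquisition_protocol")
}

#' Noise model for simulated magnitude images
#'
#' Magnitude MRI noise is Rician: the noiseless signal is perturbed in two
#' independent Gaussian quadrature channels and the magnitude taken.  A pure
#' Gaussian family is provided for estimator-calibration experiments, and
#' `"none"` disables noise.  The target SNR is defined with respect to the
#' b = 0 myocardial signal: `sigma = s0 / snr`.
#'
#' @param family one of `"rician"`, `"gaussian"`, `"none"`.
#' @param snr target signal-to-noise ratio (> 0 unless `family = "none"`).
#' @param seed integer seed.
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(family = c("rician", "gaussian", "none"),
                        snr = 40, seed = 1L) {
  family <- match.arg(family)
  if (family != "none") stopifnot_scalar(snr, "snr", positive = TRUE)
  structure(list(family = family, snr = snr, seed = as.integer(seed)),
            class = "noise_model")
}

# standard deviation of the underlying Gaussian channels for a given
# reference amplitude; NULL when the model is noiseless
noise_sigma <- function(noise, s0) {
  if (noise$family == "none") return(NULL)
  s0 / noise$snr
}

# apply the configured noise family to a noiseless magnitude array
apply_noise <- function(x, noise, s0) {
  if (noise$family == "none") return(x)
  sigma <- noise_sigma(noise, s0)
  n <- length(x)
  if (noise$family == "gaussian")
    return(x + stats::rnorm(n, sd = sigma))
  re <- x + stats::rnorm(n, sd = sigma)
  im <- stats::rnorm(n, sd = sigma)
  out <- sqrt(re^2 + im^2)
  array(out, dim = dim(x) %||% n)
}
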