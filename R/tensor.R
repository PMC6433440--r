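#' Diffusion weighting factor for rectangular gradients
#'
#' Computes `b = gamma^2 delta^2 G^2 (Delta - delta/3)` for a
#' pulsed-gradient (Stejskal-Tanner) pair of rectangular gradient lobes and
#' converts the result from s/m^2 to the conventional s/mm^2 (factor 1e-6).
#'
#' @param gamma gyromagnetic ratio in rad s^-1 T^-1 (default: proton).
#' @param delta gradient lobe duration in s.
#' @param G gradient amplitude in T/m.
#' @param Delta separation of the two gradient lobes in s.
#' @return b-value in s/mm^2.
#' @examples
#' compute_bvalue(delta = 10e-3, G = 50e-3, Delta = 20e-3)  # ~ 298 s/mm^2
#' @export
compute_bvalue <- function(gamma = 2.6752218744e8, delta, G, Delta) {
  if (delta <= 0 || G < 0) stop("invalid gradient parameters")
  if (Delta < delta) stop("invalid timing: Delta must be >= delta")
  gamma^2 * delta^2 * G^2 * (Delta - delta / 3) * 1e-6
}

#' Build the tensor-fit design matrix
#'
#' Maps each unit gradient direction `g` to the design row
#' `[gx^2, gy^2, gz^2, 2 gx gy, 2 gx gz, 2 gy gz]` so that
#' `g' D g = row . dbar` for the 6-component tensor
#' `dbar = (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)`.
#'
#' @param directions K x 3 matrix of unit gradient directions (diffusion
#'   weighted rows only; b = 0 volumes do not enter the design).
#' @return K x 6 design matrix with attribute `condition_number`.
#' @export
build_design_matrix <- function(directions) {
  g <- as.matrix(directions)
  if (ncol(g) != 3L) stop("'directions' must be a K x 3 matrix")
  if (nrow(g) < 6L) stop("need at least 6 diffusion-weighted directions")
  A <- cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
             2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
  colnames(A) <- c("xx", "yy", "zz", "xy", "xz", "yz")
  if (qr(A)$rank < 6L) stop("degenerate direction set")
  attr(A, "condition_number") <- kappa(A, exact = TRUE)
  A
}

#' Fit the diffusion tensor by log-linear least squares
#'
#' Estimates the per-voxel diffusion tensor from a diffusion-weighted
#' dataset by the pseudo-inverse solution of the log-linearized
#' Stejskal-Tanner model: with `S0` the mean of the b = 0 reference volumes
#' and `B_k = ln(S0 / S_k) / b_k`, the 6-component tensor solves
#' `A dbar = B` in the least-squares sense, `dbar = (A'A)^{-1} A' B`.
#' (The log-linear system is stated with `ln(S/S0)` on the right-hand side
#' in part of the literature; since the signal decays, the estimator uses
#' the sign that returns positive-definite tensors for decaying signals.)
#'
#' Voxels with any non-positive signal (weighted or reference) are flagged
#' invalid and excluded rather than clamped, keeping the logarithm
#' well-defined and the exclusions auditable.
#'
#' @param dwi a `dwi_dataset` (see [simulate_dwi()] or [read_dwi()]), or a
#'   4-D array.
#' @param bvals,bvecs gradient table (required when `dwi` is a bare array):
#'   per-volume b-values and a 3 x K direction matrix.
#' @param mask logical array restricting the fit; defaults to voxels whose
#'   mean b = 0 signal is positive.
#' @return an object of class `tensor_fit`: `d` (array dims x 6, ordered
#'   Dxx, Dyy, Dzz, Dxy, Dxz, Dyz), `s0` (array), `valid` (logical array),
#'   `design` (the design matrix), `condition_number`.
#' @export
fit_tensor <- function(dwi, bvals = NULL, bvecs = NULL, mask = NULL) {
  if (inherits(dwi, "dwi_dataset")) {
    data <- dwi$data
    bvals <- bvals %||% dwi$bvals
    bvecs <- bvecs %||% dwi$bvecs
    mask <- mask %||% dwi$mask
  } else data <- as.array(dwi)
  if (length(dim(data)) != 4L) stop("'dwi' must be a 4-D dataset")
  if (is.null(bvals) || is.null(bvecs)) stop("gradient table required")
  n_vol <- dim(data)[4]
  if (length(bvals) != n_vol || ncol(bvecs) != n_vol)
    stop("gradient table length does not match the number of volumes")

  is_ref <- bvals == 0
  if (!any(is_ref)) stop("no b = 0 reference volume present")
  if (sum(!is_ref) < 6L) stop("need at least 6 diffusion-weighted volumes")

  dims <- dim(data)[1:3]
  vol <- matrix(data, prod(dims), n_vol)
  s0 <- rowMeans(vol[, is_ref, drop = FALSE])

  if (is.null(mask)) mask <- array(s0 > 0, dims)
  mvec <- as.logical(mask)
  sw <- vol[mvec, !is_ref, drop = FALSE]
  s0m <- s0[mvec]
  ok <- s0m > 0 & rowSums(sw <= 0) == 0
  if (!any(ok)) stop("tensor fit failed at every voxel (non-positive signals)")

  g <- t(bvecs[, !is_ref, drop = FALSE])
  A <- build_design_matrix(g)
  bv <- bvals[!is_ref]
  # B_k = ln(S0/S_k)/b_k, voxels x K
  B <- sweep(log(s0m[ok] / sw[ok, , drop = FALSE]), 2L, bv, "/")
  dbar <- t(solve(crossprod(A), t(A) %*% t(B)))

  d <- array(NA_real_, c(dims, 6))
  midx <- which(mvec)[ok]
  for (k in 1:6) {
    v <- array(NA_real_, dims)
    v[midx] <- dbar[, k]
    d[, , , k] <- v
  }
  valid <- array(FALSE, dims)
  valid[midx] <- TRUE
  structure(list(d = d, s0 = array(s0, dims), valid = valid, design = A,
                 condition_number = attr(A, "condition_number")),
            class = c("tensor_fit", "tensor_field"))
}

#' Eigendecompose a tensor field
#'
#' Per-voxel symmetric eigendecomposition with eigenvalues sorted
#' descending and a deterministic eigenvector sign convention (the first
#' component exceeding 1e-12 in magnitude is made non-negative).  Voxels
#' with non-finite tensors are flagged invalid; voxels with any
#' non-positive eigenvalue keep their decomposition but are flagged
#' separately so downstream metrics can exclude them.
#'
#' @param field a `tensor_field`/`tensor_fit` (or an array dims x 6).
#' @param valid optional logical array of voxels to process.
#' @return list with `values` (dims x 3, descending), `vectors`
#'   (dims x 3 x 3; `[..., , i]` is the i-th eigenvector), `valid`
#'   (finite decomposition), `positive` (all eigenvalues > 0).
#' @export
eigendecompose <- function(field, valid = NULL) {
  if (inherits(field, "tensor_field")) {
    d <- field$d
    valid <- valid %||% field$valid
  } else d <- as.array(field)
  dims <- dim(d)[1:3]
  if (is.null(valid)) valid <- array(TRUE, dims)
  dmat <- matrix(d, prod(dims), 6)
  finite <- rowSums(!is.finite(dmat)) == 0
  idx <- which(as.logical(valid) & finite)
  d6 <- dmat[idx, , drop = FALSE]

  n <- length(idx)
  vals <- matrix(NA_real_, n, 3)
  vecs <- array(NA_real_, c(n, 3, 3))
  for (i in seq_len(n)) {
    m <- matrix(c(d6[i, 1], d6[i, 4], d6[i, 5],
                  d6[i, 4], d6[i, 2], d6[i, 6],
                  d6[i, 5], d6[i, 6], d6[i, 3]), 3, 3)
    e <- eigen(m, symmetric = TRUE)   # eigenvalues descending
    vals[i, ] <- e$values
    v <- e$vectors
    for (j in 1:3) {
      first <- which(abs(v[, j]) > 1e-12)[1]
      if (!is.na(first) && v[first, j] < 0) v[, j] <- -v[, j]
    }
    vecs[i, , ] <- v
  }

  values <- array(NA_real_, c(dims, 3))
  vectors <- array(NA_real_, c(dims, 3, 3))
  for (j in 1:3) {
    v <- array(NA_real_, dims); v[idx] <- vals[, j]
    values[, , , j] <- v
    for (k in 1:3) {
      v <- array(NA_real_, dims); v[idx] <- vecs[, k, j]
      vectors[, , , k, j] <- v
    }
  }
  valid_out <- array(FALSE, dims); valid_out[idx] <- TRUE
  positive <- array(FALSE, dims)
  positive[idx] <- apply(vals > 0, 1L, all)
  list(values = values, vectors = vectors, valid = valid_out,
       positive = positive)
}

#' Fractional anisotropy from an eigenvalue triple
#'
#' `FA = sqrt(3/2) * sqrt(sum((lambda - mean)^2)) / sqrt(sum(lambda^2))`,
#' the normalized dispersion of the eigenvalues: 0 for isotropic diffusion,
#' 1 in the linear (single non-zero eigenvalue) limit.
#'
#' @param lambda eigenvalues: length-3 vector, N x 3 matrix, or a
#'   `dims x 3` array as returned by [eigendecompose()].
#' @return FA with the input's voxel geometry; all-zero triples give `NA`.
#' @examples
#' compute_fa(c(2, 1, 1))  # 1/sqrt(6)
#' @export
compute_fa <- function(lambda) {
  lam <- .lambda_matrix(lambda)
  lbar <- rowMeans(lam)
  num <- rowSums((lam - lbar)^2)
  den <- rowSums(lam^2)
  fa <- sqrt(1.5) * sqrt(num) / sqrt(den)
  fa[den == 0] <- NA_real_
  .lambda_result(fa, lambda)
}

#' Apparent diffusion coefficient from an eigenvalue triple
#'
#' `ADC = (lambda1 + lambda2 + lambda3) / 3`, the tensor trace over three:
#' rotation invariant, in the units of the eigenvalues (mm^2/s).
#'
#' @inheritParams compute_fa
#' @return ADC with the input's voxel geometry.
#' @export
compute_adc <- function(lambda) {
  lam <- .lambda_matrix(lambda)
  .lambda_result(rowMeans(lam), lambda)
}

.lambda_matrix <- function(lambda) {
  if (is.matrix(lambda)) return(lambda)
  if (is.array(lambda) && length(dim(lambda)) == 4L)
    return(matrix(lambda, prod(dim(lambda)[1:3]), 3))
  matrix(lambda, nrow = 1L)
}

.lambda_result <- function(x, lambda) {
  if (is.array(lambda) && length(dim(lambda)) == 4L)
    return(array(x, dim(lambda)[1:3]))
  if (is.matrix(lambda)) return(x)
  drop(x)
}
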