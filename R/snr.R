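#' Pixel-wise SNR from a replicate stack
#'
#' Multiple acquisitions with identical parameters form a pseudo-time
#' series; per voxel, SNR is the temporal mean divided by the temporal
#' standard deviation (n - 1 denominator).  Voxels with zero temporal SD
#' are flagged undefined and excluded from ROI summaries.
#'
#' @param stack array whose last dimension indexes replicates (>= 2).
#' @param roi optional logical array (matching the image grid) defining the
#'   region over which the summary mean and SD are taken.
#' @return object of class `snr_result`: list with `snr` (map, `NA` where
#'   undefined), `mean`, `sd` (temporal moments), `roi_mean`, `roi_sd`,
#'   `n_rep`, and `factors` (normalization factors applied so far; starts
#'   empty).
#' @export
snr_map <- function(stack, roi = NULL) {
  stack <- as.array(stack)
  nd <- length(dim(stack))
  n_rep <- dim(stack)[nd]
  if (n_rep < 2L) stop("need at least 2 replicates")
  dims <- dim(stack)[-nd]
  m <- matrix(stack, prod(dims), n_rep)
  mu <- rowMeans(m)
  sdv <- sqrt(rowSums((m - mu)^2) / (n_rep - 1))
  snr <- ifelse(sdv > 0, mu / sdv, NA_real_)
  snr <- array(snr, dims)
  roi_mean <- roi_sd <- NA_real_
  if (!is.null(roi)) {
    v <- snr[as.logical(roi)]
    v <- v[is.finite(v)]
    roi_mean <- mean(v)
    roi_sd <- stats::sd(v)
  }
  structure(list(snr = snr, mean = array(mu, dims), sd = array(sdv, dims),
                 roi_mean = roi_mean, roi_sd = roi_sd, n_rep = n_rep,
                 factors = numeric(0)),
            class = "snr_result")
}

#' Normalize SNR across parallel-imaging protocols
#'
#' Compensates the SNR measured on an accelerated / high-bandwidth scan so
#' it is comparable to a reference protocol, using two multiplicative
#' factors: `sqrt(N_PE(ref) / N_PE(test))` for the shortened echo train and
#' `sqrt(bw(test) / bw(ref))` for the increased readout bandwidth.  Both
#' factors exceed one when the test scan has fewer phase encodes and higher
#' bandwidth, i.e. the measured SNR is compensated upward.
#'
#' @param result an `snr_result` (or a bare numeric SNR value).
#' @param protocol_ref,protocol_test [acquisition_protocol()]s (or lists
#'   with `n_pe` and `bandwidth`).
#' @return the input with `snr`, `roi_mean`, `roi_sd` scaled and the two
#'   factors appended to `factors` (named `pe` and `bandwidth`).
#' @export
normalize_snr <- function(result, protocol_ref, protocol_test) {
  np_r <- protocol_ref$n_pe; np_t <- protocol_test$n_pe
  bw_r <- protocol_ref$bandwidth; bw_t <- protocol_test$bandwidth
  if (any(c(np_r, np_t, bw_r, bw_t) <= 0))
    stop("phase-encode counts and bandwidths must be positive")
  f_pe <- sqrt(np_r / np_t)
  f_bw <- sqrt(bw_t / bw_r)
  f <- c(pe = f_pe, bandwidth = f_bw)
  if (is.numeric(result)) {
    out <- result * f_pe * f_bw
    attr(out, "factors") <- f
    return(out)
  }
  stopifnot(inherits(result, "snr_result"))
  result$snr <- result$snr * f_pe * f_bw
  result$roi_mean <- result$roi_mean * f_pe * f_bw
  result$roi_sd <- result$roi_sd * f_pe * f_bw
  result$factors <- c(result$factors, f)
  result
}

#' Mono-exponential T2* fit
#'
#' Per-voxel log-linear least-squares fit of `S(TE) = S0 exp(-TE / T2*)`.
#' Voxels with any non-positive signal are flagged; voxels with a
#' non-negative log-slope (flat or growing series) are flagged as having no
#' measurable decay.
#'
#' @param series array whose last dimension indexes echoes.
#' @param tes echo times in ms, ascending, length >= 3.
#' @return list with `t2star` (map, ms), `s0`, `r_squared`, `valid`.
#' @export
fit_t2star <- function(series, tes) {
  series <- as.array(series)
  nd <- length(dim(series))
  ne <- dim(series)[nd]
  if (length(tes) != ne) stop("length(tes) must match the echo dimension")
  if (ne < 3L) stop("need at least 3 echoes")
  if (is.unsorted(tes, strictly = TRUE)) stop("TEs must be ascending")
  dims <- dim(series)[-nd]
  m <- matrix(series, prod(dims), ne)
  ok <- rowSums(m <= 0) == 0
  y <- log(m[ok, , drop = FALSE])
  x <- tes - mean(tes)
  slope <- drop(y %*% x) / sum(x^2)
  icpt <- rowMeans(y) - slope * mean(tes)
  fitted <- outer(slope, tes) + icpt
  ss_res <- rowSums((y - fitted)^2)
  ss_tot <- rowSums((y - rowMeans(y))^2)
  r2 <- ifelse(ss_tot > 0, 1 - ss_res / ss_tot, NA_real_)
  decays <- slope < -1e-10        # flat series carry no T2* information

  fill <- function(vals, keep = TRUE) {
    v <- rep(NA_real_, prod(dims))
    sel <- which(ok)[keep]
    v[sel] <- vals[keep]
    array(v, dims)
  }
  t2 <- -1 / slope
  list(t2star = fill(t2, decays), s0 = fill(exp(icpt)),
       r_squared = fill(r2),
       valid = array(replace(rep(FALSE, prod(dims)), which(ok)[decays], TRUE),
                     dims))
}

#' DESPOT1 variable flip angle T1 fit
#'
#' Linearizes the spoiled gradient-echo signal: plotting `S / sin(alpha)`
#' against `S / tan(alpha)` gives a line of slope `exp(-TR / T1)`, so
#' `T1 = -TR / log(slope)`.  Nominal flip angles are scaled per voxel by
#' the B1 map before linearization.  Voxels whose fitted slope falls
#' outside (0, 1) are flagged.
#'
#' @param series array whose last dimension indexes flip angles.
#' @param flip_angles nominal flip angles in degrees (>= 2, distinct).
#' @param tr repetition time in ms.
#' @param b1_map relative transmit field (actual / nominal); scalar or
#'   array on the image grid.  Default 1 (no correction).
#' @return list with `t1` (map, ms), `m0`, `slope`, `valid`.
#' @export
fit_despot1 <- function(series, flip_angles, tr, b1_map = 1) {
  series <- as.array(series)
  nd <- length(dim(series))
  na <- dim(series)[nd]
  if (length(flip_angles) != na)
    stop("length(flip_angles) must match the series dimension")
  if (length(unique(flip_angles)) < 2L)
    stop("rank deficient: need at least 2 distinct flip angles")
  if (tr <= 0) stop("TR must be positive")
  dims <- dim(series)[-nd]
  nvox <- prod(dims)
  m <- matrix(series, nvox, na)
  b1 <- if (length(b1_map) == 1L) rep(b1_map, nvox) else as.numeric(b1_map)
  a <- outer(b1, deg2rad(flip_angles))      # actual angles, voxel x angle
  ys <- m / sin(a)
  xs <- m / tan(a)
  xbar <- rowMeans(xs); ybar <- rowMeans(ys)
  sxx <- rowSums((xs - xbar)^2)
  sxy <- rowSums((xs - xbar) * (ys - ybar))
  slope <- ifelse(sxx > 0, sxy / sxx, NA_real_)
  ok <- is.finite(slope) & slope > 0 & slope < 1
  t1 <- rep(NA_real_, nvox)
  t1[ok] <- -tr / log(slope[ok])
  e1 <- slope
  m0 <- (ybar - slope * xbar) / (1 - e1)
  list(t1 = array(t1, dims), m0 = array(ifelse(ok, m0, NA_real_), dims),
       slope = array(slope, dims), valid = array(ok, dims))
}

#' Double-angle B1 map
#'
#' In the long-TR regime the spoiled signal is proportional to
#' `sin(alpha)`, so `S(2a) / (2 S(a)) = cos(a)` and the actual flip angle
#' is `acos(S(2a) / (2 S(a)))`.  B1 is the ratio of actual to nominal
#' angle.  Voxels with non-positive `S(a)` or a ratio outside the arccos
#' domain \[-1, 1\] are flagged.
#'
#' @param img_alpha,img_2alpha magnitude images at nominal flip angles
#'   alpha and 2 alpha.
#' @param nominal_alpha nominal flip angle in degrees.
#' @return list with `b1` (map), `actual_angle` (degrees), `valid`.
#' @export
b1_double_angle <- function(img_alpha, img_2alpha, nominal_alpha) {
  a1 <- as.array(img_alpha); a2 <- as.array(img_2alpha)
  if (!identical(dim(a1), dim(a2))) stop("images must share a grid")
  ratio <- ifelse(a1 > 0, a2 / (2 * a1), NA_real_)
  ok <- is.finite(ratio) & abs(ratio) <= 1
  act <- rep(NA_real_, length(ratio))
  act[ok] <- rad2deg(acos(ratio[ok]))
  dims <- dim(a1) %||% length(a1)
  list(b1 = array(act / nominal_alpha, dims),
       actual_angle = array(act, dims),
       valid = array(ok, dims))
}

#' Relative-change stability time course
#'
#' Expresses a series of scalar measurements relative to its first (or a
#' chosen) time point, `r_t = 100 (x_t - x_0) / x_0` in percent, and
#' summarizes the series by mean +/- error of the mean and the maximum
#' absolute excursion.
#'
#' @param x numeric series of measurements (>= 2 points).
#' @param t0_index index of the reference time point.
#' @return list with `relative_change` (percent), `mean`, `sem`,
#'   `max_abs_change`.
#' @export
stability_timecourse <- function(x, t0_index = 1L) {
  if (length(x) < 2L) stop("need at least 2 time points")
  x0 <- x[t0_index]
  if (!is.finite(x0) || x0 == 0) stop("reference value is zero or undefined")
  r <- 100 * (x - x0) / x0
  list(relative_change = r, mean = mean(r),
       sem = stats::sd(r) / sqrt(length(r)), max_abs_change = max(abs(r)))
}
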