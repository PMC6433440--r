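#' Build the synthetic left-ventricle geometry
#'
#' Constructs the idealized LV described by a [phantom_spec()]: an annular
#' myocardial wall on every cavity slice, a filled (closed) cap on the
#' apical slices, per-slice cavity centers, a transmural-depth map and the
#' local cardiac coordinate frame at every myocardial voxel.  The long axis
#' is the slice-stacking axis, oriented apex (low slice index) to base.
#'
#' Transmural depth is 0 at the endocardium and 1 at the epicardium,
#' measured along the ray from the slice center through the voxel.  On the
#' apical cap, where there is no cavity, depth is the normalized distance
#' from the slice center to the epicardial radius.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `lv_geometry`: list with `mask` (logical
#'   array), `depth` (numeric array, `NA` outside the wall), `centers`
#'   (slice-wise cavity center, voxel coordinates), `long_axis`, `frames`
#'   (`e_l`, `e_c`, `e_r`: arrays of per-voxel frame vectors),
#'   `cavity_slices`, `cap_slices`, `voxel_size`, `aha_origin`.
#' @export
make_lv_geometry <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  wall <- spec$r_outer - spec$r_inner
  if (wall < spec$voxel_size)
    stop("degenerate wall: thickness below one voxel")
  dims <- spec$dims
  n_slices <- spec$n_cap_slices + spec$n_cavity_slices
  if (n_slices > dims[3])
    stop("grid too short for the requested number of slices")

  cx <- (dims[1] + 1) / 2
  cy <- (dims[2] + 1) / 2
  xs <- (seq_len(dims[1]) - cx) * spec$voxel_size
  ys <- (seq_len(dims[2]) - cy) * spec$voxel_size
  r_slice <- sqrt(outer(xs^2, ys^2, "+"))    # in-plane radius (mm)

  cap_slices <- seq_len(spec$n_cap_slices)
  cavity_slices <- spec$n_cap_slices + seq_len(spec$n_cavity_slices)

  mask <- array(FALSE, dims)
  depth <- array(NA_real_, dims)
  ann <- r_slice >= spec$r_inner & r_slice < spec$r_outer
  disk <- r_slice < spec$r_outer
  for (z in cavity_slices) {
    mask[, , z] <- ann
    d <- (r_slice - spec$r_inner) / wall
    depth[, , z][ann] <- pmin(1, pmax(0, d[ann]))
  }
  for (z in cap_slices) {
    mask[, , z] <- disk
    d <- r_slice / spec$r_outer
    depth[, , z][disk] <- pmin(1, d[disk])
  }

  centers <- matrix(NA_real_, dims[3], 2)
  centers[c(cap_slices, cavity_slices), 1] <- cx
  centers[c(cap_slices, cavity_slices), 2] <- cy

  geom <- build_local_frames(mask, long_axis = c(0, 0, 1), centers = centers)
  geom$depth <- depth
  geom$cavity_slices <- cavity_slices
  geom$cap_slices <- cap_slices
  geom$voxel_size <- spec$voxel_size
  geom$aha_origin <- spec$aha_origin
  geom$spec <- spec
  geom
}

#' Build local cardiac coordinate frames
#'
#' Establishes the local orthogonal coordinate system (longitudinal,
#' circumferential, radial) at every myocardial voxel.  The longitudinal
#' axis is the supplied long axis (apex to base); the radial axis is the
#' in-slice unit vector from the cavity center to the voxel, orthogonalized
#' against the long axis; the circumferential axis is their cross product
#' `e_c = e_l x e_r`, which is counterclockwise when viewed from the base.
#' This chirality makes right-handed endocardial helices positive in the
#' helix-angle map.
#'
#' @param mask logical 3-D array of myocardial voxels.
#' @param long_axis length-3 unit vector, apex to base.  Defaults to the
#'   slice-stacking axis.
#' @param centers per-slice cavity center as an `nz x 2` matrix in voxel
#'   coordinates; when `NULL`, the centroid of each slice's mask is used.
#' @return an `lv_geometry` list with `mask`, `long_axis`, `centers`,
#'   `frames` (`e_l`, `e_c`, `e_r` as `dim(mask) x 3` arrays) and
#'   `frame_valid` (logical array; `FALSE` where the radial direction is
#'   undefined, e.g. a voxel on the center line).
#' @export
build_local_frames <- function(mask, long_axis = c(0, 0, 1), centers = NULL) {
  mask <- as.array(mask)
  if (!any(mask)) stop("empty mask")
  dims <- dim(mask)
  e_l <- long_axis / sqrt(sum(long_axis^2))

  if (is.null(centers)) {
    centers <- matrix(NA_real_, dims[3], 2)
    for (z in seq_len(dims[3])) {
      sl <- mask[, , z]
      if (!any(sl)) next
      idx <- which(sl, arr.ind = TRUE)
      centers[z, ] <- colMeans(idx)
    }
  }

  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  d <- cbind(idx[, 1] - centers[idx[, 3], 1],
             idx[, 2] - centers[idx[, 3], 2],
             0)
  # orthogonalize the in-slice offset against the long axis
  d <- d - outer(drop(d %*% e_l), e_l)
  nr <- row_norm(d)
  valid <- nr > 1e-9
  er <- d
  er[valid, ] <- d[valid, , drop = FALSE] / nr[valid]
  er[!valid, ] <- NA_real_
  el <- matrix(e_l, n, 3, byrow = TRUE)
  ec <- row_cross(el, er)

  to_field <- function(m) {
    a <- array(NA_real_, c(dims, 3))
    for (k in 1:3) {
      v <- array(NA_real_, dims)
      v[mask] <- m[, k]
      a[, , , k] <- v
    }
    a
  }
  frame_valid <- array(FALSE, dims)
  frame_valid[mask] <- valid

  structure(list(mask = mask, long_axis = e_l, centers = centers,
                 frames = list(e_l = to_field(el), e_c = to_field(ec),
                               e_r = to_field(er)),
                 frame_valid = frame_valid),
            class = "lv_geometry")
}

#' Estimate transmural depth by profile rays
#'
#' Recomputes transmural depth from the mask alone, emulating profile lines
#' drawn between the LV center and epicardial voxels: each slice is divided
#' into angular bins around the cavity center; within a bin the smallest
#' voxel radius defines the endocardial boundary and the largest the
#' epicardial boundary, and depth is the voxel's fractional position along
#' that ray.  Values are in \[0, 1\] (multiply by 100 for percent depth).
#'
#' @param geom an `lv_geometry`.
#' @param slices slice indices to process (default: all slices with mask).
#' @param n_bins number of angular bins per slice.
#' @return numeric array of depths (`NA` outside the processed wall);
#'   voxels whose ray has zero wall thickness are flagged `NaN`.
#' @export
transmural_depth <- function(geom, slices = NULL, n_bins = 72L) {
  stopifnot(inherits(geom, "lv_geometry"))
  dims <- dim(geom$mask)
  if (is.null(slices))
    slices <- which(apply(geom$mask, 3, any))
  depth <- array(NA_real_, dims)
  for (z in slices) {
    sl <- geom$mask[, , z]
    if (!any(sl)) next
    idx <- which(sl, arr.ind = TRUE)
    dx <- idx[, 1] - geom$centers[z, 1]
    dy <- idx[, 2] - geom$centers[z, 2]
    r <- sqrt(dx^2 + dy^2)
    ang <- atan2(dy, dx)
    bin <- pmin(n_bins, floor((ang + pi) / (2 * pi) * n_bins) + 1L)
    r_in <- tapply(r, bin, min)
    r_out <- tapply(r, bin, max)
    key <- as.character(bin)
    lo <- r_in[key]
    hi <- r_out[key]
    d <- ifelse(hi > lo, (r - lo) / (hi - lo), NaN)
    v <- array(NA_real_, dims[1:2])
    v[sl] <- d
    depth[, , z] <- v
  }
  depth
}
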