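# Helix-angle and secondary eigenvector angle (E2A) maps.
#
# Both maps are defined in the local cardiac frame (longitudinal,
# circumferential, radial) built by build_local_frames().  Eigenvector sign
# is physically arbitrary (antipodal ambiguity); before an angle is taken
# the vector is flipped to a deterministic half-space so maps are
# reproducible.

# gather the rows of a dims x 3 field at the masked voxels
.gather3 <- function(a, mask) {
  m <- matrix(NA_real_, sum(mask), 3)
  for (k in 1:3) m[, k] <- a[, , , k][mask]
  m
}

.scatter <- function(x, mask, dims) {
  v <- array(NA_real_, dims)
  v[mask] <- x
  v
}

#' Helix angle map
#'
#' Projects the primary eigenvector into the plane spanned by the local
#' circumferential and longitudinal axes and measures its angle from the
#' circumferential direction: `HA = atan2(E1.e_l, E1.e_c)` in degrees.
#' With the long axis oriented apex to base, right-handed endocardial
#' fibers get positive angles.  The eigenvector is first flipped so its
#' circumferential component is non-negative, placing HA in (-90, 90].
#'
#' @param e1 primary eigenvector field (`dims x 3` array, e.g.
#'   `eigendecompose(fit)$vectors[, , , , 1]`).
#' @param geom an `lv_geometry`.
#' @param valid optional logical array of voxels to process.
#' @return list with `ha` (degrees, `NA` where undefined) and `valid`
#'   (voxels with a defined frame and a non-degenerate projection).
#' @export
helix_angle <- function(e1, geom, valid = NULL) {
  stopifnot(inherits(geom, "lv_geometry"))
  dims <- dim(geom$mask)
  mask <- geom$mask & geom$frame_valid
  if (!is.null(valid)) mask <- mask & valid
  v1 <- .gather3(e1, mask)
  ec <- .gather3(geom$frames$e_c, mask)
  el <- .gather3(geom$frames$e_l, mask)

  c_comp <- row_dot(v1, ec)
  l_comp <- row_dot(v1, el)
  flip <- !is.na(c_comp) & c_comp < 0
  c_comp[flip] <- -c_comp[flip]
  l_comp[flip] <- -l_comp[flip]
  proj <- sqrt(c_comp^2 + l_comp^2)
  ok <- is.finite(proj) & proj > 1e-6
  ha <- rep(NA_real_, length(proj))
  ha[ok] <- rad2deg(atan2(l_comp[ok], c_comp[ok]))

  valid_map <- array(FALSE, dims)
  valid_map[mask] <- ok
  list(ha = .scatter(ha, mask, dims), valid = valid_map)
}

#' Secondary eigenvector angle (E2A) map
#'
#' For every voxel a cross-myocyte plane is taken perpendicular to the
#' primary eigenvector.  The cross-myocyte direction is the unit vector
#' normal to (the wall-tangent projection of) E1 within the wall-tangent
#' plane, `xhat = e_r x E1 / |e_r x E1|`, and the in-plane radial direction
#' is `rhat = E1 x xhat`.  E2 is projected onto the span of these two axes
#' and `E2A = atan2(E2.rhat, E2.xhat)`, folded into \[-90, 90\] degrees.
#' The magnitude `|E2A|` is the quantity compared statistically (sheetlet
#' angulation).
#'
#' @param e1,e2 primary / secondary eigenvector fields (`dims x 3`).
#' @param geom an `lv_geometry`.
#' @param valid optional logical array of voxels to process.
#' @return list with `e2a` (signed, degrees), `abs_e2a`, and `valid`
#'   (voxels where E1 is not parallel to the radial axis and the
#'   projection of E2 is non-degenerate).
#' @export
e2a_angle <- function(e1, e2, geom, valid = NULL) {
  stopifnot(inherits(geom, "lv_geometry"))
  dims <- dim(geom$mask)
  mask <- geom$mask & geom$frame_valid
  if (!is.null(valid)) mask <- mask & valid
  v1 <- .gather3(e1, mask)
  v2 <- .gather3(e2, mask)
  ec <- .gather3(geom$frames$e_c, mask)
  er <- .gather3(geom$frames$e_r, mask)

  # deterministic E1 orientation (non-negative circumferential component)
  flip <- !is.na(row_dot(v1, ec)) & row_dot(v1, ec) < 0
  v1[flip, ] <- -v1[flip, , drop = FALSE]

  xh <- row_cross(er, v1)
  nx <- row_norm(xh)
  ok <- is.finite(nx) & nx > 1e-6        # E1 parallel to e_r -> degenerate
  xh[ok, ] <- xh[ok, , drop = FALSE] / nx[ok]
  rh <- row_cross(v1, xh)
  rh <- rh / pmax(row_norm(rh), 1e-12)

  x_comp <- row_dot(v2, xh)
  r_comp <- row_dot(v2, rh)
  # E2 antipodal ambiguity: force a non-negative cross-myocyte component
  neg <- !is.na(x_comp) & x_comp < 0
  x_comp[neg] <- -x_comp[neg]
  r_comp[neg] <- -r_comp[neg]
  proj <- sqrt(x_comp^2 + r_comp^2)
  ok <- ok & is.finite(proj) & proj > 1e-6
  ang <- rep(NA_real_, length(proj))
  ang[ok] <- fold_angle(rad2deg(atan2(r_comp[ok], x_comp[ok])))

  valid_map <- array(FALSE, dims)
  valid_map[mask] <- ok
  list(e2a = .scatter(ang, mask, dims),
       abs_e2a = .scatter(abs(ang), mask, dims),
       valid = valid_map)
}
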