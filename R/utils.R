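# Internal vector-field helpers.  Vector fields are stored as N x 3 matrices
# (one row per voxel); volumetric fields as arrays with the grid dims first.

`%||%` <- function(x, y) if (is.null(x)) y else x

# row-wise cross product of two N x 3 matrices
row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

row_norm <- function(a) sqrt(rowSums(a^2))

row_unit <- function(a) a / row_norm(a)

row_dot <- function(a, b) rowSums(a * b)

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# fold an angle in degrees into (-90, 90]
fold_angle <- function(x) {
  x <- (x + 90) %% 180 - 90
  x[x == -90] <- 90
  x
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  invisible(x)
}
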