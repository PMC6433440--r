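#' Generate a diffusion gradient direction table
#'
#' Produces `n` unit gradient directions by iterative pairwise electrostatic
#' repulsion on the sphere with antipodal symmetry (each direction repels
#' both the other points and their antipodes), the standard construction for
#' well-conditioned diffusion sampling schemes.  Directions are reported on
#' one hemisphere (non-negative z); the diffusion signal is even in g so the
#' sign carries no information.
#'
#' @param n number of directions (>= 6; fewer leaves the tensor
#'   underdetermined).
#' @param seed integer seed for the random initialization; the result is
#'   deterministic given `seed`.
#' @param n_iter number of repulsion iterations.
#' @return a list with elements `directions` (n x 3 matrix of unit vectors),
#'   `condition_number` (condition number of the induced tensor design
#'   matrix) and `min_separation` (minimum pairwise angular separation in
#'   degrees, antipodally symmetrized).
#' @export
generate_directions <- function(n, seed = 1L, n_iter = 2000L) {
  n <- as.integer(n)
  if (n < 6L) stop("tensor underdetermined: need at least 6 directions")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  # spiral (Fibonacci) hemisphere start plus a seeded jitter: already
  # roughly uniform, and free of the near-antipodal pairs that sit at
  # unstable equilibria of the repulsion dynamics
  i <- seq_len(n) - 0.5
  z <- i / n
  phi <- 2 * pi * i * (sqrt(5) - 1) / 2
  v <- cbind(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
  v <- row_unit(v + 0.02 * matrix(stats::rnorm(3L * n), ncol = 3L))

  for (it in seq_len(n_iter)) {
    force <- matrix(0, n, 3L)
    for (i in seq_len(n)) {
      d1 <- sweep(-v[-i, , drop = FALSE], 2L, v[i, ], "+")   # v_i - v_j
      d2 <- sweep(v[-i, , drop = FALSE], 2L, v[i, ], "+")    # v_i + v_j
      r1 <- pmax(row_norm(d1), 1e-6)
      r2 <- pmax(row_norm(d2), 1e-6)
      force[i, ] <- colSums(d1 / r1^3) + colSums(d2 / r2^3)
    }
    # tangential component only; displacement capped at a decaying angular
    # step so the dynamics stay stable whatever the raw force magnitude
    force <- force - v * row_dot(force, v)
    fmax <- max(row_norm(force))
    if (fmax < 1e-12) break
    v <- row_unit(v + (0.1 / sqrt(it)) * force / fmax)
  }
  flip <- v[, 3] < 0
  v[flip, ] <- -v[flip, , drop = FALSE]

  A <- build_design_matrix(v)
  co <- abs(v %*% t(v))
  diag(co) <- 0
  # minimum pairwise separation in the antipodal (axis) metric
  seps <- rad2deg(acos(pmin(1, co[upper.tri(co)])))
  list(directions = v,
       condition_number = kappa(A, exact = TRUE),
       min_separation = min(seps))
}

# save/restore .Random.seed so seeded helpers do not disturb global state
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
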