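# Low-level 3D geometry: internal-coordinate atom placement (NeRF),
# axis-angle rotations, least-squares superposition.

deg2rad <- function(x) x * pi / 180

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector cannot be normalized")
  v / n
}

#' Place an atom from internal coordinates
#'
#' Natural-extension reference frame (NeRF) placement: given three reference
#' positions `a`, `b`, `c`, returns the position `d` bonded to `c` with the
#' requested bond length, bond angle b-c-d and dihedral a-b-c-d.
#'
#' @param a,b,c numeric 3-vectors, reference positions (Angstrom).
#' @param bond bond length c-d in Angstrom.
#' @param angle bond angle b-c-d in degrees.
#' @param dihedral dihedral a-b-c-d in degrees.
#' @return numeric 3-vector.
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- deg2rad(angle)
  tor <- deg2rad(dihedral)
  bc <- unit(c - b)
  n <- unit(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

# cross product (kept local; avoids importing pracma for one primitive)
pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

angle_deg <- function(a, b, c) {
  u <- unit(a - b); v <- unit(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}

#' Rotation matrix about an arbitrary axis
#'
#' @param axis numeric 3-vector (need not be normalized).
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 proper rotation matrix.
#' @keywords internal
rotation_about_axis <- function(axis, angle_deg) {
  u <- unit(axis)
  th <- deg2rad(angle_deg)
  ct <- cos(th); st <- sin(th)
  ux <- matrix(c(0, -u[3], u[2],
                 u[3], 0, -u[1],
                 -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * ux + (1 - ct) * tcrossprod(u)
}

# uniform random unit vector (uses the current RNG stream)
random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- vnorm(v)
    if (n > 1e-8) return(v / n)
  }
}

#' Optimal least-squares superposition (Kabsch)
#'
#' Returns the rotation `R` and translation `t` such that `x %*% R + t`
#' best fits `y` in the least-squares sense, with `det(R) = +1`.
#'
#' @param x,y n x 3 coordinate matrices (same n, row-matched).
#' @return list with `R` (3x3), `t` (length 3) and `rmsd`.
#' @keywords internal
kabsch <- function(x, y) {
  stopifnot(nrow(x) == nrow(y), ncol(x) == 3)
  cx <- colMeans(x); cy <- colMeans(y)
  x0 <- sweep(x, 2, cx); y0 <- sweep(y, 2, cy)
  s <- svd(crossprod(x0, y0))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  t <- cy - as.vector(cx %*% R)
  fit <- x %*% R
  fit <- sweep(fit, 2, t, "+")
  list(R = R, t = t, rmsd = sqrt(mean(rowSums((fit - y)^2))))
}

apply_transform <- function(xyz, R, t) {
  sweep(xyz %*% R, 2, t, "+")
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

# Deterministic derived seed (kept below 2^31).
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + 7919 * as.double(k)) %% 2147483647)
}
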