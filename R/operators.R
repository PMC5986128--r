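#' Rotation matrix from axis and angle
#'
#' Rodrigues formula. The axis need not be normalized.
#'
#' @param axis Numeric 3-vector.
#' @param angle Radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_about <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# project a near-rotation back onto SO(3) (removes closure drift)
project_so3 <- function(R) {
  s <- svd(R)
  P <- s$u %*% t(s$v)
  if (det(P) < 0) P <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  P
}

# close a set of rotation generators under multiplication
close_group <- function(gens, tol = 1e-6, cap = 200L) {
  elems <- list(diag(3))
  frontier <- gens
  while (length(frontier) > 0L) {
    nxt <- list()
    for (g in frontier) {
      known <- any(vapply(elems, function(e) max(abs(e - g)) < 1e-4, logical(1)))
      if (!known) {
        elems[[length(elems) + 1L]] <- g
        for (e in elems) {
          nxt[[length(nxt) + 1L]] <- project_so3(e %*% g)
          nxt[[length(nxt) + 1L]] <- project_so3(g %*% e)
        }
      }
      if (length(elems) > cap) stop("group closure exceeded cap; generators do not close")
    }
    frontier <- nxt
  }
  elems
}

#' Generate the rotation operators of a point group
#'
#' Analytic operator sets for Cn (rotations about z), Dn (z principal axis,
#' x-axis 2-fold), and the cubic groups T, O, I (generated from standard
#' generators and closed under multiplication). Optionally the group is
#' centered at a point `center` (each rotation R becomes the rigid operator
#' x -> R(x - c) + c) and conjugated by a global rotation, which exercises
#' re-centering and conjugation invariance in the classifier.
#'
#' @param sym A `qs_symmetry` (or label string); H is not generable.
#' @param center Common fixed point of the generated operators.
#' @param conjugate Optional global 3x3 rotation applied by conjugation.
#' @return List of `rigid_operator`.
#' @export
point_group_operators <- function(sym, center = c(0, 0, 0), conjugate = NULL) {
  if (is.character(sym)) sym <- parse_symmetry(sym)
  stopifnot(inherits(sym, "qs_symmetry"))
  z <- c(0, 0, 1); x <- c(1, 0, 0)
  phi <- (1 + sqrt(5)) / 2
  Rs <- switch(sym$family,
    C = lapply(seq_len(sym$order) - 1L, function(k) rotation_about(z, 2 * pi * k / sym$order)),
    D = {
      cyc <- lapply(seq_len(sym$order) - 1L, function(k) rotation_about(z, 2 * pi * k / sym$order))
      flip <- rotation_about(x, pi)
      c(cyc, lapply(cyc, function(Rk) flip %*% Rk))
    },
    T = close_group(list(rotation_about(z, pi), rotation_about(c(1, 1, 1), 2 * pi / 3))),
    O = close_group(list(rotation_about(z, pi / 2), rotation_about(c(1, 1, 1), 2 * pi / 3))),
    I = close_group(list(rotation_about(z, pi), rotation_about(c(0, 1, phi), 2 * pi / 5))),
    H = stop("helical symmetry has no finite operator set")
  )
  expected <- group_order(sym)
  if (length(Rs) != expected) {
    stop("generated ", length(Rs), " operators for ", format(sym),
         ", expected ", expected)
  }
  lapply(Rs, function(R) {
    if (!is.null(conjugate)) R <- conjugate %*% R %*% t(conjugate)
    rigid_operator(R, center - R %*% center)
  })
}
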