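#' Rigid-body operator
#'
#' A proper rigid transformation x -> R x + t with R a 3x3 rotation matrix
#' (orthonormal, det +1) and t a translation in Angstrom. These are the
#' per-chain operators found in assembly descriptions; improper operations
#' (det -1) are rejected because chiral macromolecules admit only rotational
#' point groups.
#'
#' @param rotation 3x3 numeric matrix.
#' @param translation Numeric 3-vector (default zero).
#' @param tol Orthonormality/determinant tolerance.
#' @return A `rigid_operator` object (list with `R`, `t`).
#' @export
rigid_operator <- function(rotation, translation = c(0, 0, 0), tol = 1e-6) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L))) stop("rotation must be 3x3")
  translation <- as.numeric(translation)
  if (length(translation) != 3L) stop("translation must be length 3")
  if (max(abs(crossprod(rotation) - diag(3))) > sqrt(tol)) {
    stop("rotation matrix is not orthonormal within tolerance")
  }
  d <- det(rotation)
  if (abs(d - 1) > sqrt(tol)) {
    if (abs(d + 1) <= sqrt(tol)) stop("improper operator (det = -1) rejected")
    stop("rotation determinant is not +/-1")
  }
  structure(list(R = rotation, t = translation), class = "rigid_operator")
}

#' Axis and angle of a proper rotation
#'
#' The rotation angle comes from the trace formula cos(theta) = (tr(R) - 1)/2;
#' the axis from the antisymmetric part of R, or from the dominant eigen
#' direction of (R + I)/2 when the angle is close to pi (where the
#' antisymmetric part vanishes). The axis is defined up to sign; the returned
#' axis has its first non-zero component positive. An (approximate) identity
#' returns `identity = TRUE` with an arbitrary axis.
#'
#' @param op A `rigid_operator` (or plain 3x3 rotation matrix).
#' @param tol Angle below which the operator counts as the identity (radians).
#' @return List with `axis` (unit 3-vector), `angle` (radians in \[0, pi\]),
#'   `identity` (logical).
#' @export
rotation_axis_angle <- function(op, tol = 1e-6) {
  R <- if (inherits(op, "rigid_operator")) op$R else rigid_operator(op)$R
  ct <- (sum(diag(R)) - 1) / 2
  ct <- min(1, max(-1, ct))
  angle <- acos(ct)
  if (angle < tol) {
    return(list(axis = c(0, 0, 1), angle = 0, identity = TRUE))
  }
  if (angle < pi - 1e-4) {
    ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * sin(angle))
  } else {
    # near pi: axis is the eigenvector of (R + I)/2 with eigenvalue ~1
    M <- (R + diag(3)) / 2
    ev <- eigen(M, symmetric = TRUE)
    ax <- ev$vectors[, which.max(ev$values)]
  }
  ax <- ax / sqrt(sum(ax^2))
  nz <- which(abs(ax) > 1e-8)[1]
  if (ax[nz] < 0) ax <- -ax
  list(axis = ax, angle = angle, identity = FALSE)
}

op_rotations <- function(ops) {
  lapply(ops, function(o) {
    if (inherits(o, "rigid_operator")) o else rigid_operator(o)
  })
}

# distinct operators under an absolute entrywise tolerance on (R | t)
dedupe_operators <- function(ops, tol = 1e-4) {
  keep <- list()
  for (o in ops) {
    dup <- any(vapply(keep, function(k) {
      max(abs(k$R - o$R)) < tol && max(abs(k$t - o$t)) < tol
    }, logical(1)))
    if (!dup) keep[[length(keep) + 1L]] <- o
  }
  keep
}

# least-squares common fixed point of a set of rigid operators:
# minimises sum_i || (R_i - I) c + t_i ||^2. Returns c and max residual.
common_fixed_point <- function(ops) {
  A <- do.call(rbind, lapply(ops, function(o) o$R - diag(3)))
  b <- -unlist(lapply(ops, function(o) o$t))
  if (max(abs(A)) < 1e-12) {
    cc <- c(0, 0, 0)
  } else {
    # rank-deficient by construction (rotation axes are null directions):
    # minimum-norm least-squares via SVD pseudo-inverse
    sv <- svd(A)
    keep <- sv$d > 1e-8 * sv$d[1]
    cc <- sv$v[, keep, drop = FALSE] %*%
      ((t(sv$u[, keep, drop = FALSE]) %*% b) / sv$d[keep])
  }
  res <- vapply(ops, function(o) {
    max(abs((o$R - diag(3)) %*% cc + o$t))
  }, numeric(1))
  list(center = as.numeric(cc), max_residual = max(res))
}

# order of a rotation element by repeated multiplication (cap: icosahedral 5)
element_order <- function(R, tol = 1e-4, cap = 61L) {
  P <- R
  for (n in 1:cap) {
    if (max(abs(P - diag(3))) < tol) return(n)
    P <- P %*% R
  }
  NA_integer_
}

axes_collinear <- function(a, b, tol_axis) {
  abs(sum(a * b)) > cos(tol_axis)
}

axes_perpendicular <- function(a, b, tol_axis) {
  abs(sum(a * b)) < sin(tol_axis)
}

#' Classify the point group of a rigid-operator set
#'
#' Determines the rotational point group (Cn, Dn, T, O, I) of a finite set of
#' rigid operators. The set must contain the identity, consist of proper
#' rotations, share a common fixed point (operators are re-centered by solving
#' for the least-squares point all rotation axes pass through), and be closed
#' under composition: the product of any two members must match a member
#' within tolerance, else the set is rejected.
#'
#' Classification uses the group order N = number of distinct operators and
#' the folds of the distinct rotation axes: a single shared axis gives C_N;
#' an n-fold principal axis with n perpendicular 2-folds and N = 2n gives D_n;
#' N = 12 with only 3-fold and 2-fold axes gives T; N = 24 containing a 4-fold
#' gives O; N = 60 gives I. Classification is invariant under a global
#' rotation/translation applied to every operator.
#'
#' @param ops List of `rigid_operator` (or 3x3 rotation matrices).
#' @param tol_angle Angle-matching tolerance in radians.
#' @param tol_axis Axis collinearity/perpendicularity tolerance in radians.
#' @param tol_closure Relative tolerance for the closure distance.
#' @return A `qs_symmetry` object.
#' @export
classify_point_group <- function(ops, tol_angle = 0.05, tol_axis = 0.05,
                                 tol_closure = 1e-3) {
  if (length(ops) == 0L) stop("operator set must be non-empty")
  ops <- op_rotations(ops)
  ops <- dedupe_operators(ops)
  N <- length(ops)

  info <- lapply(ops, rotation_axis_angle)
  if (!any(vapply(info, `[[`, logical(1), "identity"))) {
    stop("operator set must contain the identity")
  }

  # operators must share a fixed point (axes concurrent), else no point group
  fp <- common_fixed_point(ops)
  scale <- max(1, max(vapply(ops, function(o) max(abs(o$t)), numeric(1))))
  if (fp$max_residual > 1e-3 * scale) {
    stop("operators do not share a common fixed point; not a point group")
  }

  # closure on the rotation parts
  abs_tol <- tol_closure * sqrt(3)
  Rs <- lapply(ops, `[[`, "R")
  for (i in seq_len(N)) {
    for (j in seq_len(N)) {
      P <- Rs[[i]] %*% Rs[[j]]
      d <- min(vapply(Rs, function(Rk) sqrt(sum((P - Rk)^2)), numeric(1)))
      if (d > abs_tol) stop("operator set is not closed under composition")
    }
  }

  if (N == 1L) return(symmetry("C", 1L))

  nonid <- which(!vapply(info, `[[`, logical(1), "identity"))
  elem_axis <- lapply(info[nonid], `[[`, "axis")
  elem_ord <- vapply(Rs[nonid], element_order, integer(1))
  if (any(is.na(elem_ord))) stop("operator with no finite rotation order")

  # group elements into distinct axes; each axis' fold = max element order
  axes <- list()
  for (k in seq_along(nonid)) {
    hit <- FALSE
    for (m in seq_along(axes)) {
      if (axes_collinear(axes[[m]]$axis, elem_axis[[k]], tol_axis)) {
        axes[[m]]$fold <- max(axes[[m]]$fold, elem_ord[k])
        hit <- TRUE
        break
      }
    }
    if (!hit) axes[[length(axes) + 1L]] <- list(axis = elem_axis[[k]], fold = elem_ord[k])
  }

  if (length(axes) == 1L) {
    if (axes[[1]]$fold != N) stop("single-axis set whose fold does not equal its order")
    return(symmetry("C", N))
  }

  folds <- vapply(axes, `[[`, integer(1), "fold")
  if (N == 60L) return(symmetry("I"))
  if (N == 24L && any(folds == 4L)) return(symmetry("O"))
  if (N == 12L && all(folds %in% c(2L, 3L)) && any(folds == 3L) && any(folds == 2L)) {
    return(symmetry("T"))
  }

  # dihedral: an n-fold principal axis, n perpendicular 2-folds, N = 2n
  if (N %% 2L == 0L) {
    n <- N %/% 2L
    for (m in seq_along(axes)) {
      if (axes[[m]]$fold != n) next
      perp2 <- sum(vapply(axes[-m], function(a) {
        a$fold == 2L && axes_perpendicular(a$axis, axes[[m]]$axis, tol_axis)
      }, logical(1)))
      if (perp2 == n) return(symmetry("D", n))
    }
  }
  stop("operator set matches no catalogued point group")
}

#' Stoichiometry and symmetry of an assembly from chains and operators
#'
#' Computes the assembly descriptor the way an assembly-rebuilding pipeline
#' does: stoichiometry is the canonical count of entity labels; symmetry is
#' the point-group classification of the distinct chain operators when those
#' form a valid group (closed, common fixed point, no entity repeating an
#' operator), and C1 otherwise. Distinct entity labels are never collapsed, so
#' a 2+2 assembly of two distinct entities whose four operators form a D2 set
#' is reported as (A2B2, D2) while its true (non-pseudo) symmetry as judged by
#' entity identity would be lower; label-identity is the sole criterion.
#'
#' @param chains List of chains, each a list with `entity` (label string) and
#'   `op` (a `rigid_operator`).
#' @param strict If `TRUE`, a deduplicated operator set that fails group
#'   validation raises an error instead of falling back to C1.
#' @param ... Tolerances passed to [classify_point_group()].
#' @return List with `stoichiometry` (`qs_stoich`) and `symmetry`
#'   (`qs_symmetry`).
#' @export
assembly_descriptor <- function(chains, strict = FALSE, ...) {
  if (length(chains) == 0L) stop("empty chain list")
  entities <- vapply(chains, function(ch) as.character(ch$entity), character(1))
  tab <- sort(table(entities), decreasing = TRUE)
  stoich <- canonicalize_stoichiometry(
    stoichiometry(stats::setNames(as.integer(tab), LETTERS[seq_along(tab)]))
  )

  ops <- op_rotations(lapply(chains, `[[`, "op"))
  sym <- tryCatch({
    # within one entity every chain must sit on a distinct operator
    for (e in unique(entities)) {
      sub <- dedupe_operators(ops[entities == e])
      if (length(sub) != sum(entities == e)) {
        stop("entity ", e, " repeats an operator; assembly is not operator-symmetric")
      }
    }
    classify_point_group(dedupe_operators(ops), ...)
  }, error = function(err) {
    if (strict) stop(err)
    symmetry("C", 1L)
  })
  list(stoichiometry = stoich, symmetry = sym)
}
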