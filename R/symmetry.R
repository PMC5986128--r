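#' Point-group symmetry labels
#'
#' Quaternary-structure symmetry is described by the point group of the
#' rotations mapping the assembly onto itself: cyclic (C1, C2, C3, ...),
#' dihedral (D2, D3, ...), and the cubic groups tetrahedral (T), octahedral
#' (O) and icosahedral (I). "H" is accepted as a label for open helical
#' symmetry but is never produced by the operator-based classifier.
#'
#' @param family One of `"C"`, `"D"`, `"T"`, `"O"`, `"I"`, `"H"`.
#' @param order Positive integer rotation order; required for C and D
#'   (C order >= 1, D order >= 2), disallowed otherwise.
#' @return A `qs_symmetry` object.
#' @examples
#' symmetry("C", 2)
#' parse_symmetry("D4")
#' @export
symmetry <- function(family, order = NA_integer_) {
  if (!is.character(family) || length(family) != 1L ||
      !family %in% c("C", "D", "T", "O", "I", "H")) {
    stop("unknown symmetry family: ", family)
  }
  if (family %in% c("C", "D")) {
    order <- as.integer(order)
    if (is.na(order) || order < 1L) stop(family, " symmetry needs a positive order")
    if (family == "D" && order < 2L) stop("dihedral order must be >= 2")
  } else {
    if (!is.na(order)) stop(family, " symmetry carries no numeric order")
    order <- NA_integer_
  }
  structure(list(family = family, order = order), class = "qs_symmetry")
}

#' Parse a symmetry label
#'
#' @param text Label string in the `Cn` / `Dn` / `T` / `O` / `I` / `H` grammar,
#'   e.g. `"C2"`, `"D4"`, `"T"`.
#' @return A `qs_symmetry` object.
#' @export
parse_symmetry <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    stop("symmetry label must be a non-empty string")
  }
  if (grepl("^[CD][0-9]+$", text)) {
    return(symmetry(substr(text, 1L, 1L), as.integer(substring(text, 2L))))
  }
  if (text %in% c("T", "O", "I", "H")) return(symmetry(text))
  stop("malformed symmetry label: ", text)
}

#' @export
format.qs_symmetry <- function(x, ...) {
  if (x$family %in% c("C", "D")) paste0(x$family, x$order) else x$family
}

#' @export
print.qs_symmetry <- function(x, ...) {
  cat("<symmetry> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.qs_symmetry <- function(x, ...) format(x)

sym_equal <- function(a, b) {
  a$family == b$family &&
    (is.na(a$order) && is.na(b$order) ||
       (!is.na(a$order) && !is.na(b$order) && a$order == b$order))
}

#' Group order of a point-group label
#'
#' Number of rotations in the group: n for Cn, 2n for Dn, 12 for T, 24 for O,
#' 60 for I. Undefined (NA) for helical H.
#'
#' @param sym A `qs_symmetry` object.
#' @return Integer group order, or `NA` for H.
#' @export
group_order <- function(sym) {
  stopifnot(inherits(sym, "qs_symmetry"))
  switch(sym$family,
    C = sym$order,
    D = 2L * sym$order,
    T = 12L,
    O = 24L,
    I = 60L,
    H = NA_integer_
  )
}
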