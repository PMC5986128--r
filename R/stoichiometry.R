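#' Stoichiometry composition formulas
#'
#' A stoichiometry describes the subunit composition of a protein assembly as
#' a composition formula: each distinct subunit type gets an uppercase letter
#' (A, B, C, ...) and a copy-count coefficient, so a homodimer is "A2" and a
#' two-component heterotetramer such as hemoglobin is "A2B2". The letters are
#' abstract subunit labels, not PDB chain identifiers.
#'
#' Internally a `qs_stoich` object is a named integer vector mapping subunit
#' letters to copy counts (every count >= 1).
#'
#' @param counts Named integer vector, names single uppercase letters, values
#'   positive copy counts.
#' @return A `qs_stoich` object.
#' @examples
#' stoichiometry(c(A = 2, B = 2))
#' parse_stoichiometry("A2B2")
#' @export
stoichiometry <- function(counts) {
  if (length(counts) == 0L) stop("stoichiometry must have at least one subunit")
  nm <- names(counts)
  if (is.null(nm) || any(!grepl("^[A-Z]$", nm))) {
    stop("subunit labels must be single uppercase letters")
  }
  if (anyDuplicated(nm)) stop("repeated subunit letter")
  counts <- as.integer(counts)
  if (any(is.na(counts)) || any(counts < 1L)) {
    stop("every copy count must be a positive integer")
  }
  names(counts) <- nm
  structure(counts[order(nm)], class = "qs_stoich")
}

#' Parse a stoichiometry formula string
#'
#' Accepts formulas of the form `A2B2`, `A4B2C1`, `A` (an omitted coefficient
#' means 1). Letters must be strictly increasing from left to right and
#' coefficients must be positive integers.
#'
#' @param text Formula string, e.g. `"A2B2"`.
#' @return A `qs_stoich` object.
#' @export
parse_stoichiometry <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text)) {
    stop("stoichiometry formula must be a non-empty string")
  }
  if (!grepl("^([A-Z][0-9]*)+$", text)) {
    stop("malformed stoichiometry formula: ", text)
  }
  m <- gregexpr("[A-Z][0-9]*", text)[[1]]
  parts <- regmatches(text, list(m))[[1]]
  letters_ <- substr(parts, 1L, 1L)
  nums <- substring(parts, 2L)
  counts <- ifelse(nzchar(nums), suppressWarnings(as.integer(nums)), 1L)
  if (any(is.na(counts)) || any(counts < 1L)) {
    stop("zero or invalid coefficient in: ", text)
  }
  if (anyDuplicated(letters_)) stop("repeated subunit letter in: ", text)
  if (is.unsorted(letters_, strictly = TRUE)) {
    stop("subunit letters must be strictly increasing in: ", text)
  }
  stoichiometry(stats::setNames(counts, letters_))
}

#' @export
format.qs_stoich <- function(x, ...) {
  paste0(names(x), unclass(x), collapse = "")
}

#' @export
print.qs_stoich <- function(x, ...) {
  cat("<stoichiometry> ", format(x), " (", n_subunits(x), " subunits)\n", sep = "")
  invisible(x)
}

#' @export
as.character.qs_stoich <- function(x, ...) format(x)

#' Total number of subunits in an assembly
#'
#' @param s A `qs_stoich` object.
#' @return Integer sum of all copy counts (the oligomer order).
#' @export
n_subunits <- function(s) {
  stopifnot(inherits(s, "qs_stoich"))
  sum(unclass(s))
}

#' Canonicalize a stoichiometry
#'
#' Each prediction method assigns subunit letters independently, so formulas
#' are compared label-free: counts are sorted in non-increasing order and
#' relabelled A, B, C, ... Equal counts keep their original letter order, which
#' makes the relabelling deterministic. Idempotent.
#'
#' @param s A `qs_stoich` object.
#' @return A canonical `qs_stoich` object.
#' @export
canonicalize_stoichiometry <- function(s) {
  stopifnot(inherits(s, "qs_stoich"))
  v <- unclass(s)
  ord <- order(-v, names(v))
  stoichiometry(stats::setNames(v[ord], LETTERS[seq_along(v)]))
}

stoich_equal <- function(a, b) {
  identical(
    format(canonicalize_stoichiometry(a)),
    format(canonicalize_stoichiometry(b))
  )
}
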