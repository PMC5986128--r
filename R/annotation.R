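QS_SOURCES  <- c("PDB", "SC", "TM", "PISA", "EPPIC", "CONSENSUS")
QS_STATUSES <- c("predicted", "inconclusive", "not_available")

#' Quaternary-structure annotation record
#'
#' The shared record all modules exchange: an optional stoichiometry, an
#' optional symmetry, the source that produced the call, and a status. A
#' `predicted` annotation must carry at least one of the two components.
#' Text-mining (TM) annotations never carry symmetry — symmetry is not
#' extracted from article text — and their stoichiometry encodes only the
#' oligomer order (total subunit count), so TM stoichiometries are compared
#' to other methods by order, not by full composition formula.
#'
#' @param stoichiometry A `qs_stoich`, a formula string, or `NULL`.
#' @param symmetry A `qs_symmetry`, a label string, or `NULL`.
#' @param source One of `"PDB"`, `"SC"`, `"TM"`, `"PISA"`, `"EPPIC"`,
#'   `"CONSENSUS"`.
#' @param status One of `"predicted"`, `"inconclusive"`, `"not_available"`.
#' @return A `qs_annotation` object.
#' @examples
#' qs_annotation("A2", "C2", source = "PISA")
#' qs_annotation(status = "not_available", source = "TM")
#' @export
qs_annotation <- function(stoichiometry = NULL, symmetry = NULL,
                          source = "PDB", status = "predicted") {
  source <- match.arg(source, QS_SOURCES)
  status <- match.arg(status, QS_STATUSES)
  if (is.character(stoichiometry)) stoichiometry <- parse_stoichiometry(stoichiometry)
  if (is.character(symmetry)) symmetry <- parse_symmetry(symmetry)
  if (!is.null(stoichiometry) && !inherits(stoichiometry, "qs_stoich")) {
    stop("stoichiometry must be a qs_stoich, a formula string, or NULL")
  }
  if (!is.null(symmetry) && !inherits(symmetry, "qs_symmetry")) {
    stop("symmetry must be a qs_symmetry, a label string, or NULL")
  }
  if (status != "predicted") {
    stoichiometry <- NULL
    symmetry <- NULL
  }
  if (status == "predicted" && is.null(stoichiometry) && is.null(symmetry)) {
    stop("a predicted annotation needs stoichiometry and/or symmetry")
  }
  if (source == "TM" && !is.null(symmetry)) {
    stop("TM annotations never carry symmetry")
  }
  structure(
    list(stoichiometry = stoichiometry, symmetry = symmetry,
         source = source, status = status),
    class = "qs_annotation"
  )
}

#' @export
print.qs_annotation <- function(x, ...) {
  st <- if (is.null(x$stoichiometry)) "-" else format(x$stoichiometry)
  sy <- if (is.null(x$symmetry)) "-" else format(x$symmetry)
  cat(sprintf("<annotation %s> %s  stoich=%s sym=%s\n", x$source, x$status, st, sy))
  invisible(x)
}

#' Compare two annotations component-wise
#'
#' Stoichiometries are compared after canonicalization (label-free multiset of
#' copy counts); when either side is TM-sourced, only the total subunit counts
#' are compared, because a "dimer" mention cannot distinguish A2 from AB.
#' Symmetries are compared by (family, order). A component absent from either
#' side — including any component of a non-predicted annotation — is reported
#' `"unavailable"`, never silently treated as a match.
#'
#' @param a,b `qs_annotation` objects.
#' @return A list with elements `stoich` and `sym`, each one of `"match"`,
#'   `"mismatch"`, `"unavailable"`.
#' @export
match_annotations <- function(a, b) {
  stopifnot(inherits(a, "qs_annotation"), inherits(b, "qs_annotation"))
  by_order <- a$source == "TM" || b$source == "TM"
  stoich <-
    if (is.null(a$stoichiometry) || is.null(b$stoichiometry)) {
      "unavailable"
    } else if (by_order) {
      if (n_subunits(a$stoichiometry) == n_subunits(b$stoichiometry)) "match" else "mismatch"
    } else if (stoich_equal(a$stoichiometry, b$stoichiometry)) "match" else "mismatch"
  sym <-
    if (is.null(a$symmetry) || is.null(b$symmetry)) {
      "unavailable"
    } else if (sym_equal(a$symmetry, b$symmetry)) "match" else "mismatch"
  list(stoich = stoich, sym = sym)
}

annotation_to_fields <- function(ann) {
  c(
    stoichiometry = if (is.null(ann$stoichiometry)) "" else format(ann$stoichiometry),
    symmetry = if (is.null(ann$symmetry)) "" else format(ann$symmetry),
    status = ann$status
  )
}

fields_to_annotation <- function(stoich, sym, status, source) {
  if (is.na(status) || !nzchar(status)) status <- "predicted"
  qs_annotation(
    stoichiometry = if (!is.na(stoich) && nzchar(stoich)) stoich else NULL,
    symmetry = if (!is.na(sym) && nzchar(sym)) sym else NULL,
    source = source, status = status
  )
}
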