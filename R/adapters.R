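#' Assembly candidate parsed from a PISA-style XML file
#'
#' @param assembly_id Integer id.
#' @param delta_g_diss Dissociation free energy (kcal/mol); positive means
#'   the associated state is stable.
#' @param asa Solvent-accessible surface area (A^2).
#' @param bsa Buried surface area (A^2).
#' @param chains List of chains, each `list(entity =, op = rigid_operator)`.
#' @return An `assembly_candidate` object.
#' @export
assembly_candidate <- function(assembly_id, delta_g_diss, asa, bsa, chains) {
  stopifnot(length(chains) > 0L, asa >= 0, bsa >= 0)
  structure(
    list(assembly_id = as.integer(assembly_id),
         delta_g_diss = as.numeric(delta_g_diss),
         asa = as.numeric(asa), bsa = as.numeric(bsa), chains = chains),
    class = "assembly_candidate"
  )
}

xml_num <- function(node, name) {
  el <- xml2::xml_find_first(node, name)
  if (inherits(el, "xml_missing")) stop("missing element <", name, ">")
  v <- suppressWarnings(as.numeric(xml2::xml_text(el)))
  if (is.na(v)) stop("non-numeric <", name, ">: ", xml2::xml_text(el))
  v
}

#' Parse a PISA-style assembly XML file
#'
#' Reads the assembly-description dialect written by [make_assembly_xml()]
#' (element names follow the PISA assembly XML convention:
#' `asm_set/assembly` with `id`, `diss_energy`, `asa`, `bsa`, and one
#' `molecule` per chain carrying `entity`, the nine rotation elements
#' `rxx ... rzz` and translations `tx ty tz`). One candidate per assembly; a
#' document with zero assemblies yields an empty list, which downstream code
#' records as "no assembly result".
#'
#' @param doc Path to an XML file, or an `xml2` document.
#' @return List of `assembly_candidate`.
#' @export
parse_pisa_xml <- function(doc) {
  x <- if (inherits(doc, "xml_document")) doc else xml2::read_xml(doc)
  asms <- xml2::xml_find_all(x, ".//asm_set/assembly")
  lapply(asms, function(a) {
    id <- xml_num(a, "id")
    dg <- xml_num(a, "diss_energy")
    asa <- xml_num(a, "asa")
    bsa <- xml_num(a, "bsa")
    chains <- lapply(xml2::xml_find_all(a, "./molecule"), function(m) {
      R <- matrix(c(xml_num(m, "rxx"), xml_num(m, "rxy"), xml_num(m, "rxz"),
                    xml_num(m, "ryx"), xml_num(m, "ryy"), xml_num(m, "ryz"),
                    xml_num(m, "rzx"), xml_num(m, "rzy"), xml_num(m, "rzz")),
                  nrow = 3, byrow = TRUE)
      tt <- c(xml_num(m, "tx"), xml_num(m, "ty"), xml_num(m, "tz"))
      ent <- xml2::xml_text(xml2::xml_find_first(m, "entity"))
      if (is.na(ent) || !nzchar(ent)) stop("molecule without entity label")
      list(entity = ent, op = rigid_operator(R, tt))
    })
    assembly_candidate(assembly_id = id, delta_g_diss = dg,
                       asa = asa, bsa = bsa, chains = chains)
  })
}

#' Stability call from a dissociation free energy
#'
#' Positive dissociation free energy marks a chemically stable assembly and
#' negative an unstable one; values inside the configurable gray band around
#' zero are indeterminate.
#'
#' @param dg Dissociation free energy (kcal/mol).
#' @param gray_band Half-width of the indeterminate band (kcal/mol, >= 0).
#' @return `"stable"`, `"unstable"`, or `"gray"`.
#' @export
classify_stability <- function(dg, gray_band = 0.5) {
  stopifnot(gray_band >= 0)
  if (dg > gray_band) "stable" else if (dg < -gray_band) "unstable" else "gray"
}

#' Quaternary-structure prediction from PISA-style candidates
#'
#' Selects the stable candidate with the largest dissociation free energy
#' (ties: larger buried surface, then lower assembly id) and characterizes it
#' by rebuilding stoichiometry and symmetry from its chains and operators via
#' [assembly_descriptor()]. With no stable candidate, any gray candidate
#' makes the prediction inconclusive; if every candidate is unstable the
#' dissociated monomer (A, C1) is predicted. No candidates at all means the
#' method produced no assembly result (not_available). An operator set that
#' fails group validation raises an error naming the assembly.
#'
#' @param candidates List of `assembly_candidate`.
#' @param gray_band Indeterminate band passed to [classify_stability()].
#' @param ... Tolerances passed to [assembly_descriptor()].
#' @return A `qs_annotation` with source `"PISA"`.
#' @export
pisa_prediction <- function(candidates, gray_band = 0.5, ...) {
  if (length(candidates) == 0L) {
    return(qs_annotation(source = "PISA", status = "not_available"))
  }
  verdicts <- vapply(candidates, function(cand) {
    classify_stability(cand$delta_g_diss, gray_band)
  }, character(1))
  stable <- candidates[verdicts == "stable"]
  if (length(stable)) {
    ord <- order(
      -vapply(stable, `[[`, numeric(1), "delta_g_diss"),
      -vapply(stable, `[[`, numeric(1), "bsa"),
      vapply(stable, `[[`, integer(1), "assembly_id")
    )
    best <- stable[[ord[1]]]
    desc <- tryCatch(
      assembly_descriptor(best$chains, strict = TRUE, ...),
      error = function(e) {
        stop("assembly ", best$assembly_id, ": ", conditionMessage(e))
      }
    )
    return(qs_annotation(desc$stoichiometry, desc$symmetry,
                         source = "PISA", status = "predicted"))
  }
  if (any(verdicts == "gray")) {
    return(qs_annotation(source = "PISA", status = "inconclusive"))
  }
  qs_annotation("A", "C1", source = "PISA", status = "predicted")
}

#' Parse an EPPIC-style prediction XML file
#'
#' Reads the prediction dialect written by [make_assembly_xml()] with
#' `format = "eppic"`: an `eppic_prediction` root with an `assembly` element
#' carrying `stoichiometry` and/or `symmetry` text. Missing fields leave the
#' corresponding component absent; a document with neither is
#' `not_available`. Stoichiometry is canonicalized on read.
#'
#' @param doc Path to an XML file, or an `xml2` document.
#' @return A `qs_annotation` with source `"EPPIC"`.
#' @export
parse_eppic_xml <- function(doc) {
  x <- if (inherits(doc, "xml_document")) doc else xml2::read_xml(doc)
  asm <- xml2::xml_find_first(x, ".//assembly")
  if (inherits(asm, "xml_missing")) {
    return(qs_annotation(source = "EPPIC", status = "not_available"))
  }
  txt <- function(name) {
    el <- xml2::xml_find_first(asm, name)
    if (inherits(el, "xml_missing")) return(NULL)
    v <- trimws(xml2::xml_text(el))
    if (nzchar(v)) v else NULL
  }
  st <- txt("stoichiometry")
  sy <- txt("symmetry")
  if (is.null(st) && is.null(sy)) {
    return(qs_annotation(source = "EPPIC", status = "not_available"))
  }
  qs_annotation(
    stoichiometry = if (!is.null(st)) canonicalize_stoichiometry(parse_stoichiometry(st)),
    symmetry = sy,
    source = "EPPIC", status = "predicted"
  )
}
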