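#' Write annotations in the shared long CSV dialect
#'
#' One row per (entry, source): columns `pdb_id`, `source`, `stoichiometry`,
#' `symmetry`, `status`; absent components are empty strings.
#'
#' @param annotations Named list: entry id -> named list of `qs_annotation`
#'   by source.
#' @param path Output CSV path.
#' @export
write_annotation_csv <- function(annotations, path) {
  rows <- list()
  for (id in names(annotations)) {
    for (src in names(annotations[[id]])) {
      f <- annotation_to_fields(annotations[[id]][[src]])
      rows[[length(rows) + 1L]] <- data.frame(
        pdb_id = id, source = src, stoichiometry = f[["stoichiometry"]],
        symmetry = f[["symmetry"]], status = f[["status"]]
      )
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
}

#' Read annotations from the shared long CSV dialect
#'
#' @param path CSV with columns `pdb_id`, `source`, `stoichiometry`,
#'   `symmetry`, `status`.
#' @return Named list: entry id -> named list of `qs_annotation` by source.
#' @export
read_annotation_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = character(0))
  need <- c("pdb_id", "source", "stoichiometry", "symmetry", "status")
  if (!all(need %in% names(df))) {
    stop("annotation CSV must have columns: ", paste(need, collapse = ", "))
  }
  out <- list()
  for (r in seq_len(nrow(df))) {
    ann <- fields_to_annotation(df$stoichiometry[r], df$symmetry[r],
                                df$status[r], df$source[r])
    out[[df$pdb_id[r]]][[df$source[r]]] <- ann
  }
  out
}

wide_method_cols <- function(m) {
  paste0(tolower(m), c("_stoichiometry", "_symmetry", "_status"))
}

#' Write benchmark entries as a wide per-entry prediction table
#'
#' The wide dialect carries one row per entry: `pdb_id`, the curated
#' reference (`ref_stoichiometry`, `ref_symmetry`), the deposited archive
#' annotation (`pdb_stoichiometry`, `pdb_symmetry`), and per method m in
#' (sc, tm, pisa, eppic) the columns `m_stoichiometry`, `m_symmetry`,
#' `m_status`. Empty cells mean absent components.
#'
#' @param entries List of `benchmark_entry`.
#' @param path Output CSV path.
#' @export
write_benchmark_table <- function(entries, path) {
  rows <- lapply(entries, function(e) {
    ref <- annotation_to_fields(e$reference)
    pdb <- if (is.null(e$pdb_annotation)) c(stoichiometry = "", symmetry = "")
           else annotation_to_fields(e$pdb_annotation)
    row <- data.frame(pdb_id = e$pdb_id,
                      ref_stoichiometry = ref[["stoichiometry"]],
                      ref_symmetry = ref[["symmetry"]],
                      pdb_stoichiometry = pdb[["stoichiometry"]],
                      pdb_symmetry = pdb[["symmetry"]])
    for (m in QS_METHODS) {
      ann <- e$method_results[[m]]
      f <- if (is.null(ann)) {
        c(stoichiometry = "", symmetry = "", status = "not_available")
      } else annotation_to_fields(ann)
      row[wide_method_cols(m)] <- unname(f)
    }
    row
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
}

#' Read a wide per-entry prediction table into benchmark entries
#'
#' @param path CSV in the dialect of [write_benchmark_table()].
#' @return List of `benchmark_entry`.
#' @export
read_benchmark_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = character(0))
  if (!"pdb_id" %in% names(df)) stop("benchmark table needs a pdb_id column")
  lapply(seq_len(nrow(df)), function(r) {
    ref <- fields_to_annotation(df$ref_stoichiometry[r], df$ref_symmetry[r],
                                "predicted", "PDB")
    pdb <- if (nzchar(df$pdb_stoichiometry[r]) || nzchar(df$pdb_symmetry[r])) {
      fields_to_annotation(df$pdb_stoichiometry[r], df$pdb_symmetry[r],
                           "predicted", "PDB")
    }
    methods <- list()
    for (m in QS_METHODS) {
      cols <- wide_method_cols(m)
      if (!all(cols %in% names(df))) next
      st <- df[[cols[1]]][r]; sy <- df[[cols[2]]][r]; status <- df[[cols[3]]][r]
      if (!nzchar(status)) status <- "predicted"
      if (status == "predicted" && !nzchar(st) && !nzchar(sy)) next
      methods[[m]] <- fields_to_annotation(st, sy, status, m)
    }
    benchmark_entry(df$pdb_id[r], ref, pdb, methods)
  })
}
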