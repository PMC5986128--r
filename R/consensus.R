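QS_METHODS <- c("SC", "TM", "PISA", "EPPIC")

#' Benchmark entry
#'
#' One PDB-like entry of the benchmark: the curated reference annotation, the
#' archive's deposited annotation, and the per-method predictions.
#'
#' @param pdb_id 4-character-style identifier.
#' @param reference Curated-truth `qs_annotation` (must carry stoichiometry).
#' @param pdb_annotation The archive's deposited `qs_annotation`.
#' @param method_results Named list (names among SC, TM, PISA, EPPIC) of
#'   `qs_annotation`.
#' @return A `benchmark_entry` object.
#' @export
benchmark_entry <- function(pdb_id, reference, pdb_annotation = NULL,
                            method_results = list()) {
  stopifnot(nzchar(pdb_id), inherits(reference, "qs_annotation"))
  if (is.null(reference$stoichiometry)) {
    stop("reference annotation must carry stoichiometry")
  }
  if (anyDuplicated(names(method_results))) stop("duplicate method results")
  if (!all(names(method_results) %in% QS_METHODS)) {
    stop("method names must be among ", paste(QS_METHODS, collapse = ", "))
  }
  structure(
    list(pdb_id = pdb_id, reference = reference,
         pdb_annotation = pdb_annotation, method_results = method_results),
    class = "benchmark_entry"
  )
}

#' Collect the votes cast for one entry
#'
#' Applies the exclusion rules: not-available results (insufficient cluster,
#' no article, no assembly result) never vote, and inconclusive results are
#' dropped from the denominator by default (`include_inconclusive = TRUE`
#' retains them as abstentions that enlarge the denominator without backing
#' any candidate).
#'
#' @param entry A `benchmark_entry`.
#' @param methods Subset of `c("SC", "TM", "PISA", "EPPIC")` to consult.
#' @param include_inconclusive Retain inconclusive results as abstentions.
#' @return List of `qs_annotation` votes.
#' @export
collect_votes <- function(entry, methods = QS_METHODS,
                          include_inconclusive = FALSE) {
  stopifnot(all(methods %in% QS_METHODS))
  votes <- entry$method_results[names(entry$method_results) %in% methods]
  keep_status <- if (include_inconclusive) c("predicted", "inconclusive") else "predicted"
  Filter(function(v) v$status %in% keep_status, votes)
}

# strict-majority winner of a character vector of candidate keys, or NULL
strict_majority <- function(keys, n_votes = length(keys)) {
  if (!length(keys) || n_votes == 0L) return(NULL)
  tab <- sort(table(keys), decreasing = TRUE)
  if (2L * tab[1] > n_votes) names(tab)[1] else NULL
}

#' Majority-vote consensus over method votes
#'
#' Stoichiometry and symmetry are decided independently, each by a strict
#' majority of the votes that carry that component. Text-mining votes carry
#' only an oligomer order: a TM vote backs the full composition formula of
#' any co-voted candidate with the same total subunit count, and stands as
#' the bare formula "An" only when no other candidate shares its order.
#' Symmetry votes never come from TM. A component with no strict majority is
#' left undecided; when both components are undecided the consensus is
#' inconclusive, and an empty vote set is not_available.
#'
#' @param votes List of `qs_annotation` (from [collect_votes()]).
#' @return A `qs_annotation` with source `"CONSENSUS"`.
#' @export
consensus_predict <- function(votes) {
  votes <- Filter(function(v) v$status == "predicted", votes)
  if (!length(votes)) {
    return(qs_annotation(source = "CONSENSUS", status = "not_available"))
  }

  st_votes <- Filter(function(v) !is.null(v$stoichiometry), votes)
  st_win <- NULL
  if (length(st_votes)) {
    is_tm <- vapply(st_votes, function(v) v$source == "TM", logical(1))
    full <- vapply(st_votes[!is_tm], function(v) {
      format(canonicalize_stoichiometry(v$stoichiometry))
    }, character(1))
    keys <- full
    for (v in st_votes[is_tm]) {
      ord <- n_subunits(v$stoichiometry)
      same_order <- unique(full[vapply(full, function(f) {
        n_subunits(parse_stoichiometry(f)) == ord
      }, logical(1))])
      # a TM order vote backs the (unique) co-voted formula with that order;
      # with several such formulas it cannot choose between them and abstains
      keys <- c(keys, if (length(same_order) == 1L) same_order
                      else if (length(same_order) == 0L) paste0("A", ord))
    }
    st_win <- strict_majority(keys, n_votes = length(st_votes))
  }

  sy_votes <- Filter(function(v) !is.null(v$symmetry), votes)
  sy_win <- strict_majority(
    vapply(sy_votes, function(v) format(v$symmetry), character(1))
  )

  if (is.null(st_win) && is.null(sy_win)) {
    return(qs_annotation(source = "CONSENSUS", status = "inconclusive"))
  }
  qs_annotation(stoichiometry = st_win, symmetry = sy_win,
                source = "CONSENSUS", status = "predicted")
}

#' Classify a prediction against a reference annotation
#'
#' A prediction is correct when every component both sides carry matches
#' (stoichiometry after canonicalization — by oligomer order for TM — and
#' symmetry by family and order), incorrect when every compared component
#' mismatches, and inconclusive when one compared component is right and the
#' other wrong, or when the prediction itself is inconclusive. A
#' not-available prediction stays not_available.
#'
#' @param prediction,reference `qs_annotation` objects; the reference must
#'   carry at least stoichiometry.
#' @return One of `"correct"`, `"incorrect"`, `"inconclusive"`,
#'   `"not_available"`.
#' @export
classify_outcome <- function(prediction, reference) {
  stopifnot(inherits(prediction, "qs_annotation"),
            inherits(reference, "qs_annotation"))
  if (prediction$status == "not_available") return("not_available")
  if (prediction$status == "inconclusive") return("inconclusive")
  m <- match_annotations(prediction, reference)
  compared <- c(m$stoich, m$sym)
  compared <- compared[compared != "unavailable"]
  if (!length(compared)) return("inconclusive")
  if (all(compared == "match")) return("correct")
  if (all(compared == "mismatch")) return("incorrect")
  "inconclusive"
}

entry_outcomes <- function(entry, methods = QS_METHODS,
                           include_inconclusive = FALSE) {
  per_method <- vapply(methods, function(m) {
    ann <- entry$method_results[[m]]
    if (is.null(ann)) "not_available" else classify_outcome(ann, entry$reference)
  }, character(1))
  cons <- consensus_predict(collect_votes(entry, methods, include_inconclusive))
  c(per_method, CONSENSUS = classify_outcome(cons, entry$reference))
}

#' Benchmark summary: outcome rates per method and for the consensus
#'
#' Evaluates every method and the majority-vote consensus against the
#' reference annotation of each entry and reports percentage rates of
#' correct / incorrect / inconclusive / not-available outcomes, with the
#' full benchmark as denominator, so each row sums to 100.
#'
#' @param entries List of `benchmark_entry`.
#' @param methods Methods to evaluate and feed to the consensus.
#' @param include_inconclusive Passed to [collect_votes()].
#' @return Data frame with columns `method`, `pct_correct`, `pct_incorrect`,
#'   `pct_inconclusive`, `pct_na`, `n`.
#' @export
benchmark_summary <- function(entries, methods = QS_METHODS,
                              include_inconclusive = FALSE) {
  stopifnot(length(entries) > 0L)
  out <- t(vapply(entries, entry_outcomes, character(length(methods) + 1L),
                  methods = methods,
                  include_inconclusive = include_inconclusive))
  colnames(out) <- c(methods, "CONSENSUS")
  n <- length(entries)
  rows <- lapply(colnames(out), function(m) {
    data.frame(
      method = m,
      pct_correct = 100 * sum(out[, m] == "correct") / n,
      pct_incorrect = 100 * sum(out[, m] == "incorrect") / n,
      pct_inconclusive = 100 * sum(out[, m] == "inconclusive") / n,
      pct_na = 100 * sum(out[, m] == "not_available") / n,
      n = n
    )
  })
  do.call(rbind, rows)
}

#' Method-agreement analysis
#'
#' For each outcome category, attributes every entry to the exact subset of
#' methods sharing that category on that entry (an entry on which all four
#' methods are correct counts once, under the full 4-method subset), so
#' within a category the subset counts are disjoint.
#'
#' @param entries List of `benchmark_entry`.
#' @param methods Methods to analyse.
#' @return Data frame with columns `category`, `methods` (subset label,
#'   `+`-separated), `count`.
#' @export
agreement_analysis <- function(entries, methods = QS_METHODS) {
  cats <- c("correct", "incorrect", "inconclusive", "not_available")
  counts <- new.env(parent = emptyenv())
  for (entry in entries) {
    per_method <- vapply(methods, function(m) {
      ann <- entry$method_results[[m]]
      if (is.null(ann)) "not_available" else classify_outcome(ann, entry$reference)
    }, character(1))
    for (cat in cats) {
      subset <- methods[per_method == cat]
      if (!length(subset)) next
      key <- paste(cat, paste(subset, collapse = "+"), sep = "|")
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    }
  }
  keys <- ls(counts)
  if (!length(keys)) {
    return(data.frame(category = character(0), methods = character(0),
                      count = integer(0)))
  }
  parts <- strsplit(keys, "|", fixed = TRUE)
  df <- data.frame(
    category = vapply(parts, `[[`, character(1), 1L),
    methods = vapply(parts, `[[`, character(1), 2L),
    count = vapply(keys, function(k) counts[[k]], integer(1))
  )
  rownames(df) <- NULL
  df[order(df$category, -df$count), ]
}

#' Flag entries whose archive annotation disagrees with the consensus
#'
#' An entry is a possible outlier when the consensus produced an actual
#' prediction (not inconclusive or not-available) and that prediction
#' disagrees with the deposited archive annotation on at least one compared
#' component. The fraction is taken over entries with a conclusive consensus.
#'
#' @param entries List of `benchmark_entry` (each with a `pdb_annotation`).
#' @param methods Methods feeding the consensus.
#' @return List with `flags` (named logical per entry, `NA` when the
#'   consensus is not a prediction) and `fraction` (outliers / conclusive
#'   consensus predictions).
#' @export
flag_outliers <- function(entries, methods = QS_METHODS) {
  flags <- vapply(entries, function(entry) {
    cons <- consensus_predict(collect_votes(entry, methods))
    if (cons$status != "predicted") return(NA)
    if (is.null(entry$pdb_annotation)) stop(entry$pdb_id, " has no PDB annotation")
    m <- match_annotations(cons, entry$pdb_annotation)
    compared <- c(m$stoich, m$sym)
    any(compared == "mismatch")
  }, logical(1))
  names(flags) <- vapply(entries, `[[`, character(1), "pdb_id")
  conclusive <- sum(!is.na(flags))
  list(flags = flags,
       fraction = if (conclusive > 0) sum(flags, na.rm = TRUE) / conclusive else NA_real_)
}

#' Published compositions of the source benchmark sets
#'
#' Per-oligomer-order compositions of the three previously published,
#' manually curated benchmark sets and of the deduplicated combined set:
#' Ponstingl (218 complexes), Bahadur (266), Duarte (152), and the combined
#' benchmark of 543 entries.
#'
#' @return Data frame with columns `dataset`, `oligomer`, `count`.
#' @export
benchmark_composition <- function() {
  data.frame(
    dataset = c(rep("ponstingl", 5), rep("bahadur", 2), rep("duarte", 6),
                rep("combined", 7)),
    oligomer = c(
      "monomer", "dimer", "trimer", "tetramer", "hexamer",
      "monomer", "dimer",
      "monomer", "dimer", "trimer", "tetramer", "hexamer", "dodecamer",
      "monomer", "dimer", "trimer", "tetramer", "hexamer", "octamer", "dodecamer"
    ),
    count = c(55, 88, 24, 38, 13,
              144, 122,
              78, 62, 2, 8, 1, 1,
              248, 209, 26, 44, 14, 1, 1)
  )
}
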