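#' Pairwise sequence identity and coverage
#'
#' Global (Needleman-Wunsch) alignment of two amino-acid sequences with
#' BLOSUM62 scoring (gap opening 10, extension 0.5). Identity is the fraction
#' of identical columns over the core alignment — the columns between the
#' first and last position where both sequences have a residue, i.e. terminal
#' gaps are excluded. Coverage for each sequence is the fraction of its
#' residues falling inside that core region, so a short sequence fully
#' embedded in a long one has coverage 1 on its own side and < 1 on the other.
#'
#' @param a,b `seq_record` objects (see [seq_record()]) or plain strings.
#' @return List with `identity`, `coverage_a`, `coverage_b` (fractions).
#' @export
pairwise_identity <- function(a, b) {
  sa <- if (inherits(a, "seq_record")) a$sequence else seq_record("a", a)$sequence
  sb <- if (inherits(b, "seq_record")) b$sequence else seq_record("b", b)$sequence
  pa <- Biostrings::pairwiseAlignment(
    sa, sb,
    substitutionMatrix = blosum62(),
    gapOpening = 10, gapExtension = 0.5, type = "global"
  )
  p <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  both <- which(p != "-" & s != "-")
  if (length(both) == 0L) {
    return(list(identity = 0, coverage_a = 0, coverage_b = 0))
  }
  core <- seq(min(both), max(both))
  ident <- sum(p[core] == s[core] & p[core] != "-")
  list(
    identity = ident / length(core),
    coverage_a = sum(p[core] != "-") / nchar(sa),
    coverage_b = sum(s[core] != "-") / nchar(sb)
  )
}

.qsc_cache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.qsc_cache$BLOSUM62)) {
    data("BLOSUM62", package = "Biostrings", envir = .qsc_cache)
  }
  .qsc_cache$BLOSUM62
}

#' Sequence record
#'
#' @param id Identifier string.
#' @param sequence Amino-acid string (uppercase 20-letter alphabet plus X).
#' @return A `seq_record` object.
#' @export
seq_record <- function(id, sequence) {
  if (!nzchar(sequence)) stop("empty sequence")
  sequence <- toupper(sequence)
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", sequence)) {
    stop("sequence contains characters outside the amino-acid alphabet")
  }
  structure(list(id = id, sequence = sequence), class = "seq_record")
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file of amino-acid sequences.
#' @return List of `seq_record`.
#' @export
read_fasta_records <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  mapply(seq_record, ids, as.character(ss), SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Single-linkage sequence clusters at an identity threshold
#'
#' A cluster is a set of chains in which every member is connected, directly
#' or transitively, to another member by a pairwise match with identity >=
#' k% over at least `min_coverage` of both sequences — the single-linkage
#' construction used by BLASTClust-style clustering. The returned clusters
#' partition the input: every record belongs to exactly one cluster
#' (singletons allowed).
#'
#' @param records List of `seq_record`.
#' @param k Percent identity threshold (0 < k <= 100), e.g. 70.
#' @param min_coverage Minimum alignment coverage of both sequences.
#' @return List of `qs_cluster` objects (fields `threshold_k`, `members` =
#'   character vector of record ids).
#' @export
build_clusters <- function(records, k, min_coverage = 0.9) {
  if (length(records) == 0L) stop("no records")
  if (k <= 0 || k > 100) stop("identity threshold must be in (0, 100]")
  ids <- vapply(records, `[[`, character(1), "id")
  n <- length(records)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (n > 1L) {
    edges <- integer(0)
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        pw <- pairwise_identity(records[[i]], records[[j]])
        if (pw$identity >= k / 100 && pw$coverage_a >= min_coverage &&
            pw$coverage_b >= min_coverage) {
          edges <- c(edges, i, j)
        }
      }
    }
    if (length(edges)) g <- igraph::add_edges(g, edges)
  }
  comp <- igraph::components(g)$membership
  lapply(split(ids, comp), function(mem) {
    structure(list(threshold_k = k, members = unname(mem)), class = "qs_cluster")
  })
}

#' Empirical stoichiometry/symmetry profile of a cluster
#'
#' The two discrete random variables associated with a cluster: S_t
#' (stoichiometry) and S_y (symmetry), estimated as empirical frequencies of
#' the archived annotations of the cluster members. Members lacking one
#' component are excluded from that component's marginal, with
#' renormalization. The joint empirical frequency over members carrying both
#' components is kept alongside the marginals.
#'
#' @param annotations List of `qs_annotation` (the PDB-sourced annotations of
#'   the cluster members).
#' @return A `cluster_profile` object: `p_stoich`, `p_sym` (named probability
#'   vectors over canonical labels), `p_joint` (named vector over
#'   "stoich/sym" pairs), `n_members`.
#' @export
cluster_profile <- function(annotations) {
  st <- vapply(annotations, function(a) {
    if (is.null(a$stoichiometry)) NA_character_
    else format(canonicalize_stoichiometry(a$stoichiometry))
  }, character(1))
  sy <- vapply(annotations, function(a) {
    if (is.null(a$symmetry)) NA_character_ else format(a$symmetry)
  }, character(1))
  if (all(is.na(st)) && all(is.na(sy))) stop("cluster has no annotated members")
  prop <- function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(stats::setNames(numeric(0), character(0)))
    tab <- table(x)
    stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  }
  joint <- ifelse(is.na(st) | is.na(sy), NA_character_, paste(st, sy, sep = "/"))
  structure(
    list(p_stoich = prop(st), p_sym = prop(sy), p_joint = prop(joint),
         n_members = length(annotations)),
    class = "cluster_profile"
  )
}

#' Within-cluster consistency score
#'
#' For a stoichiometry t and symmetry y, the consistency score is the product
#' of the within-cluster marginal probabilities,
#' C(t, y) = P(S_t = t) x P(S_y = y). A pair absent from the profile scores 0.
#' Setting `joint = TRUE` scores by the empirical joint frequency of (t, y)
#' instead of the product of marginals.
#'
#' @param profile A `cluster_profile`.
#' @param t Stoichiometry (`qs_stoich` or formula string).
#' @param y Symmetry (`qs_symmetry` or label string).
#' @param joint Use the empirical joint frequency instead of the product.
#' @return Score in \[0, 1\].
#' @export
consistency_score <- function(profile, t, y, joint = FALSE) {
  stopifnot(inherits(profile, "cluster_profile"))
  if (is.character(t)) t <- parse_stoichiometry(t)
  if (is.character(y)) y <- parse_symmetry(y)
  kt <- format(canonicalize_stoichiometry(t))
  ky <- format(y)
  if (joint) {
    key <- paste(kt, ky, sep = "/")
    return(unname(if (key %in% names(profile$p_joint)) profile$p_joint[[key]] else 0))
  }
  pt <- if (kt %in% names(profile$p_stoich)) profile$p_stoich[[kt]] else 0
  py <- if (ky %in% names(profile$p_sym)) profile$p_sym[[ky]] else 0
  unname(pt * py)
}

#' Default minimum cluster sizes per identity threshold
#'
#' Benchmark-calibrated minimum number of members required before a cluster is
#' allowed to vote: 5 at the 40% identity threshold, 3 at 70/90/95%.
#'
#' @return Named numeric vector, names are identity thresholds.
#' @export
default_min_sizes <- function() c("40" = 5, "70" = 3, "90" = 3, "95" = 3)

#' Representative quaternary structure of a cluster
#'
#' Applies the majority rule to the consistency score: if the cluster is
#' smaller than the minimum size for its identity threshold the result is
#' `not_available`; otherwise the (t, y) pair maximising the consistency
#' score is the representative provided the maximum score is strictly greater
#' than 0.5 (a maximum of exactly 0.5 is inconclusive).
#'
#' @param annotations List of `qs_annotation` for the cluster members.
#' @param k Identity threshold the cluster was built at.
#' @param min_sizes Named vector mapping threshold to minimum size.
#' @param min_size Direct minimum-size override (used by the size sweep).
#' @param joint Score by joint frequency instead of the product of marginals.
#' @return A `qs_annotation` with source `"SC"`.
#' @export
representative_state <- function(annotations, k, min_sizes = default_min_sizes(),
                                 min_size = NULL, joint = FALSE) {
  if (is.null(min_size)) {
    key <- as.character(k)
    if (!key %in% names(min_sizes)) stop("no minimum size configured for k = ", k)
    min_size <- min_sizes[[key]]
  }
  if (length(annotations) < min_size) {
    return(qs_annotation(source = "SC", status = "not_available"))
  }
  prof <- cluster_profile(annotations)
  pairs <- names(prof$p_joint)
  if (!length(pairs)) {
    return(qs_annotation(source = "SC", status = "inconclusive"))
  }
  scores <- vapply(pairs, function(p) {
    tv <- strsplit(p, "/", fixed = TRUE)[[1]]
    consistency_score(prof, tv[1], tv[2], joint = joint)
  }, numeric(1))
  best <- which.max(scores)
  if (scores[best] > 0.5) {
    tv <- strsplit(pairs[best], "/", fixed = TRUE)[[1]]
    qs_annotation(tv[1], tv[2], source = "SC", status = "predicted")
  } else {
    qs_annotation(source = "SC", status = "inconclusive")
  }
}

#' Error/availability trade-off across minimum cluster sizes
#'
#' For each minimum cluster size, predicts a representative state for every
#' benchmark entry from its cluster and tallies the percentage of correct,
#' incorrect, inconclusive, and not-available outcomes against the reference
#' annotations. Raising the minimum size trades incorrect predictions for
#' not-available ones.
#'
#' @param entries Named list mapping entry id to its reference
#'   `qs_annotation`.
#' @param clusters List of `qs_cluster` covering the entry ids.
#' @param annotations Named list mapping entry id to its archived
#'   (PDB-sourced) `qs_annotation` used for cluster profiles.
#' @param k Identity threshold of the clusters.
#' @param sizes Integer vector of minimum sizes to evaluate.
#' @return A data.frame with columns `min_size`, `pct_correct`,
#'   `pct_incorrect`, `pct_inconclusive`, `pct_na`.
#' @export
cluster_size_sweep <- function(entries, clusters, annotations, k, sizes = 1:50) {
  if (length(entries) == 0L) {
    return(data.frame(min_size = integer(0), pct_correct = numeric(0),
                      pct_incorrect = numeric(0), pct_inconclusive = numeric(0),
                      pct_na = numeric(0)))
  }
  cluster_of <- list()
  for (ci in seq_along(clusters)) {
    for (m in clusters[[ci]]$members) cluster_of[[m]] <- ci
  }
  ids <- names(entries)
  rows <- lapply(sizes, function(ms) {
    outcomes <- vapply(ids, function(id) {
      ci <- cluster_of[[id]]
      if (is.null(ci)) return("not_available")
      mem <- clusters[[ci]]$members
      pred <- representative_state(annotations[mem], k, min_size = ms)
      classify_outcome(pred, entries[[id]])
    }, character(1))
    n <- length(outcomes)
    data.frame(
      min_size = ms,
      pct_correct = 100 * sum(outcomes == "correct") / n,
      pct_incorrect = 100 * sum(outcomes == "incorrect") / n,
      pct_inconclusive = 100 * sum(outcomes == "inconclusive") / n,
      pct_na = 100 * sum(outcomes == "not_available") / n
    )
  })
  do.call(rbind, rows)
}
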