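AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

# point-substitute a fraction of positions (never to the original residue),
# so pairwise identities stay analytically controllable (no indels)
mutate_sequence <- function(seq, rate) {
  ch <- strsplit(seq, "")[[1]]
  k <- round(rate * length(ch))
  if (k > 0) {
    pos <- sample(length(ch), k)
    ch[pos] <- vapply(ch[pos], function(a) sample(setdiff(AA20, a), 1), character(1))
  }
  paste(ch, collapse = "")
}

#' Generate an annotated sequence-cluster fixture
#'
#' Builds clusters of point-mutated copies of independent seed sequences:
#' members of one cluster stay above the identity threshold (two copies
#' mutated at rate m are at least ~1-2m identical), different clusters are
#' unrelated random sequences. Each member carries an archived (PDB-sourced)
#' annotation: the cluster's modal (stoichiometry, symmetry), except for
#' `n_noise` members that carry the alternative annotation. The expected
#' representative of each cluster is computed at generation time by direct
#' frequency arithmetic (the consistency-score majority rule with the
#' minimum-size gate), making the fixture self-verifying; a noise level whose
#' expected outcome is ambiguous (tied maximal score above 0.5) is rejected.
#'
#' @param clusters List of cluster specs: `list(size =, modal = c(stoich,
#'   sym), n_noise = 0, alt = c(stoich, sym))`.
#' @param k Identity threshold the fixture targets (percent).
#' @param seq_length Seed sequence length (residues).
#' @param margin Identity safety margin above the threshold.
#' @param seed Integer seed; identical spec + seed gives identical output.
#' @param dir If non-NULL, write `sequences.fasta` and `annotations.tsv` here.
#' @param min_sizes Minimum-size map used for the expected outcome.
#' @return List with `records` (list of `seq_record`), `annotations` (named
#'   list id -> `qs_annotation`), `expected` (named list cluster id ->
#'   expected `qs_annotation`), `membership` (named character cluster id per
#'   record), and file paths when `dir` is given.
#' @export
make_cluster_fixture <- function(clusters, k = 70, seq_length = 120,
                                 margin = 0.05, seed = 1L, dir = NULL,
                                 min_sizes = default_min_sizes()) {
  set.seed(seed)
  rate <- (1 - k / 100 - margin) / 2
  if (rate < 0) stop("threshold too high for the identity margin")
  records <- list(); annotations <- list(); expected <- list()
  membership <- character(0)
  for (ci in seq_along(clusters)) {
    spec <- clusters[[ci]]
    size <- spec$size
    n_noise <- if (is.null(spec$n_noise)) 0L else spec$n_noise
    if (n_noise > size) stop("more noise members than members")
    alt <- if (is.null(spec$alt)) c("A", "C1") else spec$alt
    base <- random_aa(seq_length)
    cid <- sprintf("CL%02d", ci)
    anns_st <- character(size); anns_sy <- character(size)
    for (mi in seq_len(size)) {
      id <- sprintf("%s_%02d", cid, mi)
      records[[length(records) + 1L]] <- seq_record(id, mutate_sequence(base, rate))
      noisy <- mi > size - n_noise
      anns_st[mi] <- if (noisy) alt[1] else spec$modal[1]
      anns_sy[mi] <- if (noisy) alt[2] else spec$modal[2]
      annotations[[id]] <- qs_annotation(anns_st[mi], anns_sy[mi], source = "PDB")
      membership[id] <- cid
    }
    # expected outcome by direct frequency arithmetic
    key <- as.character(k)
    min_size <- if (key %in% names(min_sizes)) min_sizes[[key]] else 1
    expected[[cid]] <- if (size < min_size) {
      qs_annotation(source = "SC", status = "not_available")
    } else {
      pt <- table(anns_st) / size
      py <- table(anns_sy) / size
      pairs <- unique(paste(anns_st, anns_sy, sep = "/"))
      sc <- vapply(pairs, function(p) {
        tv <- strsplit(p, "/", fixed = TRUE)[[1]]
        as.numeric(pt[tv[1]] * py[tv[2]])
      }, numeric(1))
      if (max(sc) > 0.5 && sum(abs(sc - max(sc)) < 1e-12) > 1L) {
        stop("ambiguous fixture: tied maximal consistency score")
      }
      if (max(sc) > 0.5) {
        tv <- strsplit(pairs[which.max(sc)], "/", fixed = TRUE)[[1]]
        qs_annotation(tv[1], tv[2], source = "SC")
      } else {
        qs_annotation(source = "SC", status = "inconclusive")
      }
    }
  }
  out <- list(records = records, annotations = annotations,
              expected = expected, membership = membership, k = k)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fasta <- file.path(dir, "sequences.fasta")
    seqs <- Biostrings::AAStringSet(vapply(records, `[[`, character(1), "sequence"))
    names(seqs) <- vapply(records, `[[`, character(1), "id")
    Biostrings::writeXStringSet(seqs, fasta)
    tsv <- file.path(dir, "annotations.tsv")
    utils::write.table(
      data.frame(
        id = names(annotations),
        stoichiometry = vapply(annotations, function(a) format(a$stoichiometry), character(1)),
        symmetry = vapply(annotations, function(a) format(a$symmetry), character(1))
      ),
      tsv, sep = "\t", quote = FALSE, row.names = FALSE
    )
    out$fasta <- fasta
    out$tsv <- tsv
  }
  out
}

#' Generate a labelled sentence corpus
#'
#' Emulates the construction of the training corpus: positive sentences
#' mention an oligomeric state together with an experimental-evidence phrase;
#' negative sentences mention the same oligomer keywords in asymmetric-unit
#' or crystal-packing contexts without evidence. Each class draws filler
#' vocabulary from its own word pool; `overlap` controls the fraction of the
#' pools that is shared, which controls how separable the classes are
#' (disjoint pools give a corpus separable by construction).
#'
#' @param n_pos,n_neg Sentences per class.
#' @param vocab_size Words per class pool.
#' @param overlap Fraction of shared vocabulary in \[0, 1\].
#' @param seed Integer seed.
#' @param path If non-NULL, write a TSV (`label` tab `sentence`) here.
#' @return Data frame with columns `label`, `sentence`.
#' @export
make_corpus <- function(n_pos = 200L, n_neg = 200L, vocab_size = 40L,
                        overlap = 0, seed = 1L, path = NULL) {
  set.seed(seed)
  oligo <- names(default_oligomer_keywords())
  evidence <- default_evidence_keywords()
  shared_n <- round(overlap * vocab_size)
  shared <- sprintf("sharedword%03d", seq_len(shared_n))
  pos_pool <- c(sprintf("solutionword%03d", seq_len(vocab_size - shared_n)), shared)
  neg_pool <- c(sprintf("latticeword%03d", seq_len(vocab_size - shared_n)), shared)
  fill <- function(pool) paste(sample(pool, 3, replace = TRUE), collapse = " ")
  pos <- vapply(seq_len(n_pos), function(i) sprintf(
    "The protein forms a stable %s in solution as shown by %s with %s.",
    sample(oligo, 1), sample(evidence, 1), fill(pos_pool)
  ), character(1))
  neg <- vapply(seq_len(n_neg), function(i) sprintf(
    "The asymmetric unit contains a %s related by crystal packing near %s.",
    sample(oligo, 1), fill(neg_pool)
  ), character(1))
  df <- data.frame(
    label = c(rep("positive", n_pos), rep("negative", n_neg)),
    sentence = c(pos, neg), stringsAsFactors = FALSE
  )
  if (nrow(df)) df <- df[sample(nrow(df)), , drop = FALSE]
  rownames(df) <- NULL
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  df
}

#' Read a labelled corpus TSV
#'
#' @param path TSV with columns `label`, `sentence`.
#' @return Data frame.
#' @export
read_corpus_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}

# split the group operators among the entities of a stoichiometry:
# every entity takes the whole group, or the entity blocks partition it
assign_group_operators <- function(counts, ops) {
  g <- length(ops)
  if (all(counts == g)) {
    return(lapply(counts, function(k) ops))
  }
  if (sum(counts) == g) {
    idx <- split(seq_len(g), rep(seq_along(counts), counts))
    return(lapply(idx, function(ix) ops[ix]))
  }
  stop("stoichiometry incompatible with the requested group order ", g)
}

#' Write an assembly-prediction XML fixture
#'
#' Generates the rotation operators of the requested point group
#' analytically, assigns them to chains of the requested stoichiometry, and
#' writes either a PISA-style assembly XML (operators, dissociation energy,
#' surface areas per molecule) or an EPPIC-style prediction XML
#' (stoichiometry and symmetry strings). Round-tripping through the matching
#' parser recovers the stoichiometry, the point group, and the energy.
#'
#' @param stoich Stoichiometry (`qs_stoich` or formula string); entity copy
#'   counts must either all equal the group order or sum to it.
#' @param sym Requested point group (Cn, Dn, T, O; `qs_symmetry` or string).
#' @param dg Dissociation free energy (kcal/mol) for the PISA dialect.
#' @param path Output XML path (or `NULL` to return the document).
#' @param format `"pisa"` or `"eppic"`.
#' @param asa,bsa Surface areas for the PISA dialect.
#' @param assembly_id Assembly id for the PISA dialect.
#' @param center Common fixed point of the generated operators.
#' @return The path (invisibly) or the `xml2` document.
#' @export
make_assembly_xml <- function(stoich, sym, dg = 7.5, path = NULL,
                              format = c("pisa", "eppic"), asa = 12000,
                              bsa = 2500, assembly_id = 1L,
                              center = c(0, 0, 0)) {
  format <- match.arg(format)
  if (is.character(stoich)) stoich <- parse_stoichiometry(stoich)
  if (is.character(sym)) sym <- parse_symmetry(sym)
  if (!sym$family %in% c("C", "D", "T", "O")) {
    stop("generable groups are Cn, Dn, T, O")
  }
  if (format == "eppic") {
    doc <- xml2::xml_new_root("eppic_prediction")
    asm <- xml2::xml_add_child(doc, "assembly")
    xml2::xml_add_child(asm, "stoichiometry", format(stoich))
    xml2::xml_add_child(asm, "symmetry", format(sym))
  } else {
    ops <- point_group_operators(sym, center = center)
    blocks <- assign_group_operators(unclass(stoich), ops)
    doc <- xml2::xml_new_root("pisa_assemblies")
    set <- xml2::xml_add_child(doc, "asm_set")
    asm <- xml2::xml_add_child(set, "assembly")
    xml2::xml_add_child(asm, "id", as.character(assembly_id))
    xml2::xml_add_child(asm, "diss_energy", sprintf("%.10g", dg))
    xml2::xml_add_child(asm, "asa", sprintf("%.10g", asa))
    xml2::xml_add_child(asm, "bsa", sprintf("%.10g", bsa))
    num <- function(x) sprintf("%.12g", x)
    ci <- 0L
    for (e in seq_along(blocks)) {
      for (op in blocks[[e]]) {
        ci <- ci + 1L
        mol <- xml2::xml_add_child(asm, "molecule")
        xml2::xml_add_child(mol, "chain_id", LETTERS[(ci - 1L) %% 26L + 1L])
        xml2::xml_add_child(mol, "entity", names(unclass(stoich))[e])
        lab <- c("rxx", "rxy", "rxz", "ryx", "ryy", "ryz", "rzx", "rzy", "rzz")
        vals <- as.vector(t(op$R))
        for (q in 1:9) xml2::xml_add_child(mol, lab[q], num(vals[q]))
        xml2::xml_add_child(mol, "tx", num(op$t[1]))
        xml2::xml_add_child(mol, "ty", num(op$t[2]))
        xml2::xml_add_child(mol, "tz", num(op$t[3]))
      }
    }
  }
  if (is.null(path)) return(doc)
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Default per-method outcome probabilities for the benchmark generator
#'
#' The study conditions the synthetic benchmark emulates: sequence clustering
#' with a low error rate but a sizeable not-available fraction (small
#' clusters), text mining with a large inconclusive/not-available share, and
#' the two computational methods always producing a call, with accuracies in
#' the reported 46-81% band.
#'
#' @return Matrix (methods x categories) of probabilities, rows summing to 1.
#' @export
default_method_profile <- function() {
  m <- rbind(
    SC    = c(correct = 0.62, incorrect = 0.04, inconclusive = 0.10, not_available = 0.24),
    TM    = c(correct = 0.46, incorrect = 0.14, inconclusive = 0.07, not_available = 0.33),
    PISA  = c(correct = 0.76, incorrect = 0.16, inconclusive = 0.08, not_available = 0.00),
    EPPIC = c(correct = 0.81, incorrect = 0.16, inconclusive = 0.03, not_available = 0.00)
  )
  stopifnot(all(abs(rowSums(m) - 1) < 1e-12))
  m
}

# reference (stoichiometry, symmetry) for an oligomer order
reference_for_order <- function(ord) {
  sym <- switch(as.character(ord),
    "1" = "C1", "2" = "C2", "3" = "C3", "4" = "D2", "6" = "D3",
    "8" = "D4", "12" = "T", paste0("C", ord)
  )
  c(paste0("A", ord), sym)
}

# independent re-statement of the majority rules used as the planted oracle:
# candidates tallied by formula, TM backing the unique co-voted formula of
# its order (standing alone otherwise), strict majority per component
planted_consensus <- function(method_anns) {
  votes <- Filter(function(a) a$status == "predicted", method_anns)
  if (!length(votes)) return(list(status = "not_available"))
  st <- list(); tm_orders <- integer(0)
  sy <- character(0)
  for (a in votes) {
    if (!is.null(a$stoichiometry)) {
      if (a$source == "TM") tm_orders <- c(tm_orders, n_subunits(a$stoichiometry))
      else st[[length(st) + 1L]] <- format(canonicalize_stoichiometry(a$stoichiometry))
    }
    if (!is.null(a$symmetry)) sy <- c(sy, format(a$symmetry))
  }
  n_st <- length(st) + length(tm_orders)
  keys <- unlist(st)
  for (ord in tm_orders) {
    same <- unique(keys[vapply(keys, function(f) n_subunits(parse_stoichiometry(f)) == ord,
                               logical(1))])
    keys <- c(keys, if (length(same) == 1L) same
                    else if (length(same) == 0L) paste0("A", ord))
  }
  st_win <- NULL
  if (length(keys)) {
    tab <- sort(table(keys), decreasing = TRUE)
    if (2 * tab[1] > n_st) st_win <- names(tab)[1]
  }
  sy_win <- NULL
  if (length(sy)) {
    tab <- sort(table(sy), decreasing = TRUE)
    if (2 * tab[1] > length(sy)) sy_win <- names(tab)[1]
  }
  if (is.null(st_win) && is.null(sy_win)) return(list(status = "inconclusive"))
  list(status = "predicted", stoich = st_win, sym = sy_win)
}

#' Generate a benchmark table with planted ground truth
#'
#' Samples reference annotations from the combined benchmark's oligomer
#' composition, then draws an outcome category per method per entry from
#' `profile` and materializes it: a correct method copies the reference (TM
#' keeps only the oligomer order), an incorrect method gets a wrong
#' stoichiometry and symmetry (each dissenting method a different wrong
#' answer, so wrong votes never gang up unless planted to), and
#' inconclusive/not-available statuses are recorded as such. The expected
#' consensus outcome per entry and the expected summary are computed at
#' generation time by an independent tally of the majority rules, so the
#' generator's bookkeeping serves as the oracle for the consensus engine.
#'
#' @param n_entries Number of entries (the combined benchmark has 543).
#' @param profile Methods x categories probability matrix
#'   ([default_method_profile()]).
#' @param seed Integer seed.
#' @param dir If non-NULL, write `benchmark.csv` (wide dialect) and
#'   `expected_summary.csv` here.
#' @return List with `entries` (list of `benchmark_entry`),
#'   `planted_categories` (entries x methods character matrix),
#'   `expected_outcomes` (character vector per entry for the consensus), and
#'   `expected_summary` (data frame in the [benchmark_summary()] layout).
#' @export
make_benchmark_table <- function(n_entries = 543L,
                                 profile = default_method_profile(),
                                 seed = 1L, dir = NULL) {
  set.seed(seed)
  n_entries <- as.integer(n_entries)
  comp <- benchmark_composition()
  comp <- comp[comp$dataset == "combined", ]
  orders <- c(monomer = 1L, dimer = 2L, trimer = 3L, tetramer = 4L,
              hexamer = 6L, octamer = 8L, dodecamer = 12L)[comp$oligomer]
  ref_orders <- sample(orders, n_entries, replace = TRUE,
                       prob = comp$count / sum(comp$count))
  methods <- rownames(profile)
  cats <- colnames(profile)
  planted <- matrix("", n_entries, length(methods),
                    dimnames = list(NULL, methods))
  entries <- vector("list", n_entries)
  expected_outcomes <- character(n_entries)
  for (i in seq_len(n_entries)) {
    ref_pair <- reference_for_order(ref_orders[i])
    ref <- qs_annotation(ref_pair[1], ref_pair[2], source = "PDB")
    anns <- list()
    wrong_slot <- 0L
    for (m in methods) {
      cat_m <- sample(cats, 1, prob = profile[m, ])
      planted[i, m] <- cat_m
      anns[[m]] <- switch(cat_m,
        correct = if (m == "TM") {
          qs_annotation(paste0("A", ref_orders[i]), source = "TM")
        } else {
          qs_annotation(ref_pair[1], ref_pair[2], source = m)
        },
        incorrect = {
          wrong_slot <- wrong_slot + 1L
          wrong_order <- ref_orders[i] + wrong_slot + 12L
          if (m == "TM") {
            qs_annotation(paste0("A", wrong_order), source = "TM")
          } else {
            qs_annotation(paste0("A", wrong_order),
                          paste0("C", wrong_order), source = m)
          }
        },
        inconclusive = qs_annotation(source = m, status = "inconclusive"),
        not_available = qs_annotation(source = m, status = "not_available")
      )
    }
    entries[[i]] <- benchmark_entry(sprintf("S%04d", i), ref,
                                    pdb_annotation = ref,
                                    method_results = anns)
    pc <- planted_consensus(anns)
    expected_outcomes[i] <- if (pc$status != "predicted") {
      pc$status
    } else {
      cmp <- character(0)
      if (!is.null(pc$stoich)) cmp <- c(cmp, pc$stoich == ref_pair[1])
      if (!is.null(pc$sym)) cmp <- c(cmp, pc$sym == ref_pair[2])
      cmp <- as.logical(cmp)
      if (all(cmp)) "correct" else if (all(!cmp)) "incorrect" else "inconclusive"
    }
  }
  expected_summary <- data.frame(
    method = "CONSENSUS",
    pct_correct = 100 * sum(expected_outcomes == "correct") / n_entries,
    pct_incorrect = 100 * sum(expected_outcomes == "incorrect") / n_entries,
    pct_inconclusive = 100 * sum(expected_outcomes == "inconclusive") / n_entries,
    pct_na = 100 * sum(expected_outcomes == "not_available") / n_entries,
    n = n_entries
  )
  out <- list(entries = entries, planted_categories = planted,
              expected_outcomes = expected_outcomes,
              expected_summary = expected_summary)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    out$csv <- file.path(dir, "benchmark.csv")
    write_benchmark_table(entries, out$csv)
    utils::write.csv(expected_summary, file.path(dir, "expected_summary.csv"),
                     row.names = FALSE)
  }
  out
}
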