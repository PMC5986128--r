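#' Default abbreviation guards for sentence splitting
#'
#' Literal tokens whose trailing period does not end a sentence.
#'
#' @return Character vector of abbreviations (with their periods).
#' @export
default_abbreviations <- function() {
  c("Fig.", "Figs.", "fig.", "figs.", "Eq.", "Eqs.", "eq.", "eqs.",
    "Dr.", "Prof.", "et al.", "e.g.", "i.e.", "cf.", "vs.", "ca.",
    "approx.", "Ref.", "Refs.", "ref.", "refs.", "No.", "no.", "resp.")
}

#' Split article text into sentences
#'
#' Sentence boundaries are at sentence-final punctuation (`.`, `!`, `?`)
#' followed by whitespace, with guards for common abbreviations ("Fig.",
#' "et al.", ...) and for decimal points inside numbers. The concatenation of
#' the returned sentences, ignoring whitespace, reconstructs the input.
#'
#' @param full_text Non-empty text.
#' @param abbreviations Abbreviation guard list.
#' @return Character vector of sentences.
#' @export
split_sentences <- function(full_text, abbreviations = default_abbreviations()) {
  if (!is.character(full_text) || length(full_text) != 1L || is.na(full_text) ||
      !nzchar(trimws(full_text))) {
    stop("empty article text")
  }
  guard <- "\x01"
  txt <- full_text
  for (ab in abbreviations) {
    txt <- gsub(ab, gsub(".", guard, ab, fixed = TRUE), txt, fixed = TRUE)
  }
  txt <- gsub("(?<=[0-9])\\.(?=[0-9])", guard, txt, perl = TRUE)
  parts <- strsplit(txt, "(?<=[.!?])\\s+", perl = TRUE)[[1]]
  parts <- gsub(guard, ".", parts, fixed = TRUE)
  trimws(parts[nzchar(trimws(parts))])
}

#' Normalize and tokenize a sentence
#'
#' Lower-cases the text, strips internal punctuation (hyphens included, so
#' "size-exclusion" becomes two tokens), collapses whitespace, and splits on
#' spaces.
#'
#' @param sentence Non-empty string.
#' @return Character vector of lowercase tokens.
#' @export
preprocess <- function(sentence) {
  if (!is.character(sentence) || length(sentence) != 1L || is.na(sentence) ||
      !nzchar(sentence)) {
    stop("empty sentence")
  }
  x <- tolower(sentence)
  x <- gsub("[^a-z0-9]+", " ", x)
  x <- trimws(x)
  if (!nzchar(x)) return(character(0))
  strsplit(x, " ", fixed = TRUE)[[1]]
}

normalize_text <- function(x) {
  trimws(gsub("[^a-z0-9]+", " ", tolower(x)))
}

#' Default oligomeric-state keywords
#'
#' Stems naming oligomer orders, mapped to total subunit counts. Morphological
#' variants (plural, adjectival, homo-/hetero- prefixes) are matched by
#' [keyword_filter()] and [tally_oligomer_keywords()].
#'
#' @return Named integer vector, stem -> oligomer order.
#' @export
default_oligomer_keywords <- function() {
  c(monomer = 1L, dimer = 2L, trimer = 3L, tetramer = 4L, pentamer = 5L,
    hexamer = 6L, heptamer = 7L, octamer = 8L, nonamer = 9L, decamer = 10L,
    undecamer = 11L, dodecamer = 12L)
}

#' Default experimental-evidence keywords
#'
#' Phrases naming solution experiments that establish oligomeric state
#' (matched on normalized text, so hyphenation does not matter).
#'
#' @return Character vector of phrases.
#' @export
default_evidence_keywords <- function() {
  c("size exclusion chromatography", "gel filtration",
    "analytical ultracentrifugation", "sedimentation equilibrium",
    "sedimentation velocity", "light scattering", "native page",
    "cross linking", "crosslinking", "native mass spectrometry",
    "isothermal titration calorimetry")
}

#' Read a one-term-per-line keyword file
#'
#' @param path Text file, one keyword or phrase per line; blank lines and
#'   lines starting with `#` are skipped.
#' @return Character vector.
#' @export
read_keyword_file <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

keyword_regex <- function(stem, variants = TRUE) {
  if (variants) paste0("\\b(homo|hetero)?", stem, "(s|ic|ics)?\\b")
  else paste0("\\b", stem, "\\b")
}

#' Filter sentences by keyword occurrence
#'
#' Case-insensitive whole-word matching on normalized text; with
#' `variants = TRUE` a stem also matches its plural, adjectival and
#' homo-/hetero- forms (dimer, dimers, dimeric, homodimer, heterodimeric...).
#' The returned subset preserves input order.
#'
#' @param sentences Character vector.
#' @param keywords Character vector of stems or phrases.
#' @param variants Match morphological variants of each stem.
#' @return Subset of `sentences`.
#' @export
keyword_filter <- function(sentences, keywords, variants = TRUE) {
  if (length(keywords) == 0L) stop("keyword list must be non-empty")
  pats <- vapply(normalize_text(keywords), keyword_regex, character(1),
                 variants = variants)
  norm <- vapply(sentences, normalize_text, character(1), USE.NAMES = FALSE)
  hit <- vapply(norm, function(s) any(vapply(pats, grepl, logical(1), x = s)),
                logical(1))
  sentences[hit]
}

#' Term frequency - inverse document frequency weights
#'
#' For token n in sentence s, tf-idf(n, s) = tf(n, s) x log(N / df(n)) with
#' natural log, where tf is the raw count of n in s, df(n) the number of
#' sentences containing n, and N the corpus size. A token present in every
#' sentence has weight 0 everywhere.
#'
#' @param corpus List of token vectors (one per sentence).
#' @return List with `model` (list `N`, `df` named counts) and `vectors`
#'   (list of named numeric weight vectors, one per sentence).
#' @export
tfidf_weights <- function(corpus) {
  if (length(corpus) == 0L) stop("empty corpus")
  N <- length(corpus)
  df <- table(unlist(lapply(corpus, unique)))
  df <- stats::setNames(as.integer(df), names(df))
  model <- structure(list(N = N, df = df), class = "tfidf_model")
  vectors <- lapply(corpus, function(tokens) tfidf_transform(model, tokens))
  list(model = model, vectors = vectors)
}

# weight one tokenized sentence under a fitted tf-idf model;
# unseen tokens get df = 1 (maximally informative)
tfidf_transform <- function(model, tokens) {
  if (length(tokens) == 0L) return(stats::setNames(numeric(0), character(0)))
  tf <- table(tokens)
  d <- ifelse(names(tf) %in% names(model$df), model$df[names(tf)], 1L)
  stats::setNames(as.numeric(tf) * log(model$N / as.numeric(d)), names(tf))
}

#' Hash a weighted token vector into a fixed-dimension feature vector
#'
#' Feature hashing: each token's bucket is MurmurHash3(token) mod dim;
#' weights of colliding tokens are summed. With `signed = TRUE` a second hash
#' assigns each token a +/-1 sign so collisions cancel in expectation; with
#' unsigned hashing the sum of weights is conserved across buckets.
#'
#' @param weights Named numeric vector (token -> weight).
#' @param dim Number of buckets (a power of two; default 2^18).
#' @param signed Use sign hashing.
#' @param seed Hash seed.
#' @return A `hashed_vec`: list with `i` (1-based bucket indices), `x`
#'   (values), `dim`.
#' @export
hash_features <- function(weights, dim = 2^18, signed = TRUE, seed = 0L) {
  if (dim < 1 || abs(log2(dim) - round(log2(dim))) > 1e-9) {
    stop("dim must be a power of two")
  }
  if (length(weights) == 0L) {
    return(structure(list(i = integer(0), x = numeric(0), dim = dim),
                     class = "hashed_vec"))
  }
  toks <- names(weights)
  bucket <- murmur3_hash(toks, seed = seed) %% dim
  sgn <- if (signed) 1 - 2 * (murmur3_hash(toks, seed = seed + 1L) %% 2) else rep(1, length(toks))
  agg <- tapply(as.numeric(weights) * sgn, bucket, sum)
  structure(
    list(i = as.integer(names(agg)) + 1L, x = as.numeric(agg), dim = dim),
    class = "hashed_vec"
  )
}

hashed_to_matrix <- function(hvs) {
  stopifnot(length(hvs) > 0L)
  dim <- hvs[[1]]$dim
  m <- matrix(0, nrow = length(hvs), ncol = dim)
  for (r in seq_along(hvs)) m[r, hvs[[r]]$i] <- hvs[[r]]$x
  m
}
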