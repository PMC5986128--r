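#' Sentence-classifier configuration
#'
#' Holds the training hyper-parameters. Defaults follow the values tuned on
#' the original 11,000-sentence corpus by 10-fold cross-validated grid
#' search: RBF-kernel SVM with sigma = 0.013 and cost = 4, or boosted
#' logistic regression with 101 boosting iterations. `hash_bits` sets the
#' feature-hashing dimension (2^hash_bits buckets) used for the training
#' matrix; 2^12 keeps dense matrices modest for corpora of a few thousand
#' sentences (the standalone [hash_features()] default remains 2^18).
#'
#' @param algorithm `"svm"` (RBF-kernel support vector machine) or `"blr"`
#'   (boosted logistic regression).
#' @param sigma RBF kernel width (kernlab's sigma parametrization).
#' @param cost SVM cost penalty.
#' @param iterations Boosting rounds for BLR.
#' @param cv_folds Cross-validation folds (metadata; recorded, not run).
#' @param split Training fraction of the corpus.
#' @param hash_bits log2 of the hashed feature dimension.
#' @param signed Use sign hashing.
#' @return A `classifier_config` list.
#' @export
classifier_config <- function(algorithm = c("svm", "blr"), sigma = 0.013,
                              cost = 4, iterations = 101L, cv_folds = 10L,
                              split = 0.8, hash_bits = 12L, signed = TRUE) {
  algorithm <- match.arg(algorithm)
  stopifnot(sigma > 0, cost > 0, iterations >= 1, split > 0, split < 1)
  structure(
    list(algorithm = algorithm, sigma = sigma, cost = cost,
         iterations = as.integer(iterations), cv_folds = as.integer(cv_folds),
         split = split, hash_bits = as.integer(hash_bits), signed = signed),
    class = "classifier_config"
  )
}

corpus_to_features <- function(sentences, tfidf_model, config) {
  toks <- lapply(sentences, preprocess)
  hvs <- lapply(toks, function(tk) {
    hash_features(tfidf_transform(tfidf_model, tk),
                  dim = 2^config$hash_bits, signed = config$signed)
  })
  hashed_to_matrix(hvs)
}

#' Train the quaternary-structure sentence classifier
#'
#' Tokenizes and tf-idf-weights a labelled sentence corpus, hashes the
#' features, performs a stratified train/test split, fits the configured
#' classifier on the training part, and reports the full metric set on the
#' held-out part.
#'
#' @param corpus Data frame with columns `label` (`"positive"`/`"negative"`)
#'   and `sentence`.
#' @param config A [classifier_config()].
#' @param seed Integer seed controlling the split.
#' @return A `sentence_classifier`: list with `fit`, `config`, `tfidf`,
#'   `metrics` (held-out [evaluate_classifier()] output), `levels`.
#' @export
train_classifier <- function(corpus, config = classifier_config(), seed = 1L) {
  stopifnot(is.data.frame(corpus), all(c("label", "sentence") %in% names(corpus)))
  y <- factor(corpus$label, levels = c("negative", "positive"))
  if (any(is.na(y))) stop("labels must be 'positive' or 'negative'")
  if (nlevels(droplevels(y)) < 2L) stop("both classes must be present in the corpus")

  tf <- tfidf_weights(lapply(corpus$sentence, preprocess))
  hvs <- lapply(tf$vectors, hash_features, dim = 2^config$hash_bits,
                signed = config$signed)
  X <- hashed_to_matrix(hvs)

  set.seed(seed)
  train_idx <- unlist(lapply(split(seq_along(y), y), function(ix) {
    sample(ix, round(config$split * length(ix)))
  }), use.names = FALSE)
  test_idx <- setdiff(seq_along(y), train_idx)
  if (!length(test_idx)) stop("corpus too small for the configured split")

  fit <- if (config$algorithm == "svm") {
    kernlab::ksvm(X[train_idx, , drop = FALSE], y[train_idx], type = "C-svc",
                  kernel = "rbfdot", kpar = list(sigma = config$sigma),
                  C = config$cost, scaled = FALSE)
  } else {
    caTools::LogitBoost(X[train_idx, , drop = FALSE], y[train_idx],
                        nIter = config$iterations)
  }

  model <- structure(
    list(fit = fit, config = config, tfidf = tf$model,
         levels = c("negative", "positive")),
    class = "sentence_classifier"
  )
  scored <- classify_sentences(model, corpus$sentence[test_idx])
  model$metrics <- evaluate_classifier(scored$label, as.character(y[test_idx]),
                                       scores = scored$score)
  model
}

#' Classify sentences with a trained model
#'
#' @param model A `sentence_classifier`.
#' @param sentences Character vector.
#' @return Data frame with `sentence`, `label` (`"positive"`/`"negative"`),
#'   and `score` (higher favors the positive class).
#' @export
classify_sentences <- function(model, sentences) {
  stopifnot(inherits(model, "sentence_classifier"))
  if (length(sentences) == 0L) {
    return(data.frame(sentence = character(0), label = character(0),
                      score = numeric(0)))
  }
  X <- corpus_to_features(sentences, model$tfidf, model$config)
  if (model$config$algorithm == "svm") {
    dec <- kernlab::predict(model$fit, X, type = "decision")
    score <- as.numeric(dec)
    # kernlab orients the decision value by its internal label order
    lab <- as.character(kernlab::predict(model$fit, X))
    if (length(score) && any(lab == "positive") &&
        stats::median(score[lab == "positive"]) < 0) score <- -score
  } else {
    pr <- caTools::predict.LogitBoost(model$fit, X, type = "raw")
    score <- pr[, "positive"]
    score[is.na(score)] <- 0.5
    lab <- ifelse(score > 0.5, "positive", "negative")
  }
  data.frame(sentence = sentences, label = lab, score = score,
             stringsAsFactors = FALSE)
}

#' Classification metric set from predictions and truth
#'
#' Computes accuracy, Cohen's kappa, AUC (from scores, via pROC), sensitivity,
#' specificity, positive and negative predictive value, F1, and the Matthews
#' correlation coefficient, treating `"positive"` as the positive class.
#'
#' @param predictions Character vector of predicted labels.
#' @param truth Character vector of true labels, same length.
#' @param scores Optional numeric scores for AUC (higher = more positive).
#' @return Named list of metrics (AUC is `NA` without scores).
#' @export
evaluate_classifier <- function(predictions, truth, scores = NULL) {
  if (length(predictions) == 0L || length(predictions) != length(truth)) {
    stop("predictions and truth must be equal-length and non-empty")
  }
  tp <- sum(predictions == "positive" & truth == "positive")
  tn <- sum(predictions == "negative" & truth == "negative")
  fp <- sum(predictions == "positive" & truth == "negative")
  fn <- sum(predictions == "negative" & truth == "positive")
  n <- tp + tn + fp + fn
  acc <- (tp + tn) / n
  p_e <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (p_e == 1) 0 else (acc - p_e) / (1 - p_e)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  f1 <- if (!is.na(ppv) && !is.na(sens) && ppv + sens > 0) {
    2 * ppv * sens / (ppv + sens)
  } else NA_real_
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den else 0
  auc <- NA_real_
  if (!is.null(scores) && length(unique(truth)) == 2L) {
    auc <- as.numeric(pROC::auc(pROC::roc(
      response = factor(truth, levels = c("negative", "positive")),
      predictor = scores, quiet = TRUE, direction = "<"
    )))
  }
  list(accuracy = acc, kappa = kappa, auc = auc, sensitivity = sens,
       specificity = spec, ppv = ppv, npv = npv, f1 = f1, mcc = mcc)
}

#' Tally oligomer-order keywords in sentences
#'
#' Counts occurrences of each oligomeric-state stem (with morphological
#' variants) across the given sentences.
#'
#' @param sentences Character vector.
#' @param oligo_keywords Named integer vector stem -> order.
#' @return Named integer vector of occurrence counts per stem.
#' @export
tally_oligomer_keywords <- function(sentences,
                                    oligo_keywords = default_oligomer_keywords()) {
  norm <- vapply(sentences, normalize_text, character(1), USE.NAMES = FALSE)
  counts <- vapply(names(oligo_keywords), function(stem) {
    pat <- keyword_regex(stem, variants = TRUE)
    sum(vapply(norm, function(s) {
      hits <- gregexpr(pat, s, perl = TRUE)[[1]]
      sum(hits > 0)
    }, numeric(1)))
  }, numeric(1))
  stats::setNames(as.integer(counts), names(oligo_keywords))
}

#' Extract a stoichiometry prediction from article text
#'
#' The full text-mining pipeline: split the article into sentences, keep the
#' sentences mentioning an oligomeric-state keyword, keep those the trained
#' classifier labels quaternary-structure relevant, keep those carrying
#' experimental-evidence keywords (same-sentence by default; set
#' `evidence_scope = "article"` to accept evidence anywhere in the article),
#' then tally the oligomer keywords of the survivors. A strict majority
#' (winning count > half the tally) predicts the oligomer order n, encoded as
#' stoichiometry "An"; a tie or empty tally is inconclusive; a missing
#' article is not_available. Text mining never emits symmetry.
#'
#' @param article_text Full article text, or `NULL`/empty if unavailable.
#' @param model A trained `sentence_classifier`.
#' @param oligo_keywords Named integer vector stem -> order.
#' @param evidence_keywords Character vector of evidence phrases.
#' @param evidence_scope `"sentence"` or `"article"`.
#' @return A `qs_annotation` with source `"TM"`.
#' @export
extract_stoichiometry <- function(article_text, model,
                                  oligo_keywords = default_oligomer_keywords(),
                                  evidence_keywords = default_evidence_keywords(),
                                  evidence_scope = c("sentence", "article")) {
  evidence_scope <- match.arg(evidence_scope)
  if (is.null(article_text) || !nzchar(trimws(paste(article_text, collapse = " ")))) {
    return(qs_annotation(source = "TM", status = "not_available"))
  }
  sentences <- split_sentences(paste(article_text, collapse = " "))
  cand <- keyword_filter(sentences, names(oligo_keywords), variants = TRUE)
  if (length(cand)) {
    scored <- classify_sentences(model, cand)
    cand <- cand[scored$label == "positive"]
  }
  if (length(cand)) {
    if (evidence_scope == "sentence") {
      cand <- keyword_filter(cand, evidence_keywords, variants = FALSE)
    } else {
      any_ev <- length(keyword_filter(sentences, evidence_keywords,
                                      variants = FALSE)) > 0
      if (!any_ev) cand <- character(0)
    }
  }
  if (!length(cand)) {
    return(qs_annotation(source = "TM", status = "inconclusive"))
  }
  tally <- tally_oligomer_keywords(cand, oligo_keywords)
  tally <- tally[tally > 0]
  if (!length(tally) || max(tally) * 2 <= sum(tally)) {
    return(qs_annotation(source = "TM", status = "inconclusive"))
  }
  order_n <- oligo_keywords[[names(tally)[which.max(tally)]]]
  qs_annotation(paste0("A", order_n), source = "TM", status = "predicted")
}
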