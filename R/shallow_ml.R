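#' Build sentence-level training/prediction instances
#'
#' One instance per (sentence, candidate pair): the sentence's token layer
#' plus the token spans of the chemical and the disease mention. Instances
#' are the unit the relation classifier trains on and predicts over; the
#' paper-style protocol labels an instance true when the identifier pair is
#' in the gold standard.
#'
#' @param sents A `cid_sentences` object.
#' @param cand Candidate tibble with `scope = "sentence"` rows (typically
#'   [sentence_cooccurrences()] output, labeled via [label_candidates()]).
#' @return A list of instance objects (class `cid_instance`): fields `pmid`,
#'   `chemical_id`, `disease_id`, `sentence_index`, `tokens`, `e1`, `e2`
#'   (token index ranges of chemical and disease), `label`.
#' @export
build_instances <- function(sents, cand) {
  stopifnot(inherits(sents, "cid_sentences"))
  cand <- cand[cand$scope == "sentence", , drop = FALSE]
  m <- active_mentions(sents)
  out <- list()
  for (i in seq_len(nrow(cand))) {
    sis <- as.integer(strsplit(cand$sentence_indices[i], ",")[[1]])
    for (si in sis) {
      stext <- sents$sentences$text[match(si, sents$sentences$index)]
      toks <- annotate_tokens(stext, sentence_id = paste0(sents$pmid, ":", si))
      ms <- m[m$sentence_index == si, , drop = FALSE]
      chem_rows <- which(ms$type == "Chemical" &
        vapply(ms$concept_id, function(id)
          cand$chemical_id[i] %in% expand_ids(id), logical(1)))
      dis_rows <- which(ms$type == "Disease" &
        vapply(ms$concept_id, function(id)
          cand$disease_id[i] %in% expand_ids(id), logical(1)))
      if (!length(chem_rows) || !length(dis_rows)) next
      span_tokens <- function(r) {
        which(toks$start < ms$local_end[r] & ms$local_start[r] < toks$end)
      }
      e1 <- NULL; e2 <- NULL
      for (cr in chem_rows) for (dr in dis_rows) {
        t1 <- span_tokens(cr); t2 <- span_tokens(dr)
        if (length(t1) && length(t2) && !length(intersect(t1, t2))) {
          e1 <- t1; e2 <- t2; break
        }
      }
      if (is.null(e1)) next
      out[[length(out) + 1]] <- structure(
        list(pmid = sents$pmid, chemical_id = cand$chemical_id[i],
             disease_id = cand$disease_id[i], sentence_index = si,
             tokens = toks, e1 = e1, e2 = e2,
             label = if ("label" %in% names(cand)) cand$label[i] else NA),
        class = "cid_instance")
    }
  }
  out
}

#' Extract shallow-linguistic features for one instance
#'
#' The feature scheme of the shallow-linguistic (global + local context)
#' kernel family: the two entity mentions are collapsed to single
#' `CHEMICAL` / `DISEASE` placeholder tokens (entity blinding, applied to
#' every attribute), then
#'
#' * global contexts — n-grams (n = 1..`ngram_max`) of each token attribute
#'   (lower-cased surface, lemma, stem, POS) over three windows:
#'   fore-between (`fb`, sentence start through the second entity), between
#'   (`b`, first entity through second entity) and between-after (`ba`,
#'   first entity through sentence end);
#' * local contexts — the attribute values of the `window` tokens to each
#'   side of each entity, indexed by signed relative position.
#'
#' Feature names are deterministic strings encoding context, attribute,
#' n-gram order and content; the vector is a binary presence map.
#'
#' @param inst A `cid_instance`.
#' @param ngram_max Maximum n-gram order for global contexts.
#' @param window Local-context half-width in tokens.
#' @param attrs Token attributes to use.
#' @return A named numeric vector of 1s (sparse presence map).
#' @export
extract_features <- function(inst, ngram_max = 3, window = 2,
                             attrs = c("surface", "lemma", "stem", "pos")) {
  units <- blinded_units(inst)
  p1 <- which(units$role != "")[1]
  p2 <- which(units$role != "")[2]
  n <- nrow(units)
  ctxs <- list(fb = seq_len(p2), b = p1:p2, ba = p1:n)
  feats <- character(0)
  for (cn in names(ctxs)) {
    idx <- ctxs[[cn]]
    for (a in attrs) {
      vals <- units[[a]][idx]
      for (g in seq_len(min(ngram_max, length(vals)))) {
        for (s in seq_len(length(vals) - g + 1)) {
          feats <- c(feats, paste("g", cn, a, g,
                                  paste(vals[s:(s + g - 1)], collapse = "_"),
                                  sep = "|"))
        }
      }
    }
  }
  for (role in c("CHEMICAL", "DISEASE")) {
    e <- which(units$role == role)
    for (d in c(-seq_len(window), seq_len(window))) {
      j <- e + d
      if (j >= 1 && j <= n) {
        for (a in attrs) {
          feats <- c(feats, paste("l", role, d, a, units[[a]][j], sep = "|"))
        }
      }
    }
  }
  feats <- unique(feats)
  stats::setNames(rep(1, length(feats)), feats)
}

# Collapse entity token spans to single placeholder units; all attributes of
# an entity unit equal its role placeholder.
blinded_units <- function(inst) {
  toks <- inst$tokens
  n <- nrow(toks)
  role <- character(n)
  role[inst$e1] <- "CHEMICAL"
  role[inst$e2] <- "DISEASE"
  keep <- rep(TRUE, n)
  for (idx in list(inst$e1, inst$e2)) {
    if (length(idx) > 1) keep[idx[-1]] <- FALSE
  }
  u <- tibble::tibble(
    surface = tolower(toks$token), lemma = toks$lemma, stem = toks$stem,
    pos = toks$pos, role = role)[keep, , drop = FALSE]
  ent <- u$role != ""
  u$surface[ent] <- u$role[ent]
  u$lemma[ent] <- u$role[ent]
  u$stem[ent] <- u$role[ent]
  u$pos[ent] <- u$role[ent]
  u
}

features_to_matrix <- function(fvs, vocab) {
  X <- matrix(0, nrow = length(fvs), ncol = length(vocab),
              dimnames = list(NULL, vocab))
  for (i in seq_along(fvs)) {
    j <- match(names(fvs[[i]]), vocab)
    ok <- !is.na(j)
    X[i, j[ok]] <- fvs[[i]][ok]
  }
  X
}

#' Train the relation classifier
#'
#' A linear-kernel support vector machine over the shallow-linguistic
#' feature space, with class weights inversely proportional to class
#' frequency. The fitted model stores the feature vocabulary and the
#' explicit primal weight vector (recovered from the support vectors), so
#' the decision function can be re-scored independently of the SVM backend.
#'
#' @param instances List of labeled `cid_instance` objects (both classes
#'   must be present).
#' @param cost SVM regularization parameter C.
#' @param seed Integer seed (recorded; training itself is deterministic).
#' @param ngram_max,window Passed to [extract_features()].
#' @return An object of class `cid_model`.
#' @export
train_relation_model <- function(instances, cost = 1, seed = 42,
                                 ngram_max = 3, window = 2) {
  labels <- vapply(instances, function(x) isTRUE(x$label), logical(1))
  if (length(unique(labels)) < 2) {
    stop("training error: need at least one instance of each class",
         call. = FALSE)
  }
  set.seed(seed)
  fvs <- lapply(instances, extract_features, ngram_max = ngram_max,
                window = window)
  vocab <- sort(unique(unlist(lapply(fvs, names))))
  X <- features_to_matrix(fvs, vocab)
  y <- factor(ifelse(labels, "true", "false"), levels = c("false", "true"))
  cw <- length(y) / (2 * table(y))
  fit <- e1071::svm(X, y, kernel = "linear", cost = cost, scale = FALSE,
                    class.weights = stats::setNames(as.numeric(cw),
                                                    names(cw)))
  w <- as.numeric(crossprod(fit$coefs, fit$SV))
  b <- fit$rho
  # libsvm's decision value is positive for its internally-first label;
  # normalize so that score > 0 means "true".
  sign_flip <- if (fit$levels[fit$labels[1]] == "true") 1 else -1
  structure(list(fit = fit, vocab = vocab, w = w * sign_flip,
                 b = b * sign_flip, cost = cost, seed = seed,
                 ngram_max = ngram_max, window = window,
                 n_train = length(instances)),
            class = "cid_model")
}

#' @export
print.cid_model <- function(x, ...) {
  cat("<cid_model> linear SVM, C = ", x$cost, ", ", length(x$vocab),
      " features, trained on ", x$n_train, " instances\n", sep = "")
  invisible(x)
}

#' Decision values for instances
#'
#' @param model A `cid_model`.
#' @param instances List of `cid_instance` objects.
#' @param method `"svm"` scores through the fitted backend;
#'   `"weights"` recomputes the decision function as `X w - b` from the
#'   stored primal weights. The two agree up to numerical tolerance.
#' @return Numeric scores; positive means predicted true.
#' @export
decision_values <- function(model, instances, method = c("svm", "weights")) {
  method <- match.arg(method)
  if (!length(instances)) return(numeric(0))
  fvs <- lapply(instances, extract_features, ngram_max = model$ngram_max,
                window = model$window)
  X <- features_to_matrix(fvs, model$vocab)
  if (method == "weights") {
    return(as.numeric(X %*% model$w) - model$b)
  }
  pr <- stats::predict(model$fit, X, decision.values = TRUE)
  dv <- as.numeric(attr(pr, "decision.values"))
  pos_first <- model$fit$levels[model$fit$labels[1]] == "true"
  if (pos_first) dv else -dv
}

#' Predict CID relations with the classifier
#'
#' Scores every instance and returns the pairs predicted positive as a
#' candidate tibble with `source = "ml"` (deduplicated on identifiers: a
#' pair is positive if any of its sentence instances is).
#'
#' @param model A `cid_model`.
#' @param instances List of `cid_instance` objects.
#' @return A list with `scores` (per instance), `labels` (logical per
#'   instance) and `pairs` (candidate tibble of positives).
#' @export
predict_relations <- function(model, instances) {
  if (!length(instances)) {
    return(list(scores = numeric(0), labels = logical(0),
                pairs = empty_candidates()))
  }
  scores <- decision_values(model, instances, method = "svm")
  labels <- scores > 0
  pos <- which(labels)
  pairs <- if (length(pos)) {
    candidate_order(dplyr::distinct(dplyr::bind_rows(lapply(pos, function(i) {
      tibble::tibble(pmid = instances[[i]]$pmid,
                     chemical_id = instances[[i]]$chemical_id,
                     disease_id = instances[[i]]$disease_id,
                     scope = "sentence",
                     sentence_indices =
                       as.character(instances[[i]]$sentence_index),
                     label = NA, source = "ml")
    })), .data$pmid, .data$chemical_id, .data$disease_id, .keep_all = TRUE))
  } else {
    empty_candidates()
  }
  list(scores = scores, labels = labels, pairs = pairs)
}

#' Stratified k-fold cross-validation of the classifier
#'
#' Folds are stratified by label with sizes differing by at most one;
#' per-fold precision, recall and F-score (percent, positive class) are
#' averaged unweighted into the aggregate report.
#'
#' @param instances Labeled `cid_instance` list.
#' @param k Number of folds (at most the minority-class count).
#' @param cost,ngram_max,window Passed to [train_relation_model()].
#' @param seed Seed controlling fold assignment.
#' @return An object of class `cid_cv_report`: `folds` (per-fold tibble),
#'   `precision`, `recall`, `f_score` (aggregate, percent), `k`, `seed`.
#' @export
cross_validate <- function(instances, k = 10, cost = 1, seed = 42,
                           ngram_max = 3, window = 2) {
  n <- length(instances)
  if (k > n) stop("k = ", k, " exceeds the number of instances (", n, ")",
                  call. = FALSE)
  labels <- vapply(instances, function(x) isTRUE(x$label), logical(1))
  if (k > min(table(labels))) {
    stop("k = ", k, " exceeds the minority class count (",
         min(table(labels)), ")", call. = FALSE)
  }
  set.seed(seed)
  fold <- integer(n)
  for (cl in c(TRUE, FALSE)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  # features are a pure function of the instance: extract once, reuse per fold
  fvs <- lapply(instances, extract_features, ngram_max = ngram_max,
                window = window)
  rows <- lapply(seq_len(k), function(f) {
    tr <- which(fold != f)
    te <- which(fold == f)
    vocab <- sort(unique(unlist(lapply(fvs[tr], names))))
    Xtr <- features_to_matrix(fvs[tr], vocab)
    ytr <- factor(ifelse(labels[tr], "true", "false"),
                  levels = c("false", "true"))
    cw <- length(ytr) / (2 * table(ytr))
    fit <- e1071::svm(Xtr, ytr, kernel = "linear", cost = cost,
                      scale = FALSE,
                      class.weights = stats::setNames(as.numeric(cw),
                                                      names(cw)))
    Xte <- features_to_matrix(fvs[te], vocab)
    pred <- as.character(stats::predict(fit, Xte)) == "true"
    truth <- labels[te]
    tp <- sum(pred & truth); fp <- sum(pred & !truth)
    fn <- sum(!pred & truth)
    p <- if (tp + fp == 0) 0 else 100 * tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else 100 * tp / (tp + fn)
    f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    tibble::tibble(fold = f, n_test = length(te), tp = tp, fp = fp, fn = fn,
                   precision = p, recall = r, f_score = f1)
  })
  folds <- dplyr::bind_rows(rows)
  structure(list(folds = folds,
                 precision = mean(folds$precision),
                 recall = mean(folds$recall),
                 f_score = mean(folds$f_score),
                 k = k, seed = seed),
            class = "cid_cv_report")
}

#' @export
print.cid_cv_report <- function(x, ...) {
  cat(sprintf(
    "<cid_cv_report> %d-fold CV: P = %.2f%%, R = %.2f%%, F = %.2f%%\n",
    x$k, x$precision, x$recall, x$f_score))
  invisible(x)
}
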