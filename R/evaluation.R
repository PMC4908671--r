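round_half_up <- function(x, digits = 2) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

#' Harmonic mean of precision and recall (percent)
#'
#' `F = 2PR / (P + R)`, rounded half-up to two decimals (0 when both are
#' zero), on the percentage scale of published result tables.
#'
#' @param p Precision in percent, in \[0, 100\].
#' @param r Recall in percent, in \[0, 100\].
#' @return F-score in percent, two decimals.
#' @export
f_score <- function(p, r) {
  if (any(p < 0 | p > 100) || any(r < 0 | r > 100)) {
    stop("precision and recall must be percentages in [0, 100]",
         call. = FALSE)
  }
  f <- ifelse(p + r == 0, 0, 2 * p * r / (p + r))
  round_half_up(f, 2)
}

#' Document-level scoring of predicted CID pairs
#'
#' Predictions and gold are sets of (pmid, chemical id, disease id)
#' triples; scoring is identifier-exact, mention offsets play no role.
#' `tp = |pred ∩ gold|`, `fp = |pred \\ gold|`, `fn = |gold \\ pred|`;
#' precision, recall and F are percentages (0 whenever the denominator is
#' 0), reported both unrounded and rounded half-up to two decimals.
#'
#' @param pred Tibble with columns `pmid`, `chemical_id`, `disease_id` (a
#'   candidate tibble works as-is; duplicates are collapsed).
#' @param gold Tibble with the same columns.
#' @return An object of class `cid_eval`: `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f_score` (rounded) and `precision_raw`, `recall_raw`,
#'   `f_score_raw`.
#' @export
score_documents <- function(pred, gold) {
  pk <- unique(paste(pred$pmid, pred$chemical_id, pred$disease_id,
                     sep = "\r"))
  gk <- unique(paste(gold$pmid, gold$chemical_id, gold$disease_id,
                     sep = "\r"))
  if (!nrow(pred)) pk <- character(0)
  if (!nrow(gold)) gk <- character(0)
  tp <- length(intersect(pk, gk))
  fp <- length(setdiff(pk, gk))
  fn <- length(setdiff(gk, pk))
  p <- if (tp + fp == 0) 0 else 100 * tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else 100 * tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = round_half_up(p), recall = round_half_up(r),
                 f_score = round_half_up(f),
                 precision_raw = p, recall_raw = r, f_score_raw = f),
            class = "cid_eval")
}

#' @export
print.cid_eval <- function(x, ...) {
  cat(sprintf(
    "<cid_eval> TP %d  FP %d  FN %d | P %.2f%%  R %.2f%%  F %.2f%%\n",
    x$tp, x$fp, x$fn, x$precision, x$recall, x$f_score))
  invisible(x)
}

#' Stratify gold relations by expression level
#'
#' Classifies every gold CID relation of a corpus as sentence-expressible
#' (its chemical and disease identifiers co-occur, via annotated mentions,
#' in at least one sentence) or abstract-only (the entities never share a
#' sentence, so the relation spans multiple sentences). Uses the raw
#' mention layer — filtering is a detection concern, not a gold property.
#'
#' @param docs A `cid_document` or list of them.
#' @return A list: `n_gold`, `n_sentence_level`, `n_abstract_only`,
#'   `pct_sentence_level`, `pct_abstract_only`, and a per-relation tibble
#'   `detail`.
#' @export
stratify_gold_levels <- function(docs) {
  if (inherits(docs, "cid_document")) docs <- list(docs)
  rows <- list()
  for (doc in docs) {
    if (!nrow(doc$gold)) next
    sents <- split_sentences(doc)
    m <- sents$mentions
    sent_pairs <- character(0)
    for (si in unique(m$sentence_index)) {
      ms <- m[m$sentence_index == si, , drop = FALSE]
      cc <- expand_ids(ms$concept_id[ms$type == "Chemical"])
      dd <- expand_ids(ms$concept_id[ms$type == "Disease"])
      if (length(cc) && length(dd)) {
        sent_pairs <- c(sent_pairs,
                        paste(rep(cc, each = length(dd)),
                              rep(dd, times = length(cc)), sep = "\r"))
      }
    }
    gkey <- paste(doc$gold$chemical_id, doc$gold$disease_id, sep = "\r")
    rows[[length(rows) + 1]] <- tibble::tibble(
      pmid = doc$pmid, chemical_id = doc$gold$chemical_id,
      disease_id = doc$gold$disease_id,
      sentence_level = gkey %in% sent_pairs)
  }
  detail <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(pmid = character(), chemical_id = character(),
                   disease_id = character(), sentence_level = logical())
  n <- nrow(detail)
  ns <- sum(detail$sentence_level)
  list(n_gold = n, n_sentence_level = ns, n_abstract_only = n - ns,
       pct_sentence_level = if (n) 100 * ns / n else 0,
       pct_abstract_only = if (n) 100 * (n - ns) / n else 0,
       detail = detail)
}
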