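empty_candidates <- function() {
  tibble::tibble(pmid = character(), chemical_id = character(),
                 disease_id = character(), scope = character(),
                 sentence_indices = character(), label = logical(),
                 source = character())
}

# Expand a mention's concept id: drop unnormalized ("-1"), optionally split
# composite "|"-joined ids into their components.
expand_ids <- function(ids, expand_composite = TRUE) {
  ids <- ids[ids != "-1" & !is.na(ids)]
  if (expand_composite) {
    ids <- unlist(strsplit(ids, "|", fixed = TRUE), use.names = FALSE)
    ids <- ids[ids != "-1" & nzchar(ids)]
  } else {
    ids <- ids[!grepl("|", ids, fixed = TRUE)]
  }
  unique(ids)
}

candidate_order <- function(cand) {
  cand[order(cand$pmid, cand$chemical_id, cand$disease_id), , drop = FALSE]
}

#' Sentence-level chemical-disease co-occurrence candidates
#'
#' One candidate per unique (chemical id, disease id) pair whose two
#' entities co-occur, after NER post-processing, in at least one sentence;
#' `sentence_indices` lists every such sentence (comma-joined). Unnormalized
#' mentions (`concept_id == "-1"`) can never match identifier-level gold and
#' are excluded; composite "|"-joined ids are expanded one candidate per
#' component id (set `expand_composite = FALSE` to drop them instead).
#'
#' @param sents A `cid_sentences` object (filters applied).
#' @param expand_composite Expand composite concept ids?
#' @return A candidate tibble sorted by (pmid, chemical_id, disease_id) with
#'   `scope = "sentence"`, `source = "cooccurrence"`, label `NA`.
#' @export
sentence_cooccurrences <- function(sents, expand_composite = TRUE) {
  stopifnot(inherits(sents, "cid_sentences"))
  m <- active_mentions(sents)
  rows <- list()
  for (si in unique(m$sentence_index)) {
    ms <- m[m$sentence_index == si, , drop = FALSE]
    chems <- expand_ids(ms$concept_id[ms$type == "Chemical"], expand_composite)
    dis <- expand_ids(ms$concept_id[ms$type == "Disease"], expand_composite)
    if (length(chems) && length(dis)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        chemical_id = rep(chems, each = length(dis)),
        disease_id = rep(dis, times = length(chems)),
        sentence_index = si)
    }
  }
  if (!length(rows)) return(empty_candidates())
  all <- dplyr::bind_rows(rows)
  agg <- dplyr::summarise(
    dplyr::group_by(all, .data$chemical_id, .data$disease_id),
    sentence_indices = paste(sort(unique(.data$sentence_index)),
                             collapse = ","),
    .groups = "drop")
  candidate_order(tibble::tibble(
    pmid = sents$pmid, chemical_id = agg$chemical_id,
    disease_id = agg$disease_id, scope = "sentence",
    sentence_indices = agg$sentence_indices, label = NA,
    source = "cooccurrence"))
}

#' Abstract-level chemical-disease co-occurrence candidates
#'
#' One candidate per unique (chemical id, disease id) pair with both
#' entities anywhere in the document, regardless of sentence structure.
#' Pairs that also co-occur within a sentence carry those sentence indices;
#' pairs only expressible across sentences have empty `sentence_indices`.
#' The sentence-level candidate set is always a subset of this one.
#'
#' @inheritParams sentence_cooccurrences
#' @return A candidate tibble with `scope = "abstract"`.
#' @export
abstract_cooccurrences <- function(sents, expand_composite = TRUE) {
  stopifnot(inherits(sents, "cid_sentences"))
  m <- active_mentions(sents)
  chems <- expand_ids(m$concept_id[m$type == "Chemical"], expand_composite)
  dis <- expand_ids(m$concept_id[m$type == "Disease"], expand_composite)
  if (!length(chems) || !length(dis)) return(empty_candidates())
  cand <- tibble::tibble(
    pmid = sents$pmid,
    chemical_id = rep(chems, each = length(dis)),
    disease_id = rep(dis, times = length(chems)),
    scope = "abstract", sentence_indices = "", label = NA,
    source = "cooccurrence")
  sent_cand <- sentence_cooccurrences(sents, expand_composite)
  i <- match(paste(cand$chemical_id, cand$disease_id),
             paste(sent_cand$chemical_id, sent_cand$disease_id))
  cand$sentence_indices[!is.na(i)] <- sent_cand$sentence_indices[i[!is.na(i)]]
  candidate_order(cand)
}

#' Label candidates against a gold standard
#'
#' A candidate is labeled `TRUE` exactly when its (chemical id, disease id)
#' pair — within the same document, when the gold table carries a `pmid`
#' column — appears in the gold standard, else `FALSE`.
#'
#' @param cand A candidate tibble.
#' @param gold A tibble with columns `chemical_id`, `disease_id` and
#'   optionally `pmid`.
#' @return The candidate tibble with its `label` column filled.
#' @export
label_candidates <- function(cand, gold) {
  if (!nrow(cand)) return(cand)
  if (!nrow(gold)) {
    cand$label <- FALSE
    return(cand)
  }
  if ("pmid" %in% names(gold)) {
    key <- paste(cand$pmid, cand$chemical_id, cand$disease_id, sep = "\r")
    gkey <- paste(gold$pmid, gold$chemical_id, gold$disease_id, sep = "\r")
  } else {
    key <- paste(cand$chemical_id, cand$disease_id, sep = "\r")
    gkey <- paste(gold$chemical_id, gold$disease_id, sep = "\r")
  }
  cand$label <- key %in% gkey
  cand
}

#' Write candidates as TSV
#'
#' @param cand Candidate tibble.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_candidates <- function(cand, path) {
  utils::write.table(cand, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
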