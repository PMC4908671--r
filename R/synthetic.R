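#' Configuration for the synthetic corpus generator
#'
#' The generator emulates the phenomena the detection pipeline must cope
#' with: relations expressed through trigger patterns, trigger-free
#' assertion sentences, relations spanning several sentences
#' (abstract-only), therapeutic-indication contexts, bystander
#' co-occurrences, and NER noise (missed mentions, boundary truncation,
#' failed normalization). Default level composition mirrors the reference
#' gold standard (about 70% of relations expressible within one sentence,
#' 30% abstract-only).
#'
#' @param n_docs Number of documents.
#' @param n_chemicals,n_diseases Vocabulary sizes.
#' @param relations_per_doc Integer range (min, max) of planted relations
#'   per document.
#' @param frac_abstract_only Fraction of relations expressed only across
#'   sentences.
#' @param frac_pattern Fraction of sentence-level relations rendered via a
#'   trigger-pattern template (the rest use a trigger-free assertion verb).
#' @param frac_title_pattern Fraction of pattern relations rendered in the
#'   title rather than the body.
#' @param frac_indication Probability a document carries a
#'   therapeutic-indication context sentence ("patients with DISEASE
#'   received CHEMICAL").
#' @param frac_negative Probability a document carries a bystander
#'   co-occurrence sentence (entities, no relation).
#' @param frac_two_word_disease Fraction of disease surface forms that are
#'   two-word terms (the substrate for boundary-truncation noise).
#' @param p_miss,p_truncate,p_misnorm Per-mention NER noise rates: mention
#'   dropped; multi-word span truncated to its last word; concept id
#'   replaced by `"-1"`.
#' @param seed Mandatory integer seed.
#' @return An object of class `cid_generator_config`.
#' @export
generator_config <- function(n_docs = 100, n_chemicals = 30, n_diseases = 40,
                             relations_per_doc = c(1, 3),
                             frac_abstract_only = 0.30,
                             frac_pattern = 0.40,
                             frac_title_pattern = 0.30,
                             frac_indication = 0.20,
                             frac_negative = 0.50,
                             frac_two_word_disease = 0.30,
                             p_miss = 0, p_truncate = 0, p_misnorm = 0,
                             seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  fr <- c(frac_abstract_only, frac_pattern, frac_title_pattern,
          frac_indication, frac_negative, frac_two_word_disease,
          p_miss, p_truncate, p_misnorm)
  if (any(fr < 0 | fr > 1)) {
    stop("config error: all fractions must lie in [0, 1]", call. = FALSE)
  }
  if (relations_per_doc[1] < 1 ||
      relations_per_doc[2] < relations_per_doc[1]) {
    stop("config error: relations_per_doc must be an increasing range >= 1",
         call. = FALSE)
  }
  if (relations_per_doc[2] > min(n_chemicals, n_diseases)) {
    stop("config error: vocabulary too small for relations_per_doc",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "cid_generator_config")
}

.syllables <- c("ba", "do", "fi", "lu", "mer", "nex", "pra", "quo", "rin",
                "sol", "tam", "vex", "zor", "kel", "gat")

pseudoword <- function(i) {
  s <- .syllables
  paste0(s[(i %% 15) + 1], s[((i %/% 15) %% 15) + 1],
         s[((i %/% 225) %% 15) + 1])
}

synthetic_vocab <- function(cfg) {
  chems <- tibble::tibble(
    concept_id = sprintf("C%06d", seq_len(cfg$n_chemicals)),
    surface = paste0(vapply(seq_len(cfg$n_chemicals), pseudoword,
                            character(1)), "ib"))
  two_word <- seq_len(cfg$n_diseases) <=
    round(cfg$frac_two_word_disease * cfg$n_diseases)
  base <- paste0(vapply(seq_len(cfg$n_diseases) + 500, pseudoword,
                        character(1)), "osis")
  dis <- tibble::tibble(
    concept_id = sprintf("D%06d", seq_len(cfg$n_diseases)),
    surface = ifelse(two_word, paste("chronic", base), base))
  list(chemicals = chems, diseases = dis)
}

# Instantiate a sentence template, tracking mention offsets. subs is a named
# list: each element list(text, type, concept_id); placeholders {C} and {D}.
render_sentence <- function(template, subs) {
  text <- template
  mentions <- empty_mentions()
  repeat {
    m <- regexpr("\\{[CD]\\}", text)
    if (m == -1) break
    key <- substr(text, m + 1, m + 1)
    sub <- subs[[key]]
    text <- paste0(substr(text, 1, m - 1), sub$text,
                   substring(text, m + attr(m, "match.length")))
    mentions <- dplyr::bind_rows(mentions, tibble::tibble(
      start = as.integer(m) - 1L, end = as.integer(m) - 1L +
        nchar(sub$text),
      text = sub$text, type = sub$type, concept_id = sub$concept_id))
  }
  # sentence-case: the splitter keys on uppercase sentence starts
  first <- substr(text, 1, 1)
  if (first %in% letters) {
    substr(text, 1, 1) <- toupper(first)
    if (nrow(mentions)) {
      at0 <- mentions$start == 0
      mentions$text[at0] <- paste0(toupper(substr(mentions$text[at0], 1, 1)),
                                   substring(mentions$text[at0], 2))
    }
  }
  list(text = text, mentions = mentions)
}

.pattern_templates <- c("{C}-induced {D} was observed in several subjects.",
                        "{C}-associated {D} remains a serious concern.",
                        "{D} caused by {C} resolved after withdrawal.",
                        "{D} during {C} therapy has been reported.")
.trigger_templates <- c("{C} provoked {D} in two cases.",
                        "Treatment with {C} provoked {D} shortly afterwards.")
.negative_templates <- c("{C} dosing and {D} status were recorded separately.",
                         "The report considered {C} exposure and unrelated {D} outcomes.")
.indication_templates <- c("Patients with {D} received {C} daily.",
                           "{D} patients received {C} infusion.")
.abstract_templates_chem <- c("{C} was administered for two weeks.",
                              "All subjects completed {C} treatment.")
.abstract_templates_dis <- c("Marked {D} developed subsequently.",
                             "Investigators later documented {D}.")

#' Generate a synthetic annotated corpus
#'
#' Assembles documents from sentence templates according to the
#' configuration, applies NER noise, and returns both the documents and an
#' exact bookkeeping ledger (planted relations with their expression level,
#' planted indication pairs, the full mention table with per-mention noise
#' events), so downstream metrics have computable expected values.
#' Byte-identical output for identical configurations.
#'
#' @param cfg A [generator_config()].
#' @return An object of class `cid_synthetic_corpus`: `documents` (list of
#'   [cid_document]), `bookkeeping` (list: `relations`, `indications`,
#'   `mentions`, `vocab`), `config`.
#' @export
generate_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "cid_generator_config"))
  set.seed(cfg$seed)
  vocab <- synthetic_vocab(cfg)
  docs <- list()
  rel_rows <- list()
  ind_rows <- list()
  men_rows <- list()
  for (d in seq_len(cfg$n_docs)) {
    pmid <- sprintf("9%06d", d)
    n_rel <- sample(cfg$relations_per_doc[1]:cfg$relations_per_doc[2], 1)
    chem_idx <- sample(cfg$n_chemicals, n_rel)
    dis_idx <- sample(cfg$n_diseases, n_rel)
    sentences <- list()  # each: list(text, mentions)
    title <- NULL
    for (r in seq_len(n_rel)) {
      chem <- list(text = vocab$chemicals$surface[chem_idx[r]],
                   type = "Chemical",
                   concept_id = vocab$chemicals$concept_id[chem_idx[r]])
      dis <- list(text = vocab$diseases$surface[dis_idx[r]],
                  type = "Disease",
                  concept_id = vocab$diseases$concept_id[dis_idx[r]])
      level <- if (stats::runif(1) < cfg$frac_abstract_only) "abstract"
               else "sentence"
      via_pattern <- FALSE; in_title <- FALSE
      if (level == "abstract") {
        sentences[[length(sentences) + 1]] <-
          render_sentence(sample(.abstract_templates_chem, 1), list(C = chem))
        sentences[[length(sentences) + 1]] <-
          render_sentence(sample(.abstract_templates_dis, 1), list(D = dis))
      } else {
        via_pattern <- stats::runif(1) < cfg$frac_pattern
        tpl <- if (via_pattern) sample(.pattern_templates, 1)
               else sample(.trigger_templates, 1)
        rendered <- render_sentence(tpl, list(C = chem, D = dis))
        if (via_pattern && is.null(title) &&
            stats::runif(1) < cfg$frac_title_pattern) {
          title <- rendered
          in_title <- TRUE
        } else {
          sentences[[length(sentences) + 1]] <- rendered
        }
      }
      rel_rows[[length(rel_rows) + 1]] <- tibble::tibble(
        pmid = pmid, chemical_id = chem$concept_id,
        disease_id = dis$concept_id, level = level,
        via_pattern = via_pattern, in_title = in_title)
    }
    if (stats::runif(1) < cfg$frac_indication) {
      free_c <- setdiff(seq_len(cfg$n_chemicals), chem_idx)
      free_d <- setdiff(seq_len(cfg$n_diseases), dis_idx)
      ci <- sample(free_c, 1); di <- sample(free_d, 1)
      sentences[[length(sentences) + 1]] <- render_sentence(
        sample(.indication_templates, 1),
        list(C = list(text = vocab$chemicals$surface[ci], type = "Chemical",
                      concept_id = vocab$chemicals$concept_id[ci]),
             D = list(text = vocab$diseases$surface[di], type = "Disease",
                      concept_id = vocab$diseases$concept_id[di])))
      ind_rows[[length(ind_rows) + 1]] <- tibble::tibble(
        pmid = pmid, chemical_id = vocab$chemicals$concept_id[ci],
        disease_id = vocab$diseases$concept_id[di])
    }
    if (stats::runif(1) < cfg$frac_negative) {
      free_c <- setdiff(seq_len(cfg$n_chemicals), chem_idx)
      free_d <- setdiff(seq_len(cfg$n_diseases), dis_idx)
      ci <- sample(free_c, 1); di <- sample(free_d, 1)
      sentences[[length(sentences) + 1]] <- render_sentence(
        sample(.negative_templates, 1),
        list(C = list(text = vocab$chemicals$surface[ci], type = "Chemical",
                      concept_id = vocab$chemicals$concept_id[ci]),
             D = list(text = vocab$diseases$surface[di], type = "Disease",
                      concept_id = vocab$diseases$concept_id[di])))
    }
    if (is.null(title)) {
      title <- render_sentence(
        "Observations on {C} safety.",
        list(C = list(text = vocab$chemicals$surface[chem_idx[1]],
                      type = "Chemical",
                      concept_id = vocab$chemicals$concept_id[chem_idx[1]])))
    }
    if (!length(sentences)) {
      sentences[[1]] <- list(text = "The cohort was followed for six months.",
                             mentions = empty_mentions())
    }
    if (length(sentences) > 1) sentences <- sample(sentences)  # shuffle body
    # assemble abstract text and document-level mention offsets
    abstract <- ""
    mentions <- title$mentions
    off <- nchar(title$text) + 1L
    for (s in sentences) {
      if (nzchar(abstract)) {
        abstract <- paste(abstract, s$text)
        off <- off + 1L
      } else {
        abstract <- s$text
      }
      if (nrow(s$mentions)) {
        sm <- s$mentions
        sm$start <- sm$start + off
        sm$end <- sm$end + off
        mentions <- dplyr::bind_rows(mentions, sm)
      }
      off <- off + nchar(s$text)
    }
    # NER noise
    if (nrow(mentions)) {
      mentions <- mentions[order(mentions$start), , drop = FALSE]
      missed <- stats::runif(nrow(mentions)) < cfg$p_miss
      truncated <- stats::runif(nrow(mentions)) < cfg$p_truncate &
        grepl(" ", mentions$text, fixed = TRUE) & !missed
      misnorm <- stats::runif(nrow(mentions)) < cfg$p_misnorm & !missed
      men_rows[[length(men_rows) + 1]] <- dplyr::mutate(
        mentions, pmid = pmid, missed = missed, truncated = truncated,
        misnormalized = misnorm)
      if (any(truncated)) {
        for (i in which(truncated)) {
          last <- sub(".* ", "", mentions$text[i])
          mentions$start[i] <- mentions$end[i] - nchar(last)
          mentions$text[i] <- last
        }
      }
      mentions$concept_id[misnorm] <- "-1"
      mentions <- mentions[!missed, , drop = FALSE]
    }
    rel_doc <- dplyr::bind_rows(rel_rows[vapply(rel_rows, function(r)
      r$pmid[1] == pmid, logical(1))])
    gold <- dplyr::distinct(rel_doc[, c("chemical_id", "disease_id")])
    docs[[length(docs) + 1]] <- cid_document(
      pmid, title$text, abstract, mentions, gold)
  }
  structure(list(
    documents = docs,
    bookkeeping = list(
      relations = dplyr::bind_rows(rel_rows),
      indications = dplyr::bind_rows(ind_rows,
        tibble::tibble(pmid = character(), chemical_id = character(),
                       disease_id = character())),
      mentions = dplyr::bind_rows(men_rows),
      vocab = vocab),
    config = cfg),
    class = "cid_synthetic_corpus")
}

#' @export
print.cid_synthetic_corpus <- function(x, ...) {
  bk <- x$bookkeeping
  cat("<cid_synthetic_corpus> ", length(x$documents), " documents, ",
      nrow(bk$relations), " planted relations (",
      sum(bk$relations$level == "abstract"), " abstract-only), ",
      nrow(bk$indications), " indication pairs\n", sep = "")
  invisible(x)
}

#' Gold relations of a corpus as one table
#'
#' @param docs A list of `cid_document` or a `cid_synthetic_corpus`.
#' @return Tibble `pmid`, `chemical_id`, `disease_id`.
#' @export
corpus_gold <- function(docs) {
  if (inherits(docs, "cid_synthetic_corpus")) docs <- docs$documents
  dplyr::bind_rows(lapply(docs, function(d) {
    if (!nrow(d$gold)) return(NULL)
    tibble::tibble(pmid = d$pmid, chemical_id = d$gold$chemical_id,
                   disease_id = d$gold$disease_id)
  }), tibble::tibble(pmid = character(), chemical_id = character(),
                     disease_id = character()))
}

#' Generate a knowledge base consistent with a synthetic corpus
#'
#' Side-effect entries cover a configured fraction of the planted true
#' relations (plus optional random extras); therapeutic entries are the
#' planted indication pairs (plus optional extras). Gold pairs never
#' receive a therapeutic label and no pair receives both labels, so the
#' dual-label load check passes by construction.
#'
#' @param corpus A `cid_synthetic_corpus`.
#' @param se_coverage Fraction of gold relations present as side-effect
#'   entries.
#' @param n_extra_se,n_extra_therapeutic Random non-gold pairs added under
#'   each label.
#' @param seed Integer seed.
#' @return A `cid_kb` object.
#' @export
generate_kb <- function(corpus, se_coverage = 0.7, n_extra_se = 0,
                        n_extra_therapeutic = 0, seed = 42) {
  stopifnot(inherits(corpus, "cid_synthetic_corpus"))
  set.seed(seed)
  gold <- dplyr::distinct(
    corpus$bookkeeping$relations[, c("chemical_id", "disease_id")])
  n_se <- round(se_coverage * nrow(gold))
  se <- gold[sample(nrow(gold), n_se), , drop = FALSE]
  ther <- dplyr::distinct(
    corpus$bookkeeping$indications[, c("chemical_id", "disease_id")])
  gk <- paste(gold$chemical_id, gold$disease_id)
  ther <- ther[!paste(ther$chemical_id, ther$disease_id) %in% gk, ,
               drop = FALSE]
  vocab <- corpus$bookkeeping$vocab
  rand_pairs <- function(n, banned) {
    out <- tibble::tibble(chemical_id = character(),
                          disease_id = character())
    guard <- 0
    while (nrow(out) < n && guard < 50 * n + 100) {
      cand <- tibble::tibble(
        chemical_id = sample(vocab$chemicals$concept_id, 1),
        disease_id = sample(vocab$diseases$concept_id, 1))
      key <- paste(cand$chemical_id, cand$disease_id)
      if (!key %in% banned) {
        out <- dplyr::bind_rows(out, cand)
        banned <- c(banned, key)
      }
      guard <- guard + 1
    }
    out
  }
  used <- c(gk, paste(se$chemical_id, se$disease_id),
            paste(ther$chemical_id, ther$disease_id))
  extra_se <- rand_pairs(n_extra_se, used)
  used <- c(used, paste(extra_se$chemical_id, extra_se$disease_id))
  extra_th <- rand_pairs(n_extra_therapeutic, used)
  entries <- dplyr::bind_rows(
    dplyr::mutate(dplyr::bind_rows(se, extra_se), label = "side_effect"),
    dplyr::mutate(dplyr::bind_rows(ther, extra_th), label = "therapeutic"))
  entries$provenance <- "synthetic"
  load_kb(entries[, c("chemical_id", "disease_id", "label", "provenance")])
}

#' Generate simulated crowd votes for a corpus
#'
#' Builds one verification task per labeled sentence-level candidate of the
#' corpus and simulates workers on it; delegates to [simulate_workers()].
#'
#' @param corpus A `cid_synthetic_corpus`.
#' @param worker_accuracy,n_workers,seed Passed to [simulate_workers()].
#' @return A long vote tibble.
#' @export
generate_votes <- function(corpus, worker_accuracy = 0.9, n_workers = 5,
                           seed = 42) {
  stopifnot(inherits(corpus, "cid_synthetic_corpus"))
  rows <- list()
  for (doc in corpus$documents) {
    sents <- split_sentences(doc)
    cand <- label_candidates(sentence_cooccurrences(sents), doc$gold)
    for (i in seq_len(nrow(cand))) {
      si <- as.integer(strsplit(cand$sentence_indices[i], ",")[[1]])[1]
      rows[[length(rows) + 1]] <- tibble::tibble(
        task_id = paste(cand$pmid[i], cand$chemical_id[i],
                        cand$disease_id[i], sep = "_"),
        pmid = cand$pmid[i], chemical_id = cand$chemical_id[i],
        disease_id = cand$disease_id[i],
        sentence = sents$sentences$text[match(si, sents$sentences$index)],
        gold_label = cand$label[i])
    }
  }
  tasks <- dplyr::bind_rows(rows)
  simulate_workers(tasks, worker_accuracy = worker_accuracy,
                   n_workers = n_workers, seed = seed)
}
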