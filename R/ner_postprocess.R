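#' NER post-processing configuration
#'
#' Settings for the three post-NER cleanup rules applied before candidate
#' generation: suppression of therapeutic-indication disease contexts,
#' removal of elemental/simple chemical mentions, and resolution of
#' overlapping entity spans.
#'
#' Indication patterns are regular expressions over the sentence text in
#' which the literal token `DISEASE` stands for the (escaped) surface form
#' of each disease mention; a disease whose instantiated pattern matches is
#' flagged as a therapeutic-indication context, not a side effect. The
#' defaults capture "<disease> patient(s)" and "patient(s) with <disease>".
#'
#' @param indication_patterns Character vector of patterns containing the
#'   `DISEASE` placeholder; matched case-insensitively.
#' @param chemical_stoplist Lower-cased surface forms of chemical mentions
#'   to drop (elements and other trivially co-occurring species).
#' @param filter_indications,remove_simple_chemicals,resolve_overlaps
#'   Logical flags enabling each rule.
#' @return An object of class `cid_filter_config`.
#' @export
filter_config <- function(
    indication_patterns = c("DISEASE\\s+patients?\\b",
                            "\\bpatients?\\s+with\\s+DISEASE"),
    chemical_stoplist = c("calcium", "ca", "carbon", "c", "oxygen", "o",
                          "hydrogen", "h", "nitrogen", "n", "lead", "iron",
                          "fe", "zinc", "zn"),
    filter_indications = TRUE,
    remove_simple_chemicals = TRUE,
    resolve_overlaps = TRUE) {
  for (p in indication_patterns) {
    if (!grepl("DISEASE", p, fixed = TRUE)) {
      stop("indication pattern ", dQuote(p), " lacks the DISEASE placeholder",
           call. = FALSE)
    }
    # must compile once instantiated
    tryCatch(grepl(sub("DISEASE", "xyz", p, fixed = TRUE), "", perl = TRUE),
             error = function(e) stop("indication pattern ", dQuote(p),
                                      " does not compile: ",
                                      conditionMessage(e), call. = FALSE))
  }
  if (remove_simple_chemicals && !length(chemical_stoplist)) {
    stop("chemical_stoplist must be non-empty when its rule is enabled",
         call. = FALSE)
  }
  structure(list(indication_patterns = indication_patterns,
                 chemical_stoplist = tolower(chemical_stoplist),
                 filter_indications = filter_indications,
                 remove_simple_chemicals = remove_simple_chemicals,
                 resolve_overlaps = resolve_overlaps),
            class = "cid_filter_config")
}

#' Flag therapeutic-indication disease contexts
#'
#' Diseases mentioned as what a patient is being treated for (e.g. the
#' disease immediately followed by "patient(s)", or preceded by
#' "patients with") are the drug's indication, not its side effect, and are
#' a known false-positive source for downstream relation extraction. This
#' rule deactivates such disease mentions sentence by sentence; mentions are
#' flagged (`active = FALSE`, `filter_reason = "indication"`), never
#' deleted, so evaluation against the raw NER layer stays possible.
#'
#' @param sents A `cid_sentences` object (see [split_sentences()]).
#' @param cfg A [filter_config()].
#' @return The `cid_sentences` object with updated mention flags.
#' @export
filter_indication_diseases <- function(sents, cfg = filter_config()) {
  stopifnot(inherits(sents, "cid_sentences"))
  if (!cfg$filter_indications) return(sents)
  m <- sents$mentions
  idx <- which(m$type == "Disease" & m$active)
  for (i in idx) {
    stext <- sents$sentences$text[match(m$sentence_index[i],
                                        sents$sentences$index)]
    surf <- gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", m$text[i])
    hit <- any(vapply(cfg$indication_patterns, function(p) {
      grepl(sub("DISEASE", surf, p, fixed = TRUE), stext,
            ignore.case = TRUE, perl = TRUE)
    }, logical(1)))
    if (hit) {
      m$active[i] <- FALSE
      m$filter_reason[i] <- "indication"
    }
  }
  sents$mentions <- m
  sents
}

#' Drop simple-chemical mentions
#'
#' Elemental chemicals such as calcium (Ca), carbon (C) or oxygen (O)
#' co-occur with diseases constantly without expressing a causal relation;
#' chemical mentions whose lower-cased surface form matches the stoplist
#' exactly are deactivated. Order is preserved; non-chemical mentions are
#' untouched.
#'
#' @param mentions A mention tibble carrying `active`/`filter_reason`
#'   columns, or a `cid_sentences` object.
#' @param cfg A [filter_config()].
#' @return Same shape as the input, with updated flags.
#' @export
remove_simple_chemicals <- function(mentions, cfg = filter_config()) {
  if (inherits(mentions, "cid_sentences")) {
    mentions$mentions <- remove_simple_chemicals(mentions$mentions, cfg)
    return(mentions)
  }
  if (!cfg$remove_simple_chemicals || !nrow(mentions)) return(mentions)
  hit <- mentions$type == "Chemical" & mentions$active &
    tolower(mentions$text) %in% cfg$chemical_stoplist
  mentions$active[hit] <- FALSE
  mentions$filter_reason[hit] <- "simple_chemical"
  mentions
}

#' Resolve overlapping entity mentions
#'
#' When chemical and disease spans overlap in the text only one entity can
#' be right. The rule set: a mention strictly contained inside another is
#' dropped in favor of the container; of two partially overlapping mentions
#' the longer survives; ties go to the leftmost (then to the earlier row).
#' Applied transitively until the surviving set is pairwise disjoint.
#'
#' @param mentions A mention tibble (document-level offsets) carrying
#'   `active`/`filter_reason` columns, or a `cid_sentences` object.
#' @return Same shape as the input; losers get `active = FALSE`,
#'   `filter_reason = "overlap"`.
#' @export
resolve_overlaps <- function(mentions) {
  if (inherits(mentions, "cid_sentences")) {
    mentions$mentions <- resolve_overlaps(mentions$mentions)
    return(mentions)
  }
  if (!nrow(mentions)) return(mentions)
  alive <- which(mentions$active)
  if (length(alive) < 2) return(mentions)
  # rank: longer first, then leftmost, then original order
  len <- mentions$end - mentions$start
  ord <- alive[order(-len[alive], mentions$start[alive], alive)]
  kept <- integer(0)
  for (i in ord) {
    clash <- any(mentions$start[i] < mentions$end[kept] &
                 mentions$start[kept] < mentions$end[i])
    if (!clash) {
      kept <- c(kept, i)
    } else {
      mentions$active[i] <- FALSE
      mentions$filter_reason[i] <- "overlap"
    }
  }
  mentions
}

#' Apply the full NER post-processing chain to one document
#'
#' Overlap resolution runs first on document-level spans, then the document
#' is split into sentences, then the simple-chemical and indication-context
#' rules fire. Returns the `cid_sentences` object consumed by candidate
#' generation, pattern matching and the relation classifier.
#'
#' @param doc A [cid_document].
#' @param cfg A [filter_config()].
#' @return A `cid_sentences` object with filter flags applied.
#' @export
preprocess_document <- function(doc, cfg = filter_config()) {
  sents <- split_sentences(doc)
  if (cfg$resolve_overlaps) sents <- resolve_overlaps(sents)
  sents <- remove_simple_chemicals(sents, cfg)
  sents <- filter_indication_diseases(sents, cfg)
  sents
}

#' Active (filter-surviving) mentions
#'
#' @param x A `cid_sentences` object or mention tibble.
#' @return The subset of mentions with `active = TRUE`.
#' @export
active_mentions <- function(x) {
  m <- if (inherits(x, "cid_sentences")) x$mentions else x
  m[m$active, , drop = FALSE]
}
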