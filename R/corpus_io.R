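#' Construct an annotated document
#'
#' A document is one Medline-style abstract: a PMID, a title, an abstract
#' body, a table of typed entity mentions with character offsets, and a set
#' of gold chemical-induced-disease (CID) relations at the identifier level.
#'
#' Offsets follow the BC5-CDR convention: 0-based, half-open, indexing into
#' the concatenation `title + " " + abstract`. Slicing that concatenation at
#' `[start, end)` must reproduce the mention text.
#'
#' @param pmid Document identifier (string).
#' @param title Title text.
#' @param abstract Abstract text.
#' @param mentions Tibble with columns `start`, `end`, `text`, `type`
#'   (`"Chemical"` or `"Disease"`) and `concept_id` (MeSH-style identifier;
#'   `"-1"` marks an unnormalized mention, `"|"` joins composite ids).
#' @param gold Tibble with columns `chemical_id`, `disease_id` giving the
#'   document's gold CID relations.
#' @return An object of class `cid_document`.
#' @export
cid_document <- function(pmid, title, abstract,
                         mentions = empty_mentions(),
                         gold = empty_gold()) {
  mentions <- tibble::as_tibble(mentions)
  if (nrow(mentions) == 0) mentions <- empty_mentions()
  gold <- tibble::as_tibble(gold)
  if (nrow(gold) == 0) gold <- empty_gold()
  doc <- structure(
    list(pmid = as.character(pmid), title = title, abstract = abstract,
         mentions = mentions, gold = gold),
    class = "cid_document"
  )
  validate_document(doc)
  doc
}

empty_mentions <- function() {
  tibble::tibble(start = integer(), end = integer(), text = character(),
                 type = character(), concept_id = character())
}

empty_gold <- function() {
  tibble::tibble(chemical_id = character(), disease_id = character())
}

#' Full text of a document
#'
#' Title and abstract joined by a single space, the string into which all
#' mention offsets index.
#'
#' @param doc A `cid_document`.
#' @return A string.
#' @export
doc_text <- function(doc) paste(doc$title, doc$abstract, sep = " ")

validate_document <- function(doc) {
  m <- doc$mentions
  if (nrow(m) == 0) return(invisible(doc))
  if (any(m$start < 0 | m$start >= m$end)) {
    stop("integrity error in document ", doc$pmid,
         ": mention offsets must satisfy 0 <= start < end", call. = FALSE)
  }
  bad_type <- setdiff(unique(m$type), c("Chemical", "Disease"))
  if (length(bad_type)) {
    stop("integrity error in document ", doc$pmid,
         ": unknown mention type(s) ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  }
  text <- doc_text(doc)
  slice <- substring(text, m$start + 1L, m$end)
  if (any(slice != m$text)) {
    i <- which(slice != m$text)[1]
    stop("integrity error in document ", doc$pmid, ": span [", m$start[i],
         ", ", m$end[i], ") reads ", dQuote(slice[i]), " but annotation says ",
         dQuote(m$text[i]), call. = FALSE)
  }
  if (nrow(doc$gold) &&
      any(doc$gold$chemical_id == "-1" | doc$gold$disease_id == "-1")) {
    stop("integrity error in document ", doc$pmid,
         ": gold relation ids may not be \"-1\"", call. = FALSE)
  }
  invisible(doc)
}

#' @export
print.cid_document <- function(x, ...) {
  cat("<cid_document ", x$pmid, ">\n", sep = "")
  cat("  title:    ", substr(x$title, 1, 60),
      if (nchar(x$title) > 60) "..." else "", "\n", sep = "")
  cat("  mentions: ", nrow(x$mentions),
      " (", sum(x$mentions$type == "Chemical"), " chemical, ",
      sum(x$mentions$type == "Disease"), " disease)\n", sep = "")
  cat("  gold CID relations: ", nrow(x$gold), "\n", sep = "")
  invisible(x)
}

#' Parse a PubTator / BC5-CDR corpus
#'
#' Reads the plain-text interchange format used by the BioCreative V
#' chemical-disease relation task: per document a `PMID|t|title` line, a
#' `PMID|a|abstract` line, zero or more tab-separated mention annotation
#' lines (`pmid start end text type concept_id`), optional relation lines
#' (`pmid CID chemical_id disease_id`), and a blank line between documents.
#'
#' Every mention is verified against its offsets at parse time; a mismatch
#' raises an integrity error naming the PMID and span.
#'
#' @param x A character scalar holding the whole corpus, or a character
#'   vector of lines.
#' @return A list of [cid_document] objects, in file order.
#' @seealso [write_pubtator()], [read_pubtator()]
#' @export
parse_pubtator <- function(x) {
  if (length(x) == 1 && grepl("\n", x, fixed = TRUE)) {
    x <- strsplit(x, "\n", fixed = TRUE)[[1]]
  }
  docs <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur)) return(NULL)
    if (is.null(cur$title) || is.null(cur$abstract)) {
      stop("parse error near line ", cur$first_line,
           ": document block lacks |t| or |a| line", call. = FALSE)
    }
    cid_document(cur$pmid, cur$title, cur$abstract,
                 dplyr::bind_rows(empty_mentions(), cur$mentions),
                 dplyr::bind_rows(empty_gold(), cur$gold))
  }
  for (i in seq_along(x)) {
    line <- x[i]
    if (!nzchar(trimws(line))) {
      if (!is.null(cur)) { docs[[length(docs) + 1]] <- flush(cur); cur <- NULL }
      next
    }
    tpart <- regmatches(line, regexec("^([^|\t]+)\\|t\\|(.*)$", line))[[1]]
    apart <- regmatches(line, regexec("^([^|\t]+)\\|a\\|(.*)$", line))[[1]]
    if (length(tpart) == 3) {
      if (!is.null(cur) && !is.null(cur$title)) {
        docs[[length(docs) + 1]] <- flush(cur); cur <- NULL
      }
      if (is.null(cur)) cur <- list(pmid = tpart[2], first_line = i,
                                    mentions = list(), gold = list())
      cur$title <- tpart[3]
    } else if (length(apart) == 3) {
      if (is.null(cur)) stop("parse error at line ", i,
                             ": |a| line before |t| line", call. = FALSE)
      cur$abstract <- apart[3]
    } else if (grepl("\t", line, fixed = TRUE)) {
      if (is.null(cur)) stop("parse error at line ", i,
                             ": annotation line outside a document block",
                             call. = FALSE)
      f <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(f) == 4 && f[2] == "CID") {
        cur$gold[[length(cur$gold) + 1]] <-
          tibble::tibble(chemical_id = f[3], disease_id = f[4])
      } else if (length(f) >= 6) {
        start <- suppressWarnings(as.integer(f[2]))
        end <- suppressWarnings(as.integer(f[3]))
        if (is.na(start) || is.na(end)) {
          stop("parse error at line ", i, ": non-numeric offsets", call. = FALSE)
        }
        cur$mentions[[length(cur$mentions) + 1]] <-
          tibble::tibble(start = start, end = end, text = f[4],
                         type = f[5], concept_id = f[6])
      } else {
        stop("parse error at line ", i, ": expected 4-field relation or ",
             ">=6-field mention annotation, got ", length(f), " fields",
             call. = FALSE)
      }
    } else {
      stop("parse error at line ", i, ": unrecognized line ", dQuote(line),
           call. = FALSE)
    }
  }
  if (!is.null(cur)) docs[[length(docs) + 1]] <- flush(cur)
  docs
}

#' Read a PubTator file from disk
#'
#' @param path File path.
#' @return A list of [cid_document] objects.
#' @export
read_pubtator <- function(path) {
  parse_pubtator(readLines(path, warn = FALSE))
}

#' Serialize documents to PubTator format
#'
#' Canonical serialization: title line, abstract line, mention lines in
#' stored order, relation lines (type token `CID`), blank line after each
#' document. `parse_pubtator(write_pubtator(docs))` is the identity on the
#' data model.
#'
#' @param docs A `cid_document` or list of them.
#' @param path Optional file path; when given, the text is also written there.
#' @return The serialized text, invisibly when `path` is given.
#' @export
write_pubtator <- function(docs, path = NULL) {
  if (inherits(docs, "cid_document")) docs <- list(docs)
  blocks <- vapply(docs, function(doc) {
    validate_document(doc)
    lines <- c(paste0(doc$pmid, "|t|", doc$title),
               paste0(doc$pmid, "|a|", doc$abstract))
    m <- doc$mentions
    if (nrow(m)) {
      lines <- c(lines, paste(doc$pmid, m$start, m$end, m$text, m$type,
                              m$concept_id, sep = "\t"))
    }
    g <- doc$gold
    if (nrow(g)) {
      lines <- c(lines, paste(doc$pmid, "CID", g$chemical_id, g$disease_id,
                              sep = "\t"))
    }
    paste0(paste(lines, collapse = "\n"), "\n")
  }, character(1))
  out <- paste(blocks, collapse = "\n")
  if (!is.null(path)) {
    writeLines(out, path, sep = "")
    return(invisible(out))
  }
  out
}

# Abbreviations that do not end a sentence even when followed by space+capital.
.sentence_abbrev <- c("e.g.", "i.e.", "vs.", "Dr.", "Fig.", "Figs.", "et al.",
                      "approx.", "ca.", "cf.", "No.", "St.", "Mr.", "Mrs.",
                      "resp.", "wk.", "mg.", "inc.")

split_text_sentences <- function(text) {
  # Boundary: [.?!] followed by whitespace and an uppercase letter or digit,
  # unless the trailing token is a known abbreviation.
  if (!nzchar(text)) return(tibble::tibble(start = integer(), text = character()))
  m <- gregexpr("[.?!]+(?=[ \t]+[A-Z0-9])", text, perl = TRUE)[[1]]
  cuts <- integer(0)
  if (m[1] != -1) {
    ends <- as.integer(m) + attr(m, "match.length") - 1L
    for (e in ends) {
      head_txt <- substr(text, 1, e)
      tail_tok <- sub(".*[ \t]", "", head_txt)
      if (!(tail_tok %in% .sentence_abbrev)) cuts <- c(cuts, e)
    }
  }
  starts <- c(1L, cuts + 1L)
  stops <- c(cuts, nchar(text))
  out <- tibble::tibble(start = integer(), text = character())
  for (i in seq_along(starts)) {
    seg <- substring(text, starts[i], stops[i])
    lead_ws <- nchar(seg) - nchar(sub("^[ \t]+", "", seg))
    seg2 <- sub("^[ \t]+", "", seg)
    seg2 <- sub("[ \t]+$", "", seg2)
    if (nzchar(seg2)) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        start = starts[i] + lead_ws - 1L,  # 0-based offset into text
        text = seg2))
    }
  }
  out
}

#' Split a document into sentences and project mentions
#'
#' The title becomes sentence index 0 (`in_title = TRUE`); the abstract is
#' split by a rule-based splitter (terminal `.?!` followed by whitespace and
#' an uppercase letter or digit, with an abbreviation stoplist). Every
#' mention fully contained in one sentence is projected to sentence-local
#' offsets; a mention straddling a splitter boundary is assigned to the
#' sentence containing its start and flagged in the `straddles` column (with
#' a warning), so splitter artifacts stay visible.
#'
#' @param doc A [cid_document].
#' @return An object of class `cid_sentences`: a list with
#'   `pmid`, `sentences` (tibble: `index`, `doc_start`, `text`, `in_title`)
#'   and `mentions` (the document's mentions plus `sentence_index`,
#'   `local_start`, `local_end`, `straddles`, and filter bookkeeping columns
#'   `active`/`filter_reason` used by the NER post-processing rules).
#' @export
split_sentences <- function(doc) {
  stopifnot(inherits(doc, "cid_document"))
  title_row <- tibble::tibble(index = 0L, doc_start = 0L,
                              text = doc$title, in_title = TRUE)
  abs_sents <- split_text_sentences(doc$abstract)
  off0 <- nchar(doc$title) + 1L  # title + single space separator
  if (nrow(abs_sents)) {
    abs_rows <- tibble::tibble(index = seq_len(nrow(abs_sents)),
                               doc_start = off0 + abs_sents$start,
                               text = abs_sents$text, in_title = FALSE)
  } else {
    abs_rows <- tibble::tibble(index = integer(), doc_start = integer(),
                               text = character(), in_title = logical())
  }
  sentences <- dplyr::bind_rows(title_row, abs_rows)

  m <- doc$mentions
  if (nrow(m)) {
    sent_index <- integer(nrow(m))
    straddles <- logical(nrow(m))
    for (i in seq_len(nrow(m))) {
      holds_start <- which(sentences$doc_start <= m$start[i] &
                           m$start[i] < sentences$doc_start +
                             nchar(sentences$text))
      j <- if (length(holds_start)) max(holds_start) else 1L
      sent_index[i] <- sentences$index[j]
      straddles[i] <- m$end[i] >
        sentences$doc_start[j] + nchar(sentences$text[j])
    }
    if (any(straddles)) {
      warning("document ", doc$pmid, ": ", sum(straddles),
              " mention(s) straddle a sentence boundary; kept at the ",
              "sentence containing their start", call. = FALSE)
    }
    ds <- sentences$doc_start[match(sent_index, sentences$index)]
    m <- dplyr::mutate(m,
      sentence_index = sent_index,
      local_start = .data$start - ds,
      local_end = pmin(.data$end - ds,
                       nchar(sentences$text[match(sent_index,
                                                  sentences$index)])),
      straddles = straddles,
      active = TRUE,
      filter_reason = NA_character_)
  } else {
    m <- dplyr::mutate(m, sentence_index = integer(), local_start = integer(),
                       local_end = integer(), straddles = logical(),
                       active = logical(), filter_reason = character())
  }
  structure(list(pmid = doc$pmid, sentences = sentences, mentions = m,
                 gold = doc$gold),
            class = "cid_sentences")
}

#' @export
print.cid_sentences <- function(x, ...) {
  cat("<cid_sentences ", x$pmid, ">: ", nrow(x$sentences), " sentences, ",
      nrow(x$mentions), " mentions (", sum(x$mentions$active),
      " active)\n", sep = "")
  invisible(x)
}
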