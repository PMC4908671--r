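#' Default CID trigger patterns
#'
#' The four high-precision pattern families used for sentence-level
#' chemical-induced-disease detection, written as templates over annotated
#' entity placeholders: `CHEMICAL-induced DISEASE`,
#' `CHEMICAL-associated DISEASE`, `DISEASE caused by CHEMICAL` and
#' `DISEASE during CHEMICAL`. Matching is case-insensitive and tolerates a
#' hyphen or whitespace between entity and trigger.
#'
#' @return A pattern tibble with columns `template`, `direction`
#'   (`"chem_first"` / `"disease_first"`), `trigger` (token sequence that
#'   must appear between the two entities) and `allow_coordination`.
#' @export
default_cid_patterns <- function() {
  compile_patterns(c("CHEMICAL-induced DISEASE",
                     "CHEMICAL-associated DISEASE",
                     "DISEASE caused by CHEMICAL",
                     "DISEASE during CHEMICAL"))
}

#' Compile pattern templates
#'
#' A template is a string containing `CHEMICAL` and `DISEASE` (or `SE`)
#' exactly once each; the words between the placeholders are the trigger
#' that must occur between the two annotated mentions in a sentence.
#' Templates can be kept in a plain text file, one per line (`#` comments
#' allowed), and read with [read_patterns()].
#'
#' @param templates Character vector of templates.
#' @param allow_coordination After a match, extend the disease slot across a
#'   comma/"and" coordinated list of further disease mentions?
#' @return A pattern tibble (see [default_cid_patterns()]).
#' @export
compile_patterns <- function(templates, allow_coordination = TRUE) {
  rows <- lapply(templates, function(tpl) {
    t2 <- gsub("\\bSE\\b", "DISEASE", tpl)
    nc <- lengths(regmatches(t2, gregexpr("CHEMICAL", t2, fixed = TRUE)))
    nd <- lengths(regmatches(t2, gregexpr("DISEASE", t2, fixed = TRUE)))
    if (nc != 1 || nd != 1) {
      stop("pattern template ", dQuote(tpl),
           " must contain CHEMICAL and DISEASE exactly once", call. = FALSE)
    }
    chem_pos <- regexpr("CHEMICAL", t2, fixed = TRUE)
    dis_pos <- regexpr("DISEASE", t2, fixed = TRUE)
    direction <- if (chem_pos < dis_pos) "chem_first" else "disease_first"
    inner <- if (direction == "chem_first") {
      substr(t2, chem_pos + nchar("CHEMICAL"), dis_pos - 1)
    } else {
      substr(t2, dis_pos + nchar("DISEASE"), chem_pos - 1)
    }
    trigger <- tolower(paste(pattern_tokens(inner), collapse = " "))
    if (!nzchar(trigger)) {
      stop("pattern template ", dQuote(tpl),
           " has no trigger words between its placeholders", call. = FALSE)
    }
    tibble::tibble(template = tpl, direction = direction, trigger = trigger,
                   allow_coordination = allow_coordination)
  })
  dplyr::bind_rows(rows)
}

#' Read pattern templates from a file
#'
#' @param path Text file, one template per line; blank lines and lines
#'   starting with `#` are ignored.
#' @inheritParams compile_patterns
#' @return A pattern tibble.
#' @export
read_patterns <- function(path, allow_coordination = TRUE) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  compile_patterns(lines, allow_coordination)
}

# Word tokens of a text fragment; hyphens and punctuation are separators.
pattern_tokens <- function(x) {
  toks <- regmatches(x, gregexpr("[A-Za-z0-9]+", x))[[1]]
  tolower(toks)
}

#' Match CID trigger patterns in a document's sentences
#'
#' Matching is anchored on annotated, filter-surviving mention spans: a
#' pattern fires when a chemical mention and a disease mention occupy its
#' placeholder positions with the trigger words between them and at most
#' `max_gap` word tokens between the spans in total. String look-alikes
#' that are not annotated entities never match. With coordination enabled,
#' a trigger followed by a comma/"and"-joined list of disease mentions
#' yields one pair per listed disease. A coordinating conjunction between
#' the entity and the trigger blocks the match (the trigger's argument is
#' then a nearer conjunct).
#'
#' @param sents A `cid_sentences` object.
#' @param patterns A pattern tibble (default [default_cid_patterns()]).
#' @param title_only Restrict matching to the title sentence (run
#'   configuration 3)?
#' @param max_gap Maximum number of word tokens between the two entity
#'   spans.
#' @param expand_composite Expand composite concept ids?
#' @return A candidate tibble with `source = "pattern"`,
#'   `scope = "sentence"`.
#' @export
match_patterns <- function(sents, patterns = default_cid_patterns(),
                           title_only = FALSE, max_gap = 3,
                           expand_composite = TRUE) {
  stopifnot(inherits(sents, "cid_sentences"))
  m <- active_mentions(sents)
  out <- list()
  for (si in unique(m$sentence_index)) {
    srow <- match(si, sents$sentences$index)
    if (title_only && !sents$sentences$in_title[srow]) next
    stext <- sents$sentences$text[srow]
    ms <- m[m$sentence_index == si, , drop = FALSE]
    ms <- ms[order(ms$local_start), , drop = FALSE]
    chem_i <- which(ms$type == "Chemical")
    dis_i <- which(ms$type == "Disease")
    if (!length(chem_i) || !length(dis_i)) next
    for (p in seq_len(nrow(patterns))) {
      first_i <- if (patterns$direction[p] == "chem_first") chem_i else dis_i
      second_i <- if (patterns$direction[p] == "chem_first") dis_i else chem_i
      for (a in first_i) for (b in second_i) {
        if (ms$local_end[a] > ms$local_start[b]) next  # need a before b
        between <- substr(stext, ms$local_end[a] + 1, ms$local_start[b])
        btoks <- pattern_tokens(between)
        if (length(btoks) > max_gap) next
        trig <- strsplit(patterns$trigger[p], " ", fixed = TRUE)[[1]]
        if (!has_subsequence(btoks, trig)) next
        # a coordinating conjunction between entity and trigger means the
        # trigger's argument is a nearer conjunct, not this mention
        # ("dobutamine and exercise induced ischaemia" must not pair
        # dobutamine with the trigger)
        if (any(btoks %in% c("and", "or", "nor", "but"))) next
        chem_row <- if (patterns$direction[p] == "chem_first") a else b
        dis_row <- if (patterns$direction[p] == "chem_first") b else a
        dis_rows <- dis_row
        if (patterns$allow_coordination[p] &&
            patterns$direction[p] == "chem_first") {
          dis_rows <- c(dis_rows,
                        coordinated_diseases(ms, dis_row, stext))
        }
        for (d in dis_rows) {
          cc <- expand_ids(ms$concept_id[chem_row], expand_composite)
          dd <- expand_ids(ms$concept_id[d], expand_composite)
          if (!length(cc) || !length(dd)) next
          out[[length(out) + 1]] <- tibble::tibble(
            pmid = sents$pmid,
            chemical_id = rep(cc, each = length(dd)),
            disease_id = rep(dd, times = length(cc)),
            scope = "sentence",
            sentence_indices = as.character(si),
            label = NA, source = "pattern")
        }
      }
    }
  }
  if (!length(out)) return(empty_candidates())
  res <- dplyr::distinct(dplyr::bind_rows(out),
                         .data$pmid, .data$chemical_id, .data$disease_id,
                         .keep_all = TRUE)
  candidate_order(res)
}

# contiguous subsequence test on token vectors
has_subsequence <- function(haystack, needle) {
  n <- length(needle)
  if (n == 0 || length(haystack) < n) return(FALSE)
  for (s in seq_len(length(haystack) - n + 1)) {
    if (all(haystack[s:(s + n - 1)] == needle)) return(TRUE)
  }
  FALSE
}

# Disease mentions coordinated after `dis_row`: following mentions reachable
# through separators that are only commas/semicolons/"and"/"or" (other
# mentions in the list may intervene).
coordinated_diseases <- function(ms, dis_row, stext) {
  res <- integer(0)
  ord <- order(ms$local_start)
  pos <- match(dis_row, ord)
  if (is.na(pos)) return(res)
  cur_end <- ms$local_end[dis_row]
  k <- pos + 1
  while (k <= length(ord)) {
    nxt <- ord[k]
    sep <- substr(stext, cur_end + 1, ms$local_start[nxt])
    sep_toks <- pattern_tokens(sep)
    sep_ok <- all(sep_toks %in% c("and", "or")) &&
      !grepl("[.;:]", sep) && length(sep_toks) <= 1 &&
      nchar(gsub("[ ,]|and|or", "", sep)) == 0
    if (!sep_ok) break
    if (ms$type[nxt] == "Disease") res <- c(res, nxt)
    cur_end <- ms$local_end[nxt]
    k <- k + 1
  }
  res
}
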