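#' Tokenize, tag and normalize a sentence
#'
#' Produces the shallow token layer consumed by feature extraction: for each
#' token its surface form, character span (0-based, half-open, sentence
#' local), lower-cased lemma, Porter stem, and a coarse part-of-speech tag.
#'
#' Tagging is a deterministic rule-based tagger (closed-class lexicon plus
#' suffix heuristics over Penn-style tags); lemmatization is rule-based
#' English inflection stripping with a small irregular-form table. Both are
#' intentionally lightweight: the classifier needs consistent, not perfect,
#' morpho-syntax.
#'
#' @param text Sentence text (non-empty after trimming).
#' @param sentence_id Optional identifier used in error messages.
#' @return A tibble with columns `token`, `start`, `end`, `lemma`, `stem`,
#'   `pos`.
#' @export
annotate_tokens <- function(text, sentence_id = NULL) {
  if (!nzchar(trimws(text))) {
    stop("processing error", if (!is.null(sentence_id))
      paste0(" in sentence ", sentence_id), ": empty sentence", call. = FALSE)
  }
  m <- gregexpr("[A-Za-z]+(?:'[A-Za-z]+)?|[0-9]+(?:[.,][0-9]+)*|[^A-Za-z0-9 \t]",
                text, perl = TRUE)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  starts <- as.integer(m) - 1L
  ends <- starts + attr(m, "match.length")
  tibble::tibble(
    token = toks, start = starts, end = ends,
    lemma = vapply(toks, lemmatize, character(1), USE.NAMES = FALSE),
    stem = vapply(tolower(toks), porter_stem, character(1), USE.NAMES = FALSE),
    pos = tag_pos(toks, starts))
}

.closed_class <- c(
  "the" = "DT", "a" = "DT", "an" = "DT", "this" = "DT", "that" = "DT",
  "these" = "DT", "those" = "DT", "each" = "DT", "both" = "DT", "no" = "DT",
  "of" = "IN", "in" = "IN", "on" = "IN", "at" = "IN", "by" = "IN",
  "with" = "IN", "without" = "IN", "for" = "IN", "from" = "IN", "to" = "TO",
  "after" = "IN", "before" = "IN", "during" = "IN", "under" = "IN",
  "between" = "IN", "into" = "IN", "than" = "IN", "as" = "IN",
  "and" = "CC", "or" = "CC", "but" = "CC", "nor" = "CC",
  "not" = "RB", "also" = "RB", "only" = "RB", "however" = "RB",
  "he" = "PRP", "she" = "PRP", "it" = "PRP", "they" = "PRP", "we" = "PRP",
  "who" = "WP", "which" = "WDT",
  "may" = "MD", "can" = "MD", "could" = "MD", "should" = "MD",
  "would" = "MD", "must" = "MD", "might" = "MD", "will" = "MD",
  "is" = "VBZ", "are" = "VBP", "was" = "VBD", "were" = "VBD", "be" = "VB",
  "been" = "VBN", "being" = "VBG", "has" = "VBZ", "have" = "VBP",
  "had" = "VBD", "do" = "VBP", "does" = "VBZ", "did" = "VBD")

tag_pos <- function(tokens, starts) {
  low <- tolower(tokens)
  vapply(seq_along(tokens), function(i) {
    tok <- tokens[i]; lt <- low[i]
    if (!is.na(.closed_class[lt])) return(unname(.closed_class[lt]))
    if (grepl("^[0-9]", tok)) return("CD")
    if (grepl("^[^A-Za-z0-9]", tok)) return("SYM")
    if (grepl("ly$", lt) && nchar(lt) > 3) return("RB")
    if (grepl("ing$", lt) && nchar(lt) > 4) return("VBG")
    if (grepl("ed$", lt) && nchar(lt) > 3) return("VBD")
    if (grepl("(ous|ive|ic|al|able|ible|ary|ar|ful|less)$", lt) &&
        nchar(lt) > 4) return("JJ")
    if (grepl("[A-Z]", substr(tok, 1, 1)) && starts[i] > 0) return("NNP")
    if (grepl("s$", lt) && !grepl("(ss|us|is)$", lt) && nchar(lt) > 3) {
      return("NNS")
    }
    "NN"
  }, character(1))
}

.irregular_lemma <- c(
  "is" = "be", "are" = "be", "was" = "be", "were" = "be", "been" = "be",
  "being" = "be", "am" = "be", "has" = "have", "had" = "have",
  "having" = "have", "does" = "do", "did" = "do", "done" = "do",
  "men" = "man", "women" = "woman", "children" = "child", "mice" = "mouse",
  "feet" = "foot", "teeth" = "tooth", "data" = "datum", "given" = "give",
  "taken" = "take", "shown" = "show", "found" = "find", "seen" = "see",
  "made" = "make", "led" = "lead", "worse" = "bad", "better" = "good")

#' Rule-based English lemmatizer
#'
#' Lower-cases and strips regular inflection (`-s`, `-es`, `-ies`, `-ed`,
#' `-ing`) with orthographic repair (consonant undoubling, silent-e
#' restoration), after consulting a small irregular-form table. E.g.
#' `"induced"` becomes `"induce"`, `"patients"` becomes `"patient"`.
#'
#' @param token A single token.
#' @return The lemma (lower case).
#' @export
lemmatize <- function(token) {
  w <- tolower(token)
  if (!is.na(.irregular_lemma[w])) return(unname(.irregular_lemma[w]))
  if (nchar(w) <= 3 || grepl("[^a-z]", w)) return(w)
  restore <- function(stem) {
    # doubled final consonant from gemination: stopp -> stop
    n <- nchar(stem)
    last <- substr(stem, n, n)
    prev <- substr(stem, n - 1, n - 1)
    if (n > 2 && last == prev && !last %in% c("l", "s", "z") &&
        !grepl("[aeiou]", last)) {
      return(substr(stem, 1, n - 1))
    }
    # silent e dropped before -ed/-ing: induc -> induce
    if (grepl("([cgsvz]|[^aeiou][aeiou][^aeiouwxy])$", stem) &&
        !grepl("(ee|[aeiou]{2})$", stem)) {
      # only restore e for the soft-consonant endings; CVC handled above
      if (grepl("[cgsvz]$", stem)) return(paste0(stem, "e"))
    }
    stem
  }
  if (grepl("ies$", w) && nchar(w) > 4) return(sub("ies$", "y", w))
  if (grepl("(sses|ches|shes|xes|zes)$", w)) return(sub("es$", "", w))
  if (grepl("s$", w) && !grepl("(ss|us|is)$", w)) return(sub("s$", "", w))
  if (grepl("ied$", w)) return(sub("ied$", "y", w))
  if (grepl("eed$", w)) return(w)
  if (grepl("ed$", w) && grepl("[aeiouy].*ed$", w)) {
    return(restore(sub("ed$", "", w)))
  }
  if (grepl("ing$", w) && nchar(w) > 5 && grepl("[aeiouy].*ing$", w)) {
    return(restore(sub("ing$", "", w)))
  }
  w
}

# ---- Porter stemmer ---------------------------------------------------------
# Implemented from the published 1980 algorithm (steps 1a-5b, measure-based
# conditions). Operates on lower-case ASCII words; non-alphabetic tokens are
# returned unchanged.

p_is_cons <- function(chars, i) {
  ch <- chars[i]
  if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
  if (ch == "y") {
    if (i == 1) return(TRUE)
    return(!p_is_cons(chars, i - 1))
  }
  TRUE
}

p_measure <- function(word) {
  chars <- strsplit(word, "")[[1]]
  if (!length(chars)) return(0L)
  types <- vapply(seq_along(chars), function(i) p_is_cons(chars, i),
                  logical(1))
  rle_t <- rle(types)
  v <- rle_t$values
  if (length(v) && v[1]) v <- v[-1]            # drop leading C block
  if (length(v) && !v[length(v)]) v <- v[-length(v)]  # drop trailing V block
  as.integer(length(v) / 2)
}

p_has_vowel <- function(word) {
  chars <- strsplit(word, "")[[1]]
  any(vapply(seq_along(chars), function(i) !p_is_cons(chars, i), logical(1)))
}

p_double_cons <- function(word) {
  n <- nchar(word)
  if (n < 2) return(FALSE)
  a <- substr(word, n - 1, n - 1); b <- substr(word, n, n)
  a == b && p_is_cons(strsplit(word, "")[[1]], n)
}

p_cvc <- function(word) {
  n <- nchar(word)
  if (n < 3) return(FALSE)
  chars <- strsplit(word, "")[[1]]
  p_is_cons(chars, n) && !p_is_cons(chars, n - 1) && p_is_cons(chars, n - 2) &&
    !chars[n] %in% c("w", "x", "y")
}

p_replace <- function(word, suffix, repl, m_min = 0) {
  if (!endsWith(word, suffix)) return(NULL)
  stem <- substr(word, 1, nchar(word) - nchar(suffix))
  if (p_measure(stem) > m_min - 1) return(paste0(stem, repl))
  word
}

#' Porter stemmer
#'
#' The classic suffix-stripping stemmer, e.g. `"induced"` stems to
#' `"induc"` and `"toxicity"` to `"toxic"`.
#'
#' @param word A single lower-case word.
#' @return The stem.
#' @export
porter_stem <- function(word) {
  if (nchar(word) <= 2 || grepl("[^a-z]", word)) return(word)
  w <- word
  # Step 1a
  if (endsWith(w, "sses")) w <- sub("sses$", "ss", w)
  else if (endsWith(w, "ies")) w <- sub("ies$", "i", w)
  else if (endsWith(w, "ss")) w <- w
  else if (endsWith(w, "s")) w <- sub("s$", "", w)
  # Step 1b
  did_1b <- FALSE
  if (endsWith(w, "eed")) {
    stem <- sub("eed$", "", w)
    if (p_measure(stem) > 0) w <- sub("eed$", "ee", w)
  } else if (endsWith(w, "ed")) {
    stem <- sub("ed$", "", w)
    if (p_has_vowel(stem)) { w <- stem; did_1b <- TRUE }
  } else if (endsWith(w, "ing")) {
    stem <- sub("ing$", "", w)
    if (p_has_vowel(stem)) { w <- stem; did_1b <- TRUE }
  }
  if (did_1b) {
    if (endsWith(w, "at") || endsWith(w, "bl") || endsWith(w, "iz")) {
      w <- paste0(w, "e")
    } else if (p_double_cons(w) &&
               !substr(w, nchar(w), nchar(w)) %in% c("l", "s", "z")) {
      w <- substr(w, 1, nchar(w) - 1)
    } else if (p_measure(w) == 1 && p_cvc(w)) {
      w <- paste0(w, "e")
    }
  }
  # Step 1c
  if (endsWith(w, "y") && p_has_vowel(substr(w, 1, nchar(w) - 1))) {
    w <- sub("y$", "i", w)
  }
  # Step 2 (longest-suffix first within the step)
  s2 <- list(c("ational", "ate"), c("ization", "ize"), c("iveness", "ive"),
             c("fulness", "ful"), c("ousness", "ous"), c("tional", "tion"),
             c("biliti", "ble"), c("entli", "ent"), c("ousli", "ous"),
             c("ation", "ate"), c("alism", "al"), c("aliti", "al"),
             c("iviti", "ive"), c("enci", "ence"), c("anci", "ance"),
             c("izer", "ize"), c("abli", "able"), c("alli", "al"),
             c("ator", "ate"), c("eli", "e"))
  for (r in s2) {
    if (endsWith(w, r[1])) { w <- p_replace(w, r[1], r[2], 1); break }
  }
  # Step 3
  s3 <- list(c("icate", "ic"), c("ative", ""), c("alize", "al"),
             c("iciti", "ic"), c("ical", "ic"), c("ful", ""), c("ness", ""))
  for (r in s3) {
    if (endsWith(w, r[1])) { w <- p_replace(w, r[1], r[2], 1); break }
  }
  # Step 4
  s4 <- c("ement", "ance", "ence", "able", "ible", "ment", "ant", "ent",
          "ism", "ate", "iti", "ous", "ive", "ize", "ion", "al", "er",
          "ic", "ou")
  for (sfx in s4) {
    if (endsWith(w, sfx)) {
      stem <- substr(w, 1, nchar(w) - nchar(sfx))
      if (sfx == "ion" && !grepl("[st]$", stem)) break
      if (p_measure(stem) > 1) w <- stem
      break
    }
  }
  # Step 5a
  if (endsWith(w, "e")) {
    stem <- substr(w, 1, nchar(w) - 1)
    m <- p_measure(stem)
    if (m > 1 || (m == 1 && !p_cvc(stem))) w <- stem
  }
  # Step 5b
  if (p_measure(w) > 1 && p_double_cons(w) && endsWith(w, "l")) {
    w <- substr(w, 1, nchar(w) - 1)
  }
  w
}
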