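# Shared fixtures and independent oracles, built in code at test time.

# Document fixture from running text: mentions located by exact string search.
make_doc <- function(pmid, title, abstract, spec, gold = NULL) {
  full <- paste(title, abstract, sep = " ")
  rows <- lapply(seq_len(nrow(spec)), function(i) {
    g <- gregexpr(spec$text[i], full, fixed = TRUE)[[1]]
    tibble::tibble(start = as.integer(g) - 1L,
                   end = as.integer(g) - 1L + nchar(spec$text[i]),
                   text = spec$text[i], type = spec$type[i],
                   concept_id = spec$concept_id[i])
  })
  m <- dplyr::arrange(dplyr::bind_rows(rows), start)
  if (is.null(gold)) gold <- tibble::tibble(chemical_id = character(),
                                            disease_id = character())
  cid_document(pmid, title, abstract, m, gold)
}

# The heparin error-analysis sentence with its entity annotations.
heparin_doc <- function() {
  dis <- c("thrombocytopenia", "osteoporosis", "eosinophilia",
           "allergic reactions", "alopecia", "hyperkalemia",
           "hypoaldosteronism", "priapism")
  spec <- dplyr::bind_rows(
    tibble::tibble(text = "heparin", type = "Chemical",
                   concept_id = "D006493"),
    tibble::tibble(text = dis, type = "Disease",
                   concept_id = sprintf("D%06d", seq_along(dis))))
  make_doc("10726030", "Untoward effects of heparin.",
           paste0("However, additional important untoward effects of ",
                  "heparin therapy include heparin-induced ",
                  "thrombocytopenia, heparin-associated osteoporosis, ",
                  "eosinophilia, allergic reactions, alopecia, ",
                  "hyperkalemia, hypoaldosteronism, and priapism."),
           spec)
}

# The two therapeutic-indication context sentences.
indication_doc_coronary <- function() {
  make_doc("10677406", "Stress testing report.",
           paste0("Prolonged left ventricular dysfunction occurs in ",
                  "patients with coronary artery disease after both ",
                  "dobutamine and exercise induced myocardial ischaemia."),
           tibble::tibble(
             text = c("left ventricular dysfunction",
                      "coronary artery disease", "dobutamine",
                      "myocardial ischaemia"),
             type = c("Disease", "Disease", "Chemical", "Disease"),
             concept_id = c("D018487", "D003324", "D004280", "D017202")))
}

indication_doc_cancer <- function() {
  make_doc("10327032", "Chemotherapy complications.",
           paste0("Risk of transient hyperammonemic encephalopathy in ",
                  "cancer patients who received continuous infusion of ",
                  "5-fluorouracil with the complication of dehydration ",
                  "and infection."),
           tibble::tibble(
             text = c("encephalopathy", "cancer", "5-fluorouracil",
                      "dehydration", "infection"),
             type = c("Disease", "Disease", "Chemical", "Disease",
                      "Disease"),
             concept_id = c("D001927", "D009369", "D005472", "D003681",
                            "D007239")))
}

# Labeled sentence-level instances for a generated corpus.
corpus_instances <- function(corp, filter_cfg = filter_config()) {
  unlist(lapply(corp$documents, function(d) {
    s <- preprocess_document(d, filter_cfg)
    build_instances(s, label_candidates(sentence_cooccurrences(s), d$gold))
  }), recursive = FALSE)
}

# ---- independent oracles ----------------------------------------------------

# Overlap resolution oracle: maximal-length, leftmost selection by explicit
# repeated argmax — among still-unresolved mentions, keep the longest
# (leftmost start, then earliest row, on ties) and discard everything
# overlapping it; repeat. Coded independently of the vectorized
# sort-and-scan implementation.
oracle_resolve_overlaps <- function(starts, ends) {
  alive <- seq_along(starts)
  kept <- integer(0)
  while (length(alive)) {
    best <- alive[1]
    for (i in alive[-1]) {
      li <- ends[i] - starts[i]; lb <- ends[best] - starts[best]
      if (li > lb || (li == lb && starts[i] < starts[best])) best <- i
    }
    kept <- c(kept, best)
    overlaps <- vapply(alive, function(i)
      starts[i] < ends[best] && starts[best] < ends[i], logical(1))
    alive <- alive[!overlaps]
  }
  sort(kept)
}

# Brute-force shallow-feature enumeration, written against the documented
# scheme (placeholder-collapsed units; fb/b/ba n-grams; +/-window locals)
# with nested loops independent of extract_features() internals.
oracle_features <- function(units, ngram_max = 3, window = 2) {
  p <- which(units$role != "")
  n <- nrow(units)
  feats <- character(0)
  spans <- list(fb = c(1, p[2]), b = c(p[1], p[2]), ba = c(p[1], n))
  for (cn in names(spans)) {
    lo <- spans[[cn]][1]; hi <- spans[[cn]][2]
    for (a in c("surface", "lemma", "stem", "pos")) {
      for (g in 1:ngram_max) {
        if (hi - lo + 1 < g) next
        for (s in lo:(hi - g + 1)) {
          feats <- c(feats, paste("g", cn, a, g,
                                  paste(units[[a]][s:(s + g - 1)],
                                        collapse = "_"), sep = "|"))
        }
      }
    }
  }
  for (ri in 1:2) {
    role <- c("CHEMICAL", "DISEASE")[ri]
    e <- which(units$role == role)
    for (d in setdiff(-window:window, 0)) {
      j <- e + d
      if (j < 1 || j > n) next
      for (a in c("surface", "lemma", "stem", "pos")) {
        feats <- c(feats, paste("l", role, d, a, units[[a]][j], sep = "|"))
      }
    }
  }
  sort(unique(feats))
}

# Random blinded-unit table for feature oracle checks.
random_units <- function(n_tokens = 10) {
  vocab <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "eta",
             "theta", "iota", "kappa")
  u <- tibble::tibble(
    surface = sample(vocab, n_tokens, replace = TRUE),
    lemma = sample(vocab, n_tokens, replace = TRUE),
    stem = sample(vocab, n_tokens, replace = TRUE),
    pos = sample(c("NN", "VBD", "IN", "JJ"), n_tokens, replace = TRUE),
    role = "")
  pos <- sort(sample(n_tokens, 2))
  u$role[pos] <- c("CHEMICAL", "DISEASE")
  for (a in c("surface", "lemma", "stem", "pos")) {
    u[[a]][pos] <- u$role[pos]
  }
  u
}

# A cid_instance whose blinded_units() equal `units` (single-token entities).
units_to_instance <- function(units, label = NA) {
  n <- nrow(units)
  toks <- tibble::tibble(
    token = units$surface, start = seq_len(n) * 10L,
    end = seq_len(n) * 10L + 5L, lemma = units$lemma, stem = units$stem,
    pos = units$pos)
  structure(list(pmid = "x", chemical_id = "C1", disease_id = "D1",
                 sentence_index = 1L, tokens = toks,
                 e1 = which(units$role == "CHEMICAL"),
                 e2 = which(units$role == "DISEASE"), label = label),
            class = "cid_instance")
}
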