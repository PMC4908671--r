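test_that("sentence co-occurrences are the per-sentence ID cross product", {
  d <- make_doc("5", "Report.",
                "Drugone caused nausea and headache in the trial.",
                tibble::tibble(
                  text = c("Drugone", "nausea", "headache"),
                  type = c("Chemical", "Disease", "Disease"),
                  concept_id = c("C1", "E1", "E2")))
  cand <- sentence_cooccurrences(split_sentences(d))
  expect_equal(nrow(cand), 2)
  expect_setequal(cand$disease_id, c("E1", "E2"))
  expect_true(all(cand$chemical_id == "C1"))
})

test_that("the heparin sentence yields eight chemical-disease candidates", {
  s <- preprocess_document(heparin_doc())
  cand <- sentence_cooccurrences(s)
  expect_equal(nrow(cand), 8)
  expect_true(all(cand$chemical_id == "D006493"))
  expect_equal(length(unique(cand$disease_id)), 8)
})

test_that("candidate sets match a brute-force oracle on random corpora", {
  corp <- generate_corpus(generator_config(n_docs = 25, p_misnorm = 0.1,
                                           seed = 501))
  for (d in corp$documents) {
    s <- preprocess_document(d)
    got <- sentence_cooccurrences(s)
    # oracle: enumerate pairs per sentence with nested loops, dedupe
    m <- active_mentions(s)
    keys <- character(0)
    for (i in seq_len(nrow(m))) for (j in seq_len(nrow(m))) {
      if (m$type[i] == "Chemical" && m$type[j] == "Disease" &&
          m$sentence_index[i] == m$sentence_index[j] &&
          m$concept_id[i] != "-1" && m$concept_id[j] != "-1") {
        keys <- c(keys, paste(m$concept_id[i], m$concept_id[j]))
      }
    }
    expect_setequal(paste(got$chemical_id, got$disease_id), unique(keys))
    # sentence-level candidates are a subset of abstract-level candidates
    abs_cand <- abstract_cooccurrences(s)
    expect_true(all(paste(got$chemical_id, got$disease_id) %in%
                    paste(abs_cand$chemical_id, abs_cand$disease_id)))
  }
})

test_that("abstract-only pairs carry no sentence indices", {
  d <- make_doc("6", "Drugtwo pharmacology.",
                "It was given daily. Later fatigue developed.",
                tibble::tibble(text = c("Drugtwo", "fatigue"),
                               type = c("Chemical", "Disease"),
                               concept_id = c("C2", "E9")))
  cand <- abstract_cooccurrences(split_sentences(d))
  expect_equal(nrow(cand), 1)
  expect_equal(cand$sentence_indices, "")
  expect_equal(nrow(sentence_cooccurrences(split_sentences(d))), 0)
  # no chemicals -> empty
  d2 <- cid_document("7", "T.", "A body.")
  expect_equal(nrow(abstract_cooccurrences(split_sentences(d2))), 0)
})

test_that("unnormalized ids are excluded and composite ids expand", {
  d <- make_doc("8", "Report.", "Drugthree worsened tremor notably.",
                tibble::tibble(text = c("Drugthree", "tremor"),
                               type = c("Chemical", "Disease"),
                               concept_id = c("C3", "E1|E2")))
  cand <- sentence_cooccurrences(split_sentences(d))
  expect_setequal(cand$disease_id, c("E1", "E2"))
  cand2 <- sentence_cooccurrences(split_sentences(d),
                                  expand_composite = FALSE)
  expect_equal(nrow(cand2), 0)
  d$mentions$concept_id[d$mentions$text == "tremor"] <- "-1"
  expect_equal(nrow(sentence_cooccurrences(split_sentences(d))), 0)
})

test_that("labeling marks exactly the gold intersection", {
  cand <- tibble::tibble(pmid = "1", chemical_id = c("C1", "C1"),
                         disease_id = c("E1", "E2"), scope = "sentence",
                         sentence_indices = "1", label = NA,
                         source = "cooccurrence")
  gold <- tibble::tibble(chemical_id = "C1", disease_id = "E1")
  out <- label_candidates(cand, gold)
  expect_equal(out$label, c(TRUE, FALSE))
  expect_false(any(label_candidates(cand, gold[0, ])$label))
  # count of true labels equals |gold intersect candidates|
  corp <- generate_corpus(generator_config(n_docs = 15, seed = 502))
  for (d in corp$documents) {
    s <- preprocess_document(d)
    lab <- label_candidates(abstract_cooccurrences(s), d$gold)
    gk <- paste(d$gold$chemical_id, d$gold$disease_id)
    ck <- paste(lab$chemical_id, lab$disease_id)
    expect_equal(sum(lab$label), length(intersect(gk, ck)))
  }
})

test_that("candidate generation is deterministic and ordered", {
  corp <- generate_corpus(generator_config(n_docs = 5, seed = 503))
  s <- preprocess_document(corp$documents[[1]])
  a <- sentence_cooccurrences(s)
  b <- sentence_cooccurrences(s)
  expect_identical(a, b)
  expect_false(is.unsorted(paste(a$pmid, a$chemical_id, a$disease_id)))
})
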