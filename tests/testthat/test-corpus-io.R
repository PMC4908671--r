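test_that("parsing verifies mention offsets and recovers fields", {
  txt <- paste0(
    "123|t|Heparin case report.\n",
    "123|a|Heparin therapy can include thrombocytopenia as an effect.\n",
    "123\t49\t65\tthrombocytopenia\tDisease\tD013921\n",
    "123\t0\t7\tHeparin\tChemical\tD006493\n",
    "123\tCID\tD006493\tD013921\n")
  docs <- parse_pubtator(txt)
  expect_length(docs, 1)
  d <- docs[[1]]
  expect_equal(d$pmid, "123")
  expect_equal(nrow(d$mentions), 2)
  sl <- substring(doc_text(d), d$mentions$start + 1, d$mentions$end)
  expect_equal(sl, d$mentions$text)
  expect_equal(d$mentions$text[d$mentions$type == "Disease"],
               "thrombocytopenia")
  expect_equal(d$gold$chemical_id, "D006493")

  # offset/text mismatch is an integrity error naming the pmid
  bad <- sub("49\t65", "50\t66", txt)
  expect_error(parse_pubtator(bad), "123")
  # malformed annotation line names the line number
  expect_error(parse_pubtator("123|t|T.\n123|a|A.\n123\tx\ty\n"), "line 3")
  # empty stream
  expect_equal(parse_pubtator(""), list())
})

test_that("write/parse round-trips synthetic corpora bit-exactly", {
  corp <- generate_corpus(generator_config(n_docs = 25, p_miss = 0.1,
                                           p_misnorm = 0.1, seed = 301))
  txt <- write_pubtator(corp$documents)
  docs2 <- parse_pubtator(txt)
  expect_equal(docs2, corp$documents)
  expect_identical(write_pubtator(docs2), txt)
})

test_that("writer emits the expected lines for a minimal document", {
  d <- cid_document("7", "A title.", "A body.")
  lines <- strsplit(write_pubtator(d), "\n")[[1]]
  expect_equal(lines[1:2], c("7|t|A title.", "7|a|A body."))
  d2 <- cid_document("7", "A title.", "A body.",
                     gold = tibble::tibble(chemical_id = "C1",
                                           disease_id = "D1"))
  expect_true("7\tCID\tC1\tD1" %in% strsplit(write_pubtator(d2), "\n")[[1]])
})

test_that("sentence splitting projects mentions with exact local offsets", {
  d <- make_doc("11439380",
                "Thalidomide neuropathy in patients treated for metastatic prostate cancer.",
                "Dose was reduced. Neuropathy persisted in two cases.",
                tibble::tibble(
                  text = c("Thalidomide", "neuropathy", "prostate cancer",
                           "Neuropathy"),
                  type = c("Chemical", "Disease", "Disease", "Disease"),
                  concept_id = c("D013792", "D010523", "D011471",
                                 "D010523")))
  s <- split_sentences(d)
  expect_equal(nrow(s$sentences), 3)
  expect_true(s$sentences$in_title[1])
  expect_false(any(s$sentences$in_title[-1]))
  # local slices reproduce mention text
  for (i in seq_len(nrow(s$mentions))) {
    m <- s$mentions[i, ]
    stext <- s$sentences$text[match(m$sentence_index,
                                    s$sentences$index)]
    expect_equal(substring(stext, m$local_start + 1, m$local_end), m$text)
  }
  # title mention lands in the title sentence
  expect_equal(
    s$mentions$sentence_index[s$mentions$text == "Thalidomide"], 0L)
  # abbreviations do not split
  d2 <- cid_document("1", "T.", "Given e.g. Aspirin daily. Next sentence.")
  expect_equal(nrow(split_sentences(d2)$sentences), 3)
})

test_that("every non-straddling mention lands in exactly one sentence", {
  corp <- generate_corpus(generator_config(n_docs = 30, seed = 302))
  for (d in corp$documents) {
    s <- split_sentences(d)
    m <- s$mentions[!s$mentions$straddles, , drop = FALSE]
    # brute-force containment: count sentences fully containing each span
    for (i in seq_len(nrow(m))) {
      n_holding <- sum(s$sentences$doc_start <= m$start[i] &
                       m$end[i] <= s$sentences$doc_start +
                         nchar(s$sentences$text))
      expect_equal(n_holding, 1)
    }
    expect_equal(nrow(m), nrow(s$mentions))  # generator plants no straddlers
  }
})
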