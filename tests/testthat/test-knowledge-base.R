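kb_fixture <- function() {
  tibble::tibble(
    chemical_id = c("C1", "C1", "C2", "C2", "C3", "C3"),
    disease_id = c("E1", "E2", "E1", "E1", "E3", "E3"),
    label = c("therapeutic", "side_effect", "side_effect", "side_effect",
              "therapeutic", "side_effect"),
    provenance = "test")
}

test_that("dual-labeled pairs are rejected at load time", {
  expect_message(kb <- load_kb(kb_fixture()), "both therapeutic")
  expect_equal(kb$n_dual_dropped, 1)           # (C3, E3)
  expect_equal(kb$n_duplicates, 1)             # duplicated (C2, E1) row
  expect_equal(kb$n_therapeutic, 1)
  expect_equal(kb$n_side_effect, 2)
  expect_false(any(kb$entries$chemical_id == "C3"))
  # loaded size = rows - duplicates - dual-labeled rows
  expect_equal(nrow(kb$entries),
               nrow(kb_fixture()) - kb$n_duplicates - 2)
  expect_error(load_kb(tibble::tibble(chemical_id = "C1",
                                      disease_id = "E1", label = "oops",
                                      provenance = "x")), "row 1")
  empty <- load_kb(kb_fixture()[0, ])
  expect_equal(nrow(empty$entries), 0)
})

test_that("therapeutic filtering removes exactly the known indications", {
  kb <- suppressMessages(load_kb(kb_fixture()))
  pairs <- tibble::tibble(pmid = "1", chemical_id = c("C1", "C1", "C9"),
                          disease_id = c("E1", "E2", "E9"),
                          scope = "abstract", sentence_indices = "",
                          label = NA, source = "cooccurrence")
  out <- filter_therapeutic(pairs, kb)
  expect_equal(paste(out$chemical_id, out$disease_id), c("C1 E2", "C9 E9"))
  # monotone + idempotent + order preserving
  expect_equal(filter_therapeutic(out, kb), out)
})

test_that("side-effect selection keeps exactly the known SE pairs", {
  kb <- suppressMessages(load_kb(kb_fixture()))
  pairs <- tibble::tibble(pmid = "1", chemical_id = c("C1", "C2", "C9"),
                          disease_id = c("E2", "E1", "E9"),
                          scope = "abstract", sentence_indices = "",
                          label = NA, source = "cooccurrence")
  out <- select_known_se(pairs, kb)
  expect_equal(paste(out$chemical_id, out$disease_id), c("C1 E2", "C2 E1"))
  expect_true(all(out$source == "kb"))
  # dual-label exclusion makes select-then-filter a no-op
  expect_equal(filter_therapeutic(out, kb)[, names(out)], out)
})

test_that("disease identifier mapping applies before indexing", {
  kb <- load_kb(tibble::tibble(chemical_id = "C1", disease_id = "UMLS:9",
                               label = "side_effect", provenance = "x"),
                mapping = tibble::tibble(source_id = "UMLS:9",
                                         mesh_id = "E1"))
  expect_equal(kb$entries$disease_id, "E1")
})

test_that("generated KBs respect coverage settings", {
  corp <- generate_corpus(generator_config(n_docs = 30, seed = 801))
  gold <- corpus_gold(corp)
  # full coverage: every abstract-level candidate that is gold survives
  kb1 <- generate_kb(corp, se_coverage = 1, seed = 1)
  for (d in corp$documents[1:5]) {
    s <- preprocess_document(d)
    cand <- abstract_cooccurrences(s)
    kept <- select_known_se(cand, kb1)
    lab <- label_candidates(cand, d$gold)
    expect_true(all(paste(lab$chemical_id[lab$label],
                          lab$disease_id[lab$label]) %in%
                    paste(kept$chemical_id, kept$disease_id)))
  }
  # zero coverage: nothing survives selection
  kb0 <- generate_kb(corp, se_coverage = 0, seed = 1)
  s <- preprocess_document(corp$documents[[1]])
  expect_equal(nrow(select_known_se(abstract_cooccurrences(s), kb0)), 0)
  # therapeutic entries never collide with gold
  expect_false(any(paste(kb1$entries$chemical_id[
    kb1$entries$label == "therapeutic"],
    kb1$entries$disease_id[kb1$entries$label == "therapeutic"]) %in%
      paste(gold$chemical_id, gold$disease_id)))
})
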