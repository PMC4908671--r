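# One small trained model + corpus + KB shared across combiner tests.
combiner_env <- new.env()
combiner_fixture <- function() {
  if (is.null(combiner_env$model)) {
    train_corp <- generate_corpus(generator_config(
      n_docs = 100, frac_abstract_only = 0, seed = 1101))
    combiner_env$model <- train_relation_model(corpus_instances(train_corp))
    combiner_env$corp <- generate_corpus(generator_config(
      n_docs = 60, p_miss = 0.05, seed = 1102))
    combiner_env$kb <- generate_kb(combiner_env$corp, se_coverage = 0.7,
                                   n_extra_therapeutic = 15, seed = 9)
  }
  combiner_env
}

test_that("run configuration enforces component requirements", {
  expect_error(run_config("cascade", components = c("patterns", "ml")),
               "cascade")
  expect_error(run_pipeline(list(), model = NULL, kb = NULL,
                            cfg = run_config("union")), "config error")
  cfg <- run_config("union_title_patterns")
  expect_equal(cfg$mode, "union_title_patterns")
})

test_that("cascade reports pattern pairs alone when patterns fire", {
  fx <- combiner_fixture()
  d <- make_doc("77", "Drugnine-induced stupor.",
                "Drugnine was studied. Later weakness was noted.",
                tibble::tibble(
                  text = c("Drugnine", "stupor", "Drugnine", "weakness"),
                  type = c("Chemical", "Disease", "Chemical", "Disease"),
                  concept_id = c("C900", "E900", "C900", "E901")),
                gold = tibble::tibble(chemical_id = "C900",
                                      disease_id = "E900"))
  r1 <- run_pipeline(d, fx$model, fx$kb, run_config("cascade"))
  expect_equal(nrow(r1), 1)
  expect_equal(r1$source, "pattern")
  expect_equal(paste(r1$chemical_id, r1$disease_id), "C900 E900")
  # union mode is a superset and may add other components' pairs
  r2 <- run_pipeline(d, fx$model, fx$kb, run_config("union"))
  expect_true(all(paste(r1$chemical_id, r1$disease_id) %in%
                  paste(r2$chemical_id, r2$disease_id)))
})

test_that("title-only patterns ignore body pattern sentences", {
  fx <- combiner_fixture()
  d <- make_doc("78", "A safety report.",
                "Drugten-induced rigors were frequent.",
                tibble::tibble(text = c("Drugten", "rigors"),
                               type = c("Chemical", "Disease"),
                               concept_id = c("C901", "E902")))
  r3 <- run_pipeline(d, fx$model, fx$kb,
                     run_config("union_title_patterns"))
  expect_false(any(r3$source == "pattern"))
  r2 <- run_pipeline(d, fx$model, fx$kb, run_config("union"))
  expect_true(any(r2$source == "pattern"))
})

test_that("cascade and title-pattern outputs are subsets of the union", {
  fx <- combiner_fixture()
  key <- function(x) paste(x$pmid, x$chemical_id, x$disease_id)
  r1 <- run_pipeline(fx$corp$documents, fx$model, fx$kb,
                     run_config("cascade"))
  r2 <- run_pipeline(fx$corp$documents, fx$model, fx$kb,
                     run_config("union"))
  r3 <- run_pipeline(fx$corp$documents, fx$model, fx$kb,
                     run_config("union_title_patterns"))
  expect_true(all(key(r1) %in% key(r2)))
  expect_true(all(key(r3) %in% key(r2)))
})

test_that("final outputs never contain known therapeutic pairs", {
  fx <- combiner_fixture()
  ther <- fx$kb$entries[fx$kb$entries$label == "therapeutic", ]
  tk <- paste(ther$chemical_id, ther$disease_id)
  for (mode in c("cascade", "union", "union_title_patterns")) {
    r <- run_pipeline(fx$corp$documents[1:20], fx$model, fx$kb,
                      run_config(mode))
    expect_false(any(paste(r$chemical_id, r$disease_id) %in% tk))
  }
  # treatment_filtering delegates to the KB filter
  pairs <- tibble::tibble(pmid = "1", chemical_id = ther$chemical_id[1],
                          disease_id = ther$disease_id[1],
                          scope = "abstract", sentence_indices = "",
                          label = NA, source = "ml")
  expect_equal(nrow(treatment_filtering(pairs, fx$kb)), 0)
})

test_that("ek-role filter drops the KB as a pair source", {
  fx <- combiner_fixture()
  r_sel <- run_pipeline(fx$corp$documents[1:10], fx$model, fx$kb,
                        run_config("union", ek_role = "both"))
  r_fil <- run_pipeline(fx$corp$documents[1:10], fx$model, fx$kb,
                        run_config("union", ek_role = "filter"))
  expect_false(any(r_fil$source == "kb"))
  key <- function(x) paste(x$pmid, x$chemical_id, x$disease_id)
  expect_true(all(key(r_fil) %in% key(r_sel)))
})

test_that("dedup keeps the highest-priority provenance tag", {
  fx <- combiner_fixture()
  d <- make_doc("79", "Drugnine-induced stupor.",
                "More text follows here.",
                tibble::tibble(text = c("Drugnine", "stupor"),
                               type = c("Chemical", "Disease"),
                               concept_id = c("C900", "E900")))
  kb_se <- load_kb(tibble::tibble(chemical_id = "C900",
                                  disease_id = "E900",
                                  label = "side_effect",
                                  provenance = "x"))
  r <- run_pipeline(d, fx$model, kb_se, run_config("union"))
  expect_equal(nrow(r), 1)
  expect_equal(r$source, "pattern")
})
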