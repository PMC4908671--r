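test_that("a lone between-token contributes its context features", {
  # CHEMICAL induced DISEASE: between context holds only the trigger
  d <- make_doc("1", "T.", "Drugone induced nausea.",
                tibble::tibble(text = c("Drugone", "nausea"),
                               type = c("Chemical", "Disease"),
                               concept_id = c("C1", "E1")))
  s <- split_sentences(d)
  inst <- build_instances(s, sentence_cooccurrences(s))[[1]]
  fv <- extract_features(inst)
  expect_true("g|b|lemma|1|induce" %in% names(fv))
  expect_true("g|b|stem|1|induc" %in% names(fv))
  expect_true("g|b|surface|3|CHEMICAL_induced_DISEASE" %in% names(fv))
  expect_true("l|CHEMICAL|1|lemma|induce" %in% names(fv))
})

test_that("entity blinding makes vectors invariant to entity surfaces", {
  mk <- function(chem, dis) {
    d <- make_doc("1", "T.", paste0(chem, " induced ", dis, "."),
                  tibble::tibble(text = c(chem, dis),
                                 type = c("Chemical", "Disease"),
                                 concept_id = c("C1", "E1")))
    s <- split_sentences(d)
    extract_features(build_instances(s, sentence_cooccurrences(s))[[1]])
  }
  expect_identical(mk("Drugone", "nausea"), mk("Zaltrexin", "cephalgia"))
})

test_that("feature vectors equal brute-force n-gram enumeration", {
  set.seed(701)
  for (rep in 1:100) {
    u <- random_units(10)
    inst <- units_to_instance(u)
    got <- sort(names(extract_features(inst)))
    expect_identical(got, oracle_features(u))
  }
})

test_that("multi-token entities collapse to single placeholders", {
  d <- make_doc("1", "T.", "Optic nerve toxicity caused by tacrolimus.",
                tibble::tibble(
                  text = c("Optic nerve toxicity", "tacrolimus"),
                  type = c("Disease", "Chemical"),
                  concept_id = c("E1", "C1")))
  s <- split_sentences(d)
  inst <- build_instances(s, sentence_cooccurrences(s))[[1]]
  fv <- extract_features(inst)
  expect_true("g|b|surface|4|DISEASE_caused_by_CHEMICAL" %in%
                names(fv) == FALSE)  # n-grams stop at 3
  expect_true("g|b|surface|3|DISEASE_caused_by" %in% names(fv))
  expect_false(any(grepl("optic|nerve", names(fv))))
})

test_that("training requires both classes and separates separable data", {
  corp <- generate_corpus(generator_config(
    n_docs = 60, relations_per_doc = c(1, 1), frac_abstract_only = 0,
    frac_pattern = 0, frac_indication = 0, frac_negative = 1, seed = 702))
  insts <- corpus_instances(corp)
  labels <- vapply(insts, function(x) isTRUE(x$label), logical(1))
  expect_true(any(labels) && any(!labels))
  model <- train_relation_model(insts)
  pred <- predict_relations(model, insts)
  expect_equal(pred$labels, labels)  # training accuracy 1 on separable data
  pos <- insts[labels]
  expect_error(train_relation_model(pos), "each class")
  # duplicated dataset gives the same decision function
  model2 <- train_relation_model(c(insts, insts))
  expect_equal(decision_values(model2, insts[1:20]),
               decision_values(model, insts[1:20]), tolerance = 1e-6)
})

test_that("backend scores equal the stored-weight decision function", {
  corp <- generate_corpus(generator_config(n_docs = 40, seed = 703))
  insts <- corpus_instances(corp)
  model <- train_relation_model(insts)
  svm_scores <- decision_values(model, insts, method = "svm")
  w_scores <- decision_values(model, insts, method = "weights")
  expect_equal(svm_scores, w_scores, tolerance = 1e-8)
  expect_equal(predict_relations(model, list())$pairs,
               empty_candidates())
})

test_that("cross-validation stratifies folds and validates k", {
  corp <- generate_corpus(generator_config(
    n_docs = 40, relations_per_doc = c(1, 1), frac_abstract_only = 0,
    frac_negative = 1, seed = 704))
  insts <- corpus_instances(corp)
  labels <- vapply(insts, function(x) isTRUE(x$label), logical(1))
  k <- 5
  cv <- cross_validate(insts, k = k, seed = 1)
  expect_equal(nrow(cv$folds), k)
  expect_lte(diff(range(cv$folds$n_test)), 2)  # per-class sizes differ by <=1
  expect_equal(cv$f_score, mean(cv$folds$f_score))
  expect_error(cross_validate(insts, k = length(insts) + 1), "exceeds")
  expect_error(cross_validate(insts, k = sum(labels) + 1), "minority")
  # leave-one-out at the minority boundary runs
  small <- c(insts[which(labels)][1:5], insts[which(!labels)][1:5])
  expect_s3_class(cross_validate(small, k = 5, seed = 1), "cid_cv_report")
})

test_that("the learned weights recover a planted trigger rule", {
  corp <- generate_corpus(generator_config(
    n_docs = 120, relations_per_doc = c(1, 1), frac_abstract_only = 0,
    frac_pattern = 0, frac_indication = 0, frac_negative = 1, seed = 705))
  insts <- corpus_instances(corp)
  model <- train_relation_model(insts)
  top <- model$vocab[order(model$w, decreasing = TRUE)[1:40]]
  expect_true(any(grepl("^g\\|b\\|", top) & grepl("provok", top)))
})
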