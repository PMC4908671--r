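#' Run configuration for the combined system
#'
#' The three challenge configurations:
#'
#' * `"cascade"` (run 1): per document, the pattern matcher is tried first;
#'   if it finds any pair those pairs are the answer and the other
#'   components are not consulted; otherwise the classifier; otherwise the
#'   knowledge-base selector over abstract-level co-occurrences.
#' * `"union"` (run 2): all enabled components run and their outputs are
#'   merged.
#' * `"union_title_patterns"` (run 3): as union, but pattern matching sees
#'   only the title sentence.
#'
#' In every mode the final step removes pairs known as therapeutic
#' indications (`final_treatment_filter`). `ek_role` controls whether the
#' knowledge base contributes pairs (`"select"`), only filters
#' (`"filter"`), or both (default).
#'
#' @param mode One of `"cascade"`, `"union"`, `"union_title_patterns"`.
#' @param components Character subset of `c("patterns", "ml", "ek")`;
#'   cascade mode requires all three.
#' @param final_treatment_filter Apply the therapeutic filter last?
#' @param ek_role `"both"`, `"select"` or `"filter"`.
#' @return An object of class `cid_run_config`.
#' @export
run_config <- function(mode = c("union", "cascade", "union_title_patterns"),
                       components = c("patterns", "ml", "ek"),
                       final_treatment_filter = TRUE,
                       ek_role = c("both", "select", "filter")) {
  mode <- match.arg(mode)
  ek_role <- match.arg(ek_role)
  components <- match.arg(components, several.ok = TRUE)
  if (mode == "cascade" &&
      !all(c("patterns", "ml", "ek") %in% components)) {
    stop("config error: cascade mode requires patterns, ml and ek",
         call. = FALSE)
  }
  structure(list(mode = mode, components = components,
                 final_treatment_filter = final_treatment_filter,
                 ek_role = ek_role),
            class = "cid_run_config")
}

#' @export
print.cid_run_config <- function(x, ...) {
  cat("<cid_run_config> mode = ", x$mode, "; components = ",
      paste(x$components, collapse = "+"),
      "; treatment filter = ", x$final_treatment_filter,
      "; ek role = ", x$ek_role, "\n", sep = "")
  invisible(x)
}

.source_priority <- c(pattern = 1, ml = 2, kb = 3, cooccurrence = 4)

dedup_by_priority <- function(pairs) {
  if (!nrow(pairs)) return(pairs)
  pairs$.prio <- .source_priority[pairs$source]
  pairs <- pairs[order(pairs$pmid, pairs$chemical_id, pairs$disease_id,
                       pairs$.prio), , drop = FALSE]
  pairs <- dplyr::distinct(pairs, .data$pmid, .data$chemical_id,
                           .data$disease_id, .keep_all = TRUE)
  pairs$.prio <- NULL
  pairs
}

#' Run the combined CID detection pipeline
#'
#' Applies NER post-processing, then the components enabled in the run
#' configuration (pattern matcher, relation classifier, knowledge-base
#' selector), combines them per the configured mode, and finally removes
#' known therapeutic indications. Output is one row per predicted
#' (pmid, chemical id, disease id), deduplicated keeping the
#' highest-priority source tag (pattern > ml > kb).
#'
#' @param docs A `cid_document` or list of them.
#' @param model A `cid_model`, required when the `ml` component is enabled.
#' @param kb A `cid_kb`, required when `ek` is enabled or the treatment
#'   filter is on.
#' @param cfg A [run_config()].
#' @param filter_cfg NER post-processing settings ([filter_config()]).
#' @param patterns Pattern tibble for the matcher.
#' @param max_gap Token-gap tolerance for pattern matching.
#' @param verbose Log per-stage candidate counts?
#' @return A candidate tibble of predicted pairs.
#' @export
run_pipeline <- function(docs, model = NULL, kb = NULL,
                         cfg = run_config(),
                         filter_cfg = filter_config(),
                         patterns = default_cid_patterns(),
                         max_gap = 3, verbose = FALSE) {
  if (inherits(docs, "cid_document")) docs <- list(docs)
  if ("ml" %in% cfg$components && is.null(model)) {
    stop("config error: ml component enabled but no model given",
         call. = FALSE)
  }
  if ((("ek" %in% cfg$components && cfg$ek_role != "filter") ||
       cfg$final_treatment_filter) && is.null(kb)) {
    stop("config error: knowledge base required by this configuration",
         call. = FALSE)
  }
  title_only <- cfg$mode == "union_title_patterns"
  per_doc <- lapply(docs, function(doc) {
    sents <- preprocess_document(doc, filter_cfg)
    pat <- if ("patterns" %in% cfg$components) {
      match_patterns(sents, patterns, title_only = title_only,
                     max_gap = max_gap)
    } else empty_candidates()
    ml <- if ("ml" %in% cfg$components) {
      inst <- build_instances(sents, sentence_cooccurrences(sents))
      predict_relations(model, inst)$pairs
    } else empty_candidates()
    ek <- if ("ek" %in% cfg$components && cfg$ek_role != "filter") {
      select_known_se(abstract_cooccurrences(sents), kb)
    } else empty_candidates()
    if (cfg$mode == "cascade") {
      if (nrow(pat)) pat else if (nrow(ml)) ml else ek
    } else {
      dplyr::bind_rows(pat, ml, ek)
    }
  })
  res <- dedup_by_priority(dplyr::bind_rows(per_doc, empty_candidates()))
  n_before <- nrow(res)
  if (cfg$final_treatment_filter) res <- treatment_filtering(res, kb)
  if (verbose) {
    message("combined candidates: ", n_before,
            " in, ", nrow(res), " out after treatment filtering")
  }
  candidate_order(res)
}

#' Final treatment filtering
#'
#' Removes predicted pairs annotated as the drug's therapeutic indication
#' in the knowledge base; delegates to [filter_therapeutic()].
#'
#' @param results Candidate tibble.
#' @param kb A `cid_kb`.
#' @return The filtered candidate tibble.
#' @export
treatment_filtering <- function(results, kb) filter_therapeutic(results, kb)

#' Write predicted pairs as BC5-style relation lines
#'
#' @param pairs Candidate tibble.
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_relations <- function(pairs, path) {
  lines <- paste(pairs$pmid, "CID", pairs$chemical_id, pairs$disease_id,
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
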