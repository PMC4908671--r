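#' Load a chemical-disease knowledge base
#'
#' Reads a 4-column TSV (header required: `chemical_id`, `disease_id`,
#' `label`, `provenance`) of known chemical-disease associations labeled
#' `therapeutic` (the chemical treats the disease) or `side_effect` (the
#' chemical causes it). Exact duplicates are collapsed; a pair carrying
#' both labels is contradictory and the whole pair is dropped at load time
#' (with a message), so the therapeutic and side-effect sets are disjoint
#' by construction.
#'
#' Disease identifiers in a foreign vocabulary can be mapped to the corpus
#' vocabulary via an optional 2-column mapping table (`source_id`,
#' `mesh_id`); unmapped identifiers are kept as-is and simply never match.
#'
#' @param x Path to the TSV, or a data frame already in that shape.
#' @param mapping Optional mapping data frame / TSV path.
#' @return An object of class `cid_kb`: `entries` tibble plus load counters
#'   (`n_therapeutic`, `n_side_effect`, `n_dual_dropped`, `n_duplicates`).
#' @export
load_kb <- function(x, mapping = NULL) {
  if (is.character(x)) {
    x <- utils::read.delim(x, sep = "\t", header = TRUE,
                           colClasses = "character")
  }
  x <- tibble::as_tibble(x)
  need <- c("chemical_id", "disease_id", "label", "provenance")
  if (!all(need %in% names(x))) {
    stop("knowledge base must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  bad <- which(!x$label %in% c("therapeutic", "side_effect"))
  if (length(bad)) {
    stop("load error at row ", bad[1], ": unknown label ",
         dQuote(x$label[bad[1]]), call. = FALSE)
  }
  if (!is.null(mapping)) {
    if (is.character(mapping)) {
      mapping <- utils::read.delim(mapping, sep = "\t", header = TRUE,
                                   colClasses = "character")
    }
    i <- match(x$disease_id, mapping$source_id)
    x$disease_id[!is.na(i)] <- mapping$mesh_id[i[!is.na(i)]]
  }
  n_in <- nrow(x)
  x <- dplyr::distinct(x, .data$chemical_id, .data$disease_id, .data$label,
                       .keep_all = TRUE)
  n_dup <- n_in - nrow(x)
  key <- paste(x$chemical_id, x$disease_id, sep = "\r")
  dual <- names(which(tapply(x$label, key, function(l)
    length(unique(l)) > 1)))
  n_dual <- sum(key %in% dual)
  if (n_dual) {
    message("dropped ", length(dual),
            " pair(s) labeled both therapeutic and side_effect (",
            n_dual, " rows)")
  }
  x <- x[!key %in% dual, , drop = FALSE]
  structure(list(entries = x,
                 n_therapeutic = sum(x$label == "therapeutic"),
                 n_side_effect = sum(x$label == "side_effect"),
                 n_dual_dropped = length(dual),
                 n_duplicates = n_dup),
            class = "cid_kb")
}

#' @export
print.cid_kb <- function(x, ...) {
  cat("<cid_kb> ", x$n_therapeutic, " therapeutic, ", x$n_side_effect,
      " side-effect associations",
      if (x$n_dual_dropped) paste0(" (", x$n_dual_dropped,
                                   " dual-labeled pairs dropped)"),
      "\n", sep = "")
  invisible(x)
}

kb_keys <- function(kb, label) {
  e <- kb$entries[kb$entries$label == label, , drop = FALSE]
  paste(e$chemical_id, e$disease_id, sep = "\r")
}

#' Remove known therapeutic indications
#'
#' Drops candidate pairs whose identifiers match a therapeutic entry of the
#' knowledge base — a drug known to treat a disease is unlikely to be
#' reported as causing it. The final filtering step of every run
#' configuration. Monotone, idempotent, order-preserving.
#'
#' @param pairs Candidate tibble.
#' @param kb A `cid_kb`.
#' @return The surviving candidate tibble.
#' @export
filter_therapeutic <- function(pairs, kb) {
  if (!nrow(pairs)) return(pairs)
  key <- paste(pairs$chemical_id, pairs$disease_id, sep = "\r")
  pairs[!key %in% kb_keys(kb, "therapeutic"), , drop = FALSE]
}

#' Select known side-effect pairs
#'
#' Keeps only candidate pairs with a side-effect entry in the knowledge
#' base; survivors are tagged `source = "kb"`. The abstract-level detection
#' mode of the expert-knowledge approach. Because dual-labeled pairs are
#' excluded at load time, the output is disjoint from the therapeutic set,
#' so applying [filter_therapeutic()] afterwards changes nothing.
#'
#' @inheritParams filter_therapeutic
#' @return The surviving candidate tibble, `source = "kb"`.
#' @export
select_known_se <- function(pairs, kb) {
  if (!nrow(pairs)) return(pairs)
  key <- paste(pairs$chemical_id, pairs$disease_id, sep = "\r")
  out <- pairs[key %in% kb_keys(kb, "side_effect"), , drop = FALSE]
  if (nrow(out)) out$source <- "kb"
  out
}
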