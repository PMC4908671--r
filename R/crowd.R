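#' Aggregate redundant crowd judgments into relation labels
#'
#' Each crowd verification task is one sentence plus one chemical-disease
#' concept pair, judged true/false by a fixed number of workers (redundancy
#' 5 in the reference design). The aggregate label is true exactly when at
#' least `threshold` workers voted true.
#'
#' @param votes A long vote table with columns `task_id` and `vote`
#'   (logical), typically also `pmid`, `chemical_id`, `disease_id`,
#'   `sentence`, `worker_id`.
#' @param threshold Minimum number of true votes for a true label.
#' @param redundancy Required number of votes per task; a task with any
#'   other count raises an aggregation error.
#' @return A tibble, one row per task: identifying columns, `n_true`,
#'   `n_votes`, `label`, `unanimous_false`.
#' @export
aggregate_votes <- function(votes, threshold = 3, redundancy = 5) {
  votes <- tibble::as_tibble(votes)
  stopifnot(all(c("task_id", "vote") %in% names(votes)))
  keep <- intersect(c("task_id", "pmid", "chemical_id", "disease_id",
                      "sentence", "gold_label"), names(votes))
  agg <- dplyr::summarise(
    dplyr::group_by(votes, dplyr::across(dplyr::all_of(keep))),
    n_true = sum(.data$vote), n_votes = dplyr::n(), .groups = "drop")
  short <- which(agg$n_votes != redundancy)
  if (length(short)) {
    stop("aggregation error: task ", agg$task_id[short[1]], " has ",
         agg$n_votes[short[1]], " votes, expected ", redundancy,
         call. = FALSE)
  }
  agg$label <- agg$n_true >= threshold
  agg$unanimous_false <- agg$n_true == 0
  agg[order(agg$task_id), , drop = FALSE]
}

#' Crowd corpus summary statistics
#'
#' @param agg Aggregated task tibble from [aggregate_votes()].
#' @return A list: `n_tasks`, `n_true`, `n_false`, `pct_true` (fraction of
#'   tasks reaching the vote threshold, percent), `pct_unanimous_false`
#'   (percent of tasks with zero true votes).
#' @export
corpus_statistics <- function(agg) {
  list(n_tasks = nrow(agg),
       n_true = sum(agg$label),
       n_false = sum(!agg$label),
       pct_true = 100 * mean(agg$label),
       pct_unanimous_false = 100 * mean(agg$unanimous_false))
}

#' Balance a crowd-labeled corpus for training
#'
#' Keeps every positive task and downsamples negatives without replacement
#' to `round(n_pos * ratio)` (the reference corpus used 698 positives and
#' 930 sampled negatives, ratio 930/698). Deterministic given the seed. If
#' fewer negatives exist than requested, all are kept with a warning.
#'
#' @param agg Aggregated task tibble.
#' @param ratio Target negative:positive ratio.
#' @param seed Integer seed for the negative sample.
#' @return The balanced task tibble (positives first, then sampled
#'   negatives in draw order).
#' @export
balance_corpus <- function(agg, ratio = 930 / 698, seed = 42) {
  pos <- agg[agg$label, , drop = FALSE]
  neg <- agg[!agg$label, , drop = FALSE]
  n_want <- round(nrow(pos) * ratio)
  if (n_want > nrow(neg)) {
    warning("requested ", n_want, " negatives but only ", nrow(neg),
            " available; keeping all", call. = FALSE)
    n_want <- nrow(neg)
  }
  set.seed(seed)
  take <- sample(nrow(neg), n_want)
  dplyr::bind_rows(pos, neg[take, , drop = FALSE])
}

#' Simulate crowd workers on gold-labeled tasks
#'
#' A statistical stand-in for the microtask platform: each of `n_workers`
#' votes equals the task's gold label, flipped independently with
#' probability `1 - worker_accuracy`. The accuracy parameter subsumes the
#' platform's quiz gating (workers below a 70% accuracy gate would be
#' excluded in the real pipeline).
#'
#' @param tasks Tibble with a `task_id` column and a logical `gold_label`
#'   column (other columns are carried through).
#' @param worker_accuracy Per-vote probability of agreeing with gold; must
#'   exceed 0.5 (else majority aggregation is uninformative) and be at most
#'   1.
#' @param n_workers Votes per task.
#' @param seed Integer seed.
#' @return A long vote tibble (`task_id`, carried columns, `worker_id`,
#'   `vote`).
#' @export
simulate_workers <- function(tasks, worker_accuracy = 0.9, n_workers = 5,
                             seed = 42) {
  stopifnot(worker_accuracy > 0.5, worker_accuracy <= 1)
  tasks <- tibble::as_tibble(tasks)
  set.seed(seed)
  n <- nrow(tasks)
  long <- tasks[rep(seq_len(n), each = n_workers), , drop = FALSE]
  long$worker_id <- rep(seq_len(n_workers), times = n)
  flip <- stats::runif(n * n_workers) > worker_accuracy
  long$vote <- xor(long$gold_label, flip)
  long
}

#' Closed-form accuracy of threshold aggregation
#'
#' Probability that majority-threshold aggregation of `n` independent votes
#' with per-vote accuracy `p` recovers the gold label:
#' `sum_{k >= threshold} C(n, k) p^k (1 - p)^(n - k)` (the same value for
#' gold-true and gold-false tasks by symmetry of the flip model).
#'
#' @param p Per-vote accuracy.
#' @param n Votes per task.
#' @param threshold Votes needed for a true call.
#' @return The aggregated accuracy.
#' @export
aggregated_accuracy <- function(p, n = 5, threshold = 3) {
  k <- threshold:n
  sum(choose(n, k) * p^k * (1 - p)^(n - k))
}

#' Read a crowd vote table
#'
#' Reads the long-format vote TSV used throughout the package (columns
#' `task_id`, `pmid`, `chemical_id`, `disease_id`, `sentence`, `worker_id`,
#' `vote`; `vote` as logical or 0/1). Externally released vote data must be
#' converted to this layout first.
#'
#' @param path TSV file path.
#' @return A vote tibble.
#' @export
read_crowd_votes <- function(path) {
  if (!nzchar(path) || !file.exists(path)) {
    stop("vote table not found: ", dQuote(path), call. = FALSE)
  }
  x <- tibble::as_tibble(utils::read.delim(path, sep = "\t", header = TRUE))
  if (!all(c("task_id", "vote") %in% names(x))) {
    stop("vote table must have task_id and vote columns", call. = FALSE)
  }
  x$vote <- as.logical(x$vote)
  x
}
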