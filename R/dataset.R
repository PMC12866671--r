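# Labelled association datasets: negative sampling (2:1 by default, sampled
# once and held fixed) and stratified 0.6/0.2/0.2 train/validation/test
# splitting with no pair appearing in more than one split.

#' Sample negative ncRNA-drug pairs
#'
#' Draws `ratio x |positives|` pairs uniformly without replacement from the
#' unknown pairs (the full ncRNA x drug product minus the positives).
#' Negatives are sampled once, before splitting, and held fixed.
#'
#' @param positives Data.frame with columns `source_id` (ncRNA) and
#'   `target_id` (drug), e.g. a `pair_list`.
#' @param ncrna_universe,drug_universe Character vectors of candidate ids.
#' @param ratio Negatives per positive (default 2).
#' @param seed RNG seed; same seed, same negatives.
#' @return Data.frame `source_id`, `target_id` of sampled negative pairs.
#' @export
sample_negatives <- function(positives, ncrna_universe, drug_universe,
                             ratio = 2, seed = 1) {
  n_n <- length(ncrna_universe); n_d <- length(drug_universe)
  pos_lin <- (match(positives$source_id, ncrna_universe) - 1) * n_d +
    match(positives$target_id, drug_universe)
  assert_that(!anyNA(pos_lin), "positive pair outside the given universes")
  n_need <- ratio * nrow(positives)
  n_unknown <- n_n * n_d - length(unique(pos_lin))
  if (n_unknown < n_need) {
    stop("not enough unknown pairs to sample ", n_need, " negatives",
         call. = FALSE)
  }
  unknown <- setdiff(seq_len(n_n * n_d), pos_lin)
  pick <- with_seed(seed, sample(unknown, n_need))
  data.frame(source_id = ncrna_universe[(pick - 1) %/% n_d + 1],
             target_id = drug_universe[(pick - 1) %% n_d + 1],
             stringsAsFactors = FALSE)
}

#' Stratified train/validation/test split
#'
#' Splits labelled pairs stratified by label.  Split sizes use the rule:
#' floor every split's share, assign the remainder to train.  No pair
#' appears in more than one split; reproducible given `seed`.
#'
#' @param pairs Data.frame with columns `ncrna_id`, `drug_id`, `label`.
#' @param fractions Numeric length-3 `(train, val, test)` summing to 1.
#' @param seed RNG seed.
#' @param task `"LD"` or `"MD"`, recorded on the result.
#' @return An `association_dataset`: the input data.frame plus a `split`
#'   column in `{train, val, test}` and a `task` attribute.
#' @export
split_dataset <- function(pairs, fractions = c(0.6, 0.2, 0.2), seed = 1,
                          task = c("LD", "MD")) {
  task <- match.arg(task)
  assert_that(abs(sum(fractions) - 1) < 1e-8, "fractions must sum to 1")
  assert_that(all(pairs$label %in% c(0, 1)), "labels must be 0/1")
  key <- paste(pairs$ncrna_id, pairs$drug_id)
  assert_that(!anyDuplicated(key), "duplicate pair in dataset")
  pairs$split <- NA_character_
  for (lab in unique(pairs$label)) {
    rows <- which(pairs$label == lab)
    n <- length(rows)
    n_val <- floor(fractions[2] * n)
    n_test <- floor(fractions[3] * n)
    n_train <- n - n_val - n_test
    if (min(n_train, n_val, n_test) < 1) {
      stop("label class ", lab, " too small (", n,
           ") to populate all three splits", call. = FALSE)
    }
    ord <- with_seed(child_seed(seed, lab + 101), sample(rows))
    pairs$split[ord[seq_len(n_train)]] <- "train"
    pairs$split[ord[n_train + seq_len(n_val)]] <- "val"
    pairs$split[ord[n_train + n_val + seq_len(n_test)]] <- "test"
  }
  attr(pairs, "task") <- task
  class(pairs) <- c("association_dataset", "data.frame")
  pairs
}

#' Build a labelled, split association dataset from positives
#'
#' Convenience wrapper: samples fixed negatives via [sample_negatives()],
#' binds labels, and splits via [split_dataset()].
#'
#' @param positives Data.frame `source_id` (ncRNA), `target_id` (drug).
#' @param ncrna_universe,drug_universe Candidate id vectors.
#' @param ratio Negative:positive ratio (default 2).
#' @param fractions Split fractions (default `c(0.6, 0.2, 0.2)`).
#' @param seed RNG seed (negatives and split derive sub-seeds from it).
#' @param task `"LD"` or `"MD"`.
#' @return An `association_dataset`.
#' @export
build_dataset <- function(positives, ncrna_universe, drug_universe,
                          ratio = 2, fractions = c(0.6, 0.2, 0.2), seed = 1,
                          task = c("LD", "MD")) {
  task <- match.arg(task)
  negs <- sample_negatives(positives, ncrna_universe, drug_universe,
                           ratio = ratio, seed = child_seed(seed, 7))
  all_pairs <- data.frame(
    ncrna_id = c(positives$source_id, negs$source_id),
    drug_id = c(positives$target_id, negs$target_id),
    label = c(rep(1L, nrow(positives)), rep(0L, nrow(negs))),
    stringsAsFactors = FALSE)
  split_dataset(all_pairs, fractions, seed = child_seed(seed, 8), task = task)
}

#' Validate association-dataset invariants
#'
#' Positives and negatives disjoint, one split per pair, per-split negative
#' counts about twice the positives (when `ratio = 2`), split fractions
#' near the requested shares.
#'
#' @param ds An `association_dataset`.
#' @export
validate_dataset <- function(ds) {
  assert_that(inherits(ds, "association_dataset"), "not an association_dataset")
  key <- paste(ds$ncrna_id, ds$drug_id)
  assert_that(!anyDuplicated(key), "pair appears more than once")
  assert_that(all(ds$split %in% c("train", "val", "test")), "bad split value")
  invisible(TRUE)
}
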