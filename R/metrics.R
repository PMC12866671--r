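# Ranking metrics (AUC, AUPR, Precision/Recall/NDCG at k), standard-split
# evaluation and leave-one-entity-out cold-start protocols.

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a uniformly chosen
#' positive outscores a uniformly chosen negative, ties counted 1/2.
#'
#' @param scores Numeric scores (any monotone scale).
#' @param labels 0/1 labels.
#' @return Scalar in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  assert_that(length(scores) == length(labels), "length mismatch")
  assert_that(all(labels %in% c(0, 1)), "labels must be 0/1")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  assert_that(n_pos > 0 && n_neg > 0, "auc needs both classes")
  r <- rank(scores)                      # average ranks handle ties as 1/2
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Area of the precision-recall step curve over all score thresholds
#' (equal scores are grouped into one threshold).
#'
#' @inheritParams auc
#' @return Scalar in `[0, 1]`.
#' @export
aupr <- function(scores, labels) {
  assert_that(length(scores) == length(labels), "length mismatch")
  assert_that(all(labels %in% c(0, 1)), "labels must be 0/1")
  n_pos <- sum(labels == 1)
  assert_that(n_pos > 0, "aupr needs at least one positive")
  ord <- order(-scores)
  s <- scores[ord]; y <- labels[ord]
  # group tied scores: cumulative TP/FP at each distinct threshold
  grp_end <- which(!duplicated(s, fromLast = TRUE))   # last index of each group
  tp <- cumsum(y)[grp_end]
  fp <- cumsum(1 - y)[grp_end]
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

order_by_score <- function(scores) order(-scores, seq_along(scores))

#' Precision within the top-k predictions
#'
#' Ties are broken by stable input order (documented, deterministic).
#'
#' @inheritParams auc
#' @param k Cutoff, `1 <= k <= length(scores)`.
#' @return `(# positives in top k) / k`.
#' @export
precision_at_k <- function(scores, labels, k) {
  assert_that(k >= 1 && k <= length(scores), "k out of range")
  top <- order_by_score(scores)[seq_len(k)]
  sum(labels[top] == 1) / k
}

#' Recall within the top-k predictions
#'
#' @inheritParams precision_at_k
#' @return `(# positives in top k) / (# positives)`.
#' @export
recall_at_k <- function(scores, labels, k) {
  assert_that(k >= 1 && k <= length(scores), "k out of range")
  n_pos <- sum(labels == 1)
  assert_that(n_pos > 0, "recall_at_k needs at least one positive")
  top <- order_by_score(scores)[seq_len(k)]
  sum(labels[top] == 1) / n_pos
}

#' Normalized discounted cumulative gain at k
#'
#' Binary relevance: `DCG = sum_i rel_i / log2(i + 1)` over the top k,
#' normalized by the DCG of the ideal ordering over the same k.
#'
#' @inheritParams precision_at_k
#' @return Scalar in `[0, 1]`.
#' @export
ndcg_at_k <- function(scores, labels, k) {
  assert_that(k >= 1 && k <= length(scores), "k out of range")
  n_pos <- sum(labels == 1)
  assert_that(n_pos > 0, "ndcg_at_k needs at least one positive")
  top <- order_by_score(scores)[seq_len(k)]
  dcg <- sum(labels[top] / log2(seq_len(k) + 1))
  idcg <- sum(1 / log2(seq_len(min(k, n_pos)) + 1))
  dcg / idcg
}

#' Evaluate a fitted model on one split
#'
#' Scores every pair of the chosen split with the frozen model and computes
#' AUC, AUPR and the three top-k metrics for every k in `k_list`.
#'
#' @param model A fitted `ncd_model`.
#' @param split `"train"`, `"val"` or `"test"` (default).
#' @param k_list Integer cutoffs (default `c(10, 30)`); values above the
#'   split size are dropped.
#' @return A `metrics_report` list: `auc`, `aupr`, `precision_at_k`,
#'   `recall_at_k`, `ndcg_at_k` (named by k), `n_pos`, `n_neg`.
#' @export
evaluate_split <- function(model, split = "test", k_list = c(10, 30)) {
  ds <- model$dataset[model$dataset$split == split, ]
  assert_that(nrow(ds) > 0, paste("empty split:", split))
  scores <- predict(model, ds)
  report_metrics(scores, ds$label, k_list)
}

report_metrics <- function(scores, labels, k_list = c(10, 30)) {
  k_list <- k_list[k_list <= length(scores)]
  rep <- list(auc = auc(scores, labels), aupr = aupr(scores, labels),
              precision_at_k = list(), recall_at_k = list(),
              ndcg_at_k = list(),
              n_pos = sum(labels == 1), n_neg = sum(labels == 0))
  for (k in k_list) {
    kn <- as.character(k)
    rep$precision_at_k[[kn]] <- precision_at_k(scores, labels, k)
    rep$recall_at_k[[kn]] <- recall_at_k(scores, labels, k)
    rep$ndcg_at_k[[kn]] <- ndcg_at_k(scores, labels, k)
  }
  class(rep) <- "metrics_report"
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("AUC %.4f | AUPR %.4f  (%d pos, %d neg)\n",
              x$auc, x$aupr, x$n_pos, x$n_neg))
  for (k in names(x$precision_at_k)) {
    cat(sprintf("  @%s: precision %.4f  recall %.4f  ndcg %.4f\n", k,
                x$precision_at_k[[k]], x$recall_at_k[[k]], x$ndcg_at_k[[k]]))
  }
  invisible(x)
}

#' Leave-one-entity-out cold-start evaluation
#'
#' Removes every target-relation association of one held-out ncRNA or drug
#' from training, refits the model, then ranks the entity against all
#' candidate partners: its true partners are the positives and all
#' remaining partners with no known association to the entity are the
#' negatives.
#'
#' @param network A `hetero_network`.
#' @param associations Positive `pair_list` for the task (columns
#'   `source_id` = ncRNA, `target_id` = drug).
#' @param entity_id Id of the held-out ncRNA or drug.
#' @param config A [train_config()].
#' @param k Ranking cutoff (default 30).
#' @return A `loo_result` list: entity, entity type, `auc`, `aupr`,
#'   `precision_at_k`, `recall_at_k`, `ndcg_at_k`, `n_candidates`, `n_pos`.
#' @export
leave_one_out <- function(network, associations, entity_id,
                          config = train_config(), k = 30) {
  nt <- ncrna_type_for_task(config$task)
  ent_type <- if (entity_id %in% network$nodes[[nt]]) {
    nt
  } else if (entity_id %in% network$nodes[["drug"]]) {
    "drug"
  } else {
    stop("entity ", entity_id, " not found in the network", call. = FALSE)
  }
  col <- if (ent_type == "drug") "target_id" else "source_id"
  held <- associations[associations[[col]] == entity_id, ]
  rest <- associations[associations[[col]] != entity_id, ]
  assert_that(nrow(held) >= 1, "held-out entity has no positive association")

  ncrna_rest <- setdiff(network$nodes[[nt]],
                        if (ent_type != "drug") entity_id else character(0))
  drug_rest <- setdiff(network$nodes[["drug"]],
                       if (ent_type == "drug") entity_id else character(0))
  ds <- build_dataset(rest, ncrna_rest, drug_rest,
                      ratio = config$negative_ratio,
                      fractions = config$fractions,
                      seed = config$seed, task = config$task)
  model <- train_model(network, ds, config)

  partners <- if (ent_type == "drug") network$nodes[[nt]] else network$nodes[["drug"]]
  pos_partners <- if (ent_type == "drug") held$source_id else held$target_id
  cand <- data.frame(
    ncrna_id = if (ent_type == "drug") partners else entity_id,
    drug_id = if (ent_type == "drug") entity_id else partners,
    stringsAsFactors = FALSE)
  labels <- as.integer(partners %in% pos_partners)
  scores <- predict(model, cand)
  k_eff <- min(k, length(partners))
  structure(list(
    entity_id = entity_id, entity_type = ent_type,
    auc = auc(scores, labels), aupr = aupr(scores, labels),
    precision_at_k = precision_at_k(scores, labels, k_eff),
    recall_at_k = recall_at_k(scores, labels, k_eff),
    ndcg_at_k = ndcg_at_k(scores, labels, k_eff),
    k = k_eff, n_candidates = length(partners), n_pos = sum(labels),
    model = model), class = "loo_result")
}
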