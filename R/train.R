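# Full-graph training: Adam on the encoder + decoder under mean binary
# cross-entropy.  Leakage control: only training-split positives of the
# target association relation are present in the message-passing graph;
# validation/test association edges never enter it.

#' Training configuration
#'
#' Defaults follow the grid-search optimum reported for the lncRNA-drug
#' task: learning rate 5e-4, 100 epochs, hidden dimension 64, `min`
#' aggregation, 2:1 negative sampling, 0.6/0.2/0.2 splits.
#'
#' @param learning_rate Adam step size (default 5e-4).
#' @param epochs Training epochs (default 100).
#' @param hidden_dim Hidden channel dimension (default 64).
#' @param aggregation Message pooling strategy (default `"min"`).
#' @param negative_ratio Negatives per positive (default 2).
#' @param fractions Train/val/test fractions (default 0.6/0.2/0.2).
#' @param layers Encoder depth (default 2).
#' @param leaky_slope LeakyReLU negative slope (default 0.2).
#' @param task `"LD"` or `"MD"`.
#' @param seed Master seed; all run randomness derives from it.
#' @param include_eval_edges Permissive variant: keep val/test association
#'   edges in the message-passing graph (default `FALSE`, the leakage-safe
#'   reading).
#' @param adam_beta1,adam_beta2,adam_eps Adam moment constants.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 5e-4, epochs = 100, hidden_dim = 64,
                         aggregation = c("min", "mean", "sum", "max"),
                         negative_ratio = 2, fractions = c(0.6, 0.2, 0.2),
                         layers = 2, leaky_slope = 0.2,
                         task = c("LD", "MD"), seed = 1,
                         include_eval_edges = FALSE,
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         adam_eps = 1e-8) {
  assert_that(epochs >= 1, "epochs must be >= 1")
  assert_that(negative_ratio >= 1, "negative_ratio must be >= 1")
  assert_that(abs(sum(fractions) - 1) < 1e-8, "fractions must sum to 1")
  structure(list(
    learning_rate = learning_rate, epochs = epochs, hidden_dim = hidden_dim,
    aggregation = match.arg(aggregation), negative_ratio = negative_ratio,
    fractions = fractions, layers = layers, leaky_slope = leaky_slope,
    task = match.arg(task), seed = seed,
    include_eval_edges = include_eval_edges,
    adam_beta1 = adam_beta1, adam_beta2 = adam_beta2, adam_eps = adam_eps
  ), class = "train_config")
}

target_relation_for_task <- function(task) if (task == "LD") "ld" else "md"

# Replace the target association relation's edges by exactly the
# training-split positives (unless the permissive variant is requested).
build_training_network <- function(network, dataset, config) {
  rel <- target_relation_for_task(config$task)
  net <- network
  if (!isTRUE(config$include_eval_edges)) {
    train_pos <- dataset[dataset$split == "train" & dataset$label == 1, ]
    net$edges[[rel]] <- canonicalize_edges(
      data.frame(id_a = train_pos$ncrna_id, id_b = train_pos$drug_id,
                 score = 1, stringsAsFactors = FALSE),
      intra = FALSE)
    # leakage guard: graph target edges == training positives, as multisets
    g_key <- sort(paste(net$edges[[rel]]$id_a, net$edges[[rel]]$id_b))
    t_key <- sort(unique(paste(train_pos$ncrna_id, train_pos$drug_id)))
    assert_that(identical(g_key, t_key),
                "leakage guard: graph target edges differ from training positives")
  }
  net
}

adam_step <- function(params, grads, state, lr, b1, b2, eps, t) {
  state$m <- tree_map2(function(m, g) b1 * m + (1 - b1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) b2 * v + (1 - b2) * g^2, state$v, grads)
  corr1 <- 1 - b1^t; corr2 <- 1 - b2^t
  upd <- tree_map2(function(m, v) (m / corr1) / (sqrt(v / corr2) + eps),
                   state$m, state$v)
  params <- tree_map2(function(p, u) p - lr * u, params, upd)
  list(params = params, state = state)
}

pairs_to_idx <- function(ds, prep, task) {
  nt <- ncrna_type_for_task(task)
  idx_n <- match(ds$ncrna_id, prep$ids[[nt]])
  idx_d <- match(ds$drug_id, prep$ids[["drug"]])
  assert_that(!anyNA(idx_n) && !anyNA(idx_d),
              "dataset pair does not resolve in network")
  cbind(idx_n, idx_d)
}

#' Train the heterogeneous graph link-prediction model
#'
#' Fits the relation-type-aware encoder and the MLP edge decoder by
#' full-batch Adam under mean binary cross-entropy (logistic link) on the
#' training split.  Validation AUC/AUPR are recorded each epoch; the
#' returned model carries the parameters of the epoch with the best
#' validation AUC (ties to the earliest epoch).  All randomness derives
#' from `config$seed`.
#'
#' @param network A `hetero_network` containing all candidate nodes.
#' @param dataset An `association_dataset` (see [build_dataset()]).
#' @param config A [train_config()].
#' @return An object of class `ncd_model`: list with `params` (best),
#'   `final_params`, `config`, `network` (the training graph), `dataset`,
#'   `history` (per-epoch loss and validation AUC/AUPR), `best_epoch`.
#' @export
train_model <- function(network, dataset, config = train_config()) {
  validate_dataset(dataset)
  assert_that(identical(attr(dataset, "task"), config$task),
              "dataset task does not match config task")
  net <- build_training_network(network, dataset, config)
  prep <- compile_network(net)
  enc_cfg <- encoder_config(hidden_dim = config$hidden_dim,
                            layers = config$layers,
                            aggregation = config$aggregation,
                            leaky_slope = config$leaky_slope,
                            task = config$task,
                            seed = child_seed(config$seed, 1))
  params <- init_model_params(net, enc_cfg)

  tr <- dataset[dataset$split == "train", ]
  va <- dataset[dataset$split == "val", ]
  idx_tr <- pairs_to_idx(tr, prep, config$task)
  idx_va <- if (nrow(va) > 0) pairs_to_idx(va, prep, config$task)
  y_tr <- tr$label
  n_tr <- nrow(tr)

  state <- list(m = tree_zero_like(params), v = tree_zero_like(params))
  history <- data.frame(epoch = seq_len(config$epochs), loss = NA_real_,
                        val_auc = NA_real_, val_aupr = NA_real_)
  best <- list(auc = -Inf, epoch = NA_integer_, params = params)

  for (ep in seq_len(config$epochs)) {
    fwd <- model_forward(prep, params, enc_cfg, idx_tr, want_cache = TRUE)
    loss <- bce_loss(fwd$logits, y_tr)
    if (!is.finite(loss)) {
      stop("training diverged (non-finite loss) at epoch ", ep, call. = FALSE)
    }
    dlogits <- (sigmoid(fwd$logits) - y_tr) / n_tr
    grads <- model_backward(prep, params, enc_cfg, fwd, idx_tr, dlogits)
    if (config$learning_rate > 0) {
      st <- adam_step(params, grads, state, config$learning_rate,
                      config$adam_beta1, config$adam_beta2, config$adam_eps, ep)
      params <- st$params
      state <- st$state
    }
    history$loss[ep] <- loss
    if (!is.null(idx_va) && length(unique(va$label)) == 2) {
      sc <- model_forward(prep, params, enc_cfg, idx_va)$logits
      history$val_auc[ep] <- auc(sc, va$label)
      history$val_aupr[ep] <- aupr(sc, va$label)
      if (history$val_auc[ep] > best$auc) {
        best <- list(auc = history$val_auc[ep], epoch = ep, params = params)
      }
    } else {
      best <- list(auc = NA_real_, epoch = ep, params = params)
    }
  }
  structure(list(params = best$params, final_params = params,
                 config = config, enc_config = enc_cfg,
                 network = net, dataset = dataset,
                 history = history, best_epoch = best$epoch),
            class = "ncd_model")
}

#' Predict association logits for ncRNA-drug pairs
#'
#' Scores pairs with the frozen fitted model, using the training
#' message-passing graph (validation/test association edges are not part
#' of it).
#'
#' @param object A fitted `ncd_model`.
#' @param pairs Data.frame with columns `ncrna_id` and `drug_id` (defaults
#'   to the model's full dataset).
#' @param type `"link"` returns logits, `"response"` sigmoid probabilities.
#' @param ... Unused.
#' @return Numeric vector, one score per pair.
#' @export
predict.ncd_model <- function(object, pairs = NULL,
                              type = c("link", "response"), ...) {
  type <- match.arg(type)
  pairs <- pairs %||% object$dataset
  prep <- compile_network(object$network)
  idx <- pairs_to_idx(pairs, prep, object$config$task)
  logits <- model_forward(prep, object$params, object$enc_config, idx)$logits
  if (type == "response") sigmoid(logits) else logits
}

#' @export
print.ncd_model <- function(x, ...) {
  cat("ncRNA-drug heterogeneous graph link-prediction model\n")
  cat(sprintf("  task %s | hidden %d | layers %d | aggregation %s\n",
              x$config$task, x$config$hidden_dim, x$config$layers,
              x$config$aggregation))
  cat(sprintf("  trained %d epochs (lr %g), best validation AUC %.4f at epoch %s\n",
              x$config$epochs, x$config$learning_rate,
              max(x$history$val_auc, na.rm = TRUE),
              x$best_epoch))
  invisible(x)
}

#' @export
summary.ncd_model <- function(object, k_list = c(10, 30), ...) {
  rep <- tryCatch(evaluate_split(object, split = "test", k_list = k_list),
                  error = function(e) NULL)
  out <- list(model = object, test_report = rep,
              history = object$history, best_epoch = object$best_epoch)
  class(out) <- "summary.ncd_model"
  out
}

#' @export
print.summary.ncd_model <- function(x, ...) {
  print(x$model)
  h <- x$history
  cat(sprintf("  final training loss %.4f (epoch 1: %.4f)\n",
              h$loss[nrow(h)], h$loss[1]))
  if (!is.null(x$test_report)) {
    r <- x$test_report
    cat(sprintf("  test AUC %.4f | AUPR %.4f", r$auc, r$aupr))
    for (k in names(r$precision_at_k)) {
      cat(sprintf(" | P@%s %.3f", k, r$precision_at_k[[k]]))
    }
    cat("\n")
  }
  invisible(x)
}

#' @export
coef.ncd_model <- function(object, ...) object$params

#' @export
plot.ncd_model <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  plot(h$epoch, h$loss, type = "l", xlab = "epoch", ylab = "training loss",
       main = "BCE loss", ...)
  if (any(is.finite(h$val_auc))) {
    plot(h$epoch, h$val_auc, type = "l", xlab = "epoch", ylab = "validation AUC",
         main = "validation AUC", ylim = c(0, 1), ...)
    graphics::abline(v = x$best_epoch, lty = 2, col = "grey50")
  }
  invisible(x)
}
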