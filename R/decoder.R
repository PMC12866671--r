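# Edge decoder: concatenation pooling of the (ncRNA, drug) embedding pair
# followed by a three-layer MLP producing one association logit,
#   P = W3 . LeakyReLU(W2 . LeakyReLU(W1 H + b1) + b2) + b3,
# trained under mean binary cross-entropy with a logistic link.

#' Joint pair features by concatenation pooling
#'
#' Concatenates an ncRNA embedding row and a drug embedding row, ncRNA
#' block first.
#'
#' @param h_ncrna,h_drug Numeric vectors (or matrices with matching row
#'   counts, concatenated rowwise).
#' @return A vector (or matrix) of length/width `length(h_ncrna) +
#'   length(h_drug)`.
#' @export
pair_features <- function(h_ncrna, h_drug) {
  if (is.matrix(h_ncrna) || is.matrix(h_drug)) {
    return(cbind(as.matrix(h_ncrna), as.matrix(h_drug)))
  }
  c(h_ncrna, h_drug)
}

# Internal decoder forward with cache.
decoder_run <- function(Hp, dec, slope = 0.2, want_cache = FALSE) {
  Z1 <- sweep(Hp %*% dec$W1, 2, dec$b1, `+`)
  A1 <- leaky_relu(Z1, slope)
  Z2 <- sweep(A1 %*% dec$W2, 2, dec$b2, `+`)
  A2 <- leaky_relu(Z2, slope)
  logits <- drop(A2 %*% dec$W3) + dec$b3
  list(logits = logits,
       cache = if (want_cache) list(Hp = Hp, Z1 = Z1, A1 = A1, Z2 = Z2, A2 = A2))
}

decoder_backward <- function(dlogits, dec, cache, slope = 0.2) {
  dZ3 <- matrix(dlogits, ncol = 1)
  g <- list(W3 = t(cache$A2) %*% dZ3, b3 = sum(dZ3))
  dA2 <- dZ3 %*% t(dec$W3)
  dZ2 <- dA2 * leaky_relu_grad(cache$Z2, slope)
  g$W2 <- t(cache$A1) %*% dZ2; g$b2 <- colSums(dZ2)
  dA1 <- dZ2 %*% t(dec$W2)
  dZ1 <- dA1 * leaky_relu_grad(cache$Z1, slope)
  g$W1 <- t(cache$Hp) %*% dZ1; g$b1 <- colSums(dZ1)
  list(grads = g[c("W1", "b1", "W2", "b2", "W3", "b3")],
       dHp = dZ1 %*% t(dec$W1))
}

#' Score pairs with the MLP edge decoder
#'
#' @param H Matrix of joint pair features (one row per pair), e.g. from
#'   [pair_features()].
#' @param params Decoder parameters: list `W1,b1,W2,b2,W3,b3` (as in the
#'   `dec` component of [init_model_params()]).
#' @param leaky_slope LeakyReLU negative slope.
#' @return Numeric vector of association logits, one per pair.
#' @export
score_pairs <- function(H, params, leaky_slope = 0.2) {
  H <- as.matrix(H)
  out <- decoder_run(H, params, leaky_slope)$logits
  if (!all(is.finite(out))) stop("non-finite decoder output", call. = FALSE)
  out
}

#' Binary cross-entropy over logits
#'
#' Mean of `-(y log s(p) + (1-y) log(1-s(p)))` with logistic `s`, computed
#' in the numerically stabilized log-sum-exp form; finite for any finite
#' logit.
#'
#' @param logits Numeric vector of pair logits.
#' @param labels 0/1 vector of the same length.
#' @return Scalar loss.
#' @export
bce_loss <- function(logits, labels) {
  assert_that(length(logits) > 0, "bce_loss: empty input")
  assert_that(length(logits) == length(labels), "bce_loss: length mismatch")
  assert_that(all(labels %in% c(0, 1)), "bce_loss: labels must be 0/1")
  # -[y log s(p) + (1-y) log(1-s(p))] = log(1+exp(p)) - y p   (stabilized)
  mean(log1pexp(logits) - labels * logits)
}

# ---- whole-model forward/backward (internal) ------------------------------

# pairs_idx: integer matrix, col 1 = ncRNA index (type per config$task),
# col 2 = drug index.
model_forward <- function(prep, params, config, pairs_idx,
                          Xs = NULL, Amats = NULL, want_cache = FALSE) {
  run <- encoder_run(prep, params, config, Xs = Xs, Amats = Amats,
                     want_cache = want_cache)
  nt <- ncrna_type_for_task(config$task)
  Hp <- pair_features(run$H[[nt]][pairs_idx[, 1], , drop = FALSE],
                      run$H[["drug"]][pairs_idx[, 2], , drop = FALSE])
  dr <- decoder_run(Hp, params$dec, config$leaky_slope, want_cache = want_cache)
  list(logits = dr$logits, H = run$H, run = run, dec_cache = dr$cache)
}

model_backward <- function(prep, params, config, fwd, pairs_idx, dlogits,
                           Xs = NULL, Amats = NULL, want_inputs = FALSE) {
  nt <- ncrna_type_for_task(config$task)
  h <- ncol(fwd$H[[nt]])
  db <- decoder_backward(dlogits, params$dec, fwd$dec_cache, config$leaky_slope)
  dH <- lapply(fwd$H, function(m) m * 0)
  dn_pair <- db$dHp[, seq_len(h), drop = FALSE]
  dd_pair <- db$dHp[, h + seq_len(ncol(fwd$H[["drug"]])), drop = FALSE]
  agg_n <- rowsum(dn_pair, group = pairs_idx[, 1])
  dH[[nt]][as.integer(rownames(agg_n)), ] <-
    dH[[nt]][as.integer(rownames(agg_n)), , drop = FALSE] + agg_n
  agg_d <- rowsum(dd_pair, group = pairs_idx[, 2])
  dH[["drug"]][as.integer(rownames(agg_d)), ] <-
    dH[["drug"]][as.integer(rownames(agg_d)), , drop = FALSE] + agg_d
  eb <- encoder_backward(prep, params, config, fwd$run, dH,
                         Xs = Xs, Amats = Amats, want_inputs = want_inputs)
  out <- list(proj = eb$proj, enc = eb$enc, dec = db$grads)
  if (want_inputs) {
    out$dX <- eb$dX
    out$dA <- eb$dA
  }
  out
}
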