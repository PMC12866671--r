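# Relation-type-aware message passing.  Each undirected cross-type relation
# (lm, ld, md) expands into two directed relations with independent weight
# pairs; intra-type relations (ll, mm, dd) use one pair applied symmetrically.
# Per layer and node type:  h_type = sigma( agg_r( W_r^self h + sum_{u in
# N_r} W_r^neigh h_u ) )  with agg in {max, mean, sum, min} and LeakyReLU
# sigma.  No degree normalization, no implicit self-loops beyond the
# explicit self term.

DIRECTED_RELATIONS <- data.frame(
  dir = c("ll", "lm", "ld", "mm", "ml", "md", "dd", "dl", "dm"),
  tgt = c("lncRNA", "lncRNA", "lncRNA", "miRNA", "miRNA", "miRNA",
          "drug", "drug", "drug"),
  src = c("lncRNA", "miRNA", "drug", "miRNA", "lncRNA", "drug",
          "drug", "lncRNA", "miRNA"),
  und = c("ll", "lm", "ld", "mm", "lm", "md", "dd", "ld", "md"),
  stringsAsFactors = FALSE
)

# Compile a hetero_network into index structures for message passing:
# per directed relation, an edge-index matrix, the originating undirected
# edge row, and a dense adjacency.
compile_network <- function(net) {
  types <- NODE_TYPES[vapply(NODE_TYPES, function(t) length(net$nodes[[t]]) > 0,
                             logical(1))]
  idx <- lapply(net$nodes[types], function(ids) stats::setNames(seq_along(ids), ids))
  dirs <- list()
  for (i in seq_len(nrow(DIRECTED_RELATIONS))) {
    d <- DIRECTED_RELATIONS[i, ]
    if (!(d$tgt %in% types) || !(d$src %in% types)) next
    ed <- net$edges[[d$und]]
    intra <- d$tgt == d$src
    if (intra) {
      ti <- c(idx[[d$tgt]][ed$id_a], idx[[d$tgt]][ed$id_b])
      si <- c(idx[[d$src]][ed$id_b], idx[[d$src]][ed$id_a])
      ur <- c(seq_len(nrow(ed)), seq_len(nrow(ed)))
    } else {
      # undirected edge columns are ordered (type_a, type_b); orient them
      a_is_tgt <- relation_types()$type_a[match(d$und, relation_types()$rel)] == d$tgt
      if (a_is_tgt) {
        ti <- idx[[d$tgt]][ed$id_a]; si <- idx[[d$src]][ed$id_b]
      } else {
        ti <- idx[[d$tgt]][ed$id_b]; si <- idx[[d$src]][ed$id_a]
      }
      ur <- seq_len(nrow(ed))
    }
    n_t <- length(net$nodes[[d$tgt]]); n_s <- length(net$nodes[[d$src]])
    A <- matrix(0, n_t, n_s)
    if (length(ti) > 0) A[cbind(ti, si)] <- 1
    dirs[[d$dir]] <- list(dir = d$dir, tgt = d$tgt, src = d$src, und = d$und,
                          ei = cbind(tgt = unname(ti), src = unname(si)),
                          und_row = unname(ur), A = A)
  }
  list(types = types,
       n = vapply(types, function(t) length(net$nodes[[t]]), integer(1)),
       ids = net$nodes[types],
       X = net$features[types],
       dirs = dirs,
       und_edges = net$edges)
}

#' Encoder configuration defaults
#'
#' @param hidden_dim Embedding width per node type (default 64).
#' @param layers Number of message-passing rounds (default 2).
#' @param aggregation Pooling across relation messages: `"min"` (default),
#'   `"mean"`, `"sum"` or `"max"`.
#' @param leaky_slope Negative slope of the LeakyReLU activation (default 0.2).
#' @param task Target association relation, `"LD"` or `"MD"`.
#' @param seed Seed for weight initialization.
#' @return A named list of encoder settings.
#' @export
encoder_config <- function(hidden_dim = 64, layers = 2,
                           aggregation = c("min", "mean", "sum", "max"),
                           leaky_slope = 0.2, task = c("LD", "MD"), seed = 1) {
  list(hidden_dim = hidden_dim, layers = layers,
       aggregation = match.arg(aggregation), leaky_slope = leaky_slope,
       task = match.arg(task), seed = seed)
}

ncrna_type_for_task <- function(task) if (task == "LD") "lncRNA" else "miRNA"

#' Initialize model parameters for a network
#'
#' Glorot-uniform initialization of the type-specific input projections, the
#' per-layer per-directed-relation weight pairs (`W_self`, `W_neigh`), and
#' the three-layer MLP decoder.  All randomness derives from `config$seed`.
#'
#' @param network A `hetero_network`.
#' @param config From [encoder_config()]; `hidden_dim`, `layers`, `seed` used.
#' @return List with components `proj`, `enc` (one list of relations per
#'   layer) and `dec` (`W1,b1,W2,b2,W3,b3`).
#' @export
init_model_params <- function(network, config = encoder_config()) {
  prep <- compile_network(network)
  h <- config$hidden_dim
  with_seed(config$seed, {
    proj <- lapply(prep$X, function(X) glorot(ncol(X), h))
    enc <- lapply(seq_len(config$layers), function(l) {
      lapply(prep$dirs, function(d) list(W_self = glorot(h, h),
                                         W_neigh = glorot(h, h)))
    })
    dec <- list(W1 = glorot(2 * h, h), b1 = numeric(h),
                W2 = glorot(h, h), b2 = numeric(h),
                W3 = glorot(h, 1), b3 = numeric(1))
    list(proj = proj, enc = enc, dec = dec)
  })
}

#' Relation-type-aware message function
#'
#' Computes, for every target node `v`, `f_r(v) = W_self h_v + sum_{u in
#' N_r(v)} W_neigh h_u`.  Nodes with no neighbours under the relation
#' receive only the self term (the empty sum is zero).
#'
#' @param h_src Source-type embeddings, one row per node.
#' @param h_tgt Target-type embeddings, one row per node.
#' @param edges Two-column integer matrix of directed edges `(src, tgt)`.
#' @param W_self,W_neigh Weight matrices (`out_dim x in_dim`), applied as
#'   `h %*% t(W)`.
#' @return Matrix of messages, one row per target node.
#' @export
relation_message <- function(h_src, h_tgt, edges, W_self, W_neigh) {
  h_src <- as.matrix(h_src); h_tgt <- as.matrix(h_tgt)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0) {
    assert_that(all(edges[, 1] >= 1 & edges[, 1] <= nrow(h_src)) &&
                all(edges[, 2] >= 1 & edges[, 2] <= nrow(h_tgt)),
                "edge index out of range")
  }
  out <- h_tgt %*% t(W_self)
  if (nrow(edges) > 0) {
    contrib <- h_src[edges[, 1], , drop = FALSE] %*% t(W_neigh)
    agg <- rowsum(contrib, group = edges[, 2])
    rows <- as.integer(rownames(agg))
    out[rows, ] <- out[rows, , drop = FALSE] + agg
  }
  out
}

#' Aggregate per-relation messages
#'
#' Elementwise pooling of equally shaped message matrices across the
#' relation axis.
#'
#' @param messages Non-empty list of matrices of identical shape.
#' @param strategy One of `"max"`, `"mean"`, `"sum"`, `"min"`.
#' @return The pooled matrix.  For `"min"`/`"max"` an `"argselect"`
#'   attribute records which message supplied each cell (ties go to the
#'   earliest message, the subgradient convention used in training).
#' @export
aggregate_relations <- function(messages, strategy = c("max", "mean", "sum", "min")) {
  strategy <- match.arg(strategy)
  assert_that(length(messages) >= 1, "need at least one message matrix")
  dims <- vapply(messages, function(m) paste(dim(m), collapse = "x"), character(1))
  assert_that(length(unique(dims)) == 1, "message shape mismatch")
  K <- length(messages)
  if (strategy == "sum") return(Reduce(`+`, messages))
  if (strategy == "mean") return(Reduce(`+`, messages) / K)
  agg <- messages[[1]]
  arg <- matrix(1L, nrow(agg), ncol(agg))
  cmp <- if (strategy == "min") `<` else `>`
  for (k in seq_len(K)[-1]) {
    upd <- cmp(messages[[k]], agg)
    agg[upd] <- messages[[k]][upd]
    arg[upd] <- k
  }
  attr(agg, "argselect") <- arg
  agg
}

# ---- full forward pass (internal) -----------------------------------------
# Xs/Amats default to the network's own features/adjacency; integrated
# gradients passes scaled copies.  Returns embeddings and, if wanted, the
# cache needed for backpropagation.
encoder_run <- function(prep, params, config, Xs = NULL, Amats = NULL,
                        want_cache = FALSE) {
  Xs <- Xs %||% prep$X
  Amats <- Amats %||% lapply(prep$dirs, `[[`, "A")
  slope <- config$leaky_slope
  strat <- config$aggregation
  H <- Map(function(X, P) X %*% P, Xs, params$proj[prep$types])
  # directed relations grouped by target type, in a fixed order
  by_tgt <- split(names(prep$dirs),
                  vapply(prep$dirs, `[[`, character(1), "tgt"))
  cache <- list(H0 = H, layers = vector("list", config$layers))
  for (l in seq_len(config$layers)) {
    W <- params$enc[[l]]
    Ms <- list()
    Fs <- list()
    for (dn in names(prep$dirs)) {
      d <- prep$dirs[[dn]]
      Ms[[dn]] <- H[[d$src]] %*% W[[dn]]$W_neigh
      Fs[[dn]] <- H[[d$tgt]] %*% W[[dn]]$W_self + Amats[[dn]] %*% Ms[[dn]]
      if (!all(is.finite(Fs[[dn]]))) {
        stop("non-finite embeddings at encoder layer ", l, call. = FALSE)
      }
    }
    Z <- list(); arg <- list()
    for (t in names(by_tgt)) {
      msgs <- Fs[by_tgt[[t]]]
      z <- aggregate_relations(msgs, strat)
      arg[[t]] <- attr(z, "argselect")
      attr(z, "argselect") <- NULL
      Z[[t]] <- z
    }
    Hnew <- lapply(Z, leaky_relu, slope = slope)
    if (!all(vapply(Hnew, function(m) all(is.finite(m)), logical(1)))) {
      stop("non-finite embeddings at encoder layer ", l, call. = FALSE)
    }
    if (want_cache) {
      cache$layers[[l]] <- list(Hin = H, Ms = Ms, Z = Z, arg = arg)
    }
    H <- Hnew[names(H)]
  }
  list(H = H, cache = if (want_cache) cache, by_tgt = by_tgt)
}

#' Encoder forward pass
#'
#' Applies the type-specific input projections followed by `config$layers`
#' rounds of relation-type-aware message passing with pooling and LeakyReLU.
#' The `"sparse"` method aggregates neighbour sums over edge lists; the
#' `"dense"` method is an adjacency-matrix-product reference implementation.
#' Both must agree to numerical precision.
#'
#' @param network A `hetero_network`.
#' @param params From [init_model_params()].
#' @param config From [encoder_config()].
#' @param method `"sparse"` or `"dense"`.
#' @return Named list of embedding matrices (`n_nodes x hidden_dim`) per
#'   node type, row order matching the network node order.
#' @export
encoder_forward <- function(network, params, config = encoder_config(),
                            method = c("sparse", "dense")) {
  method <- match.arg(method)
  prep <- compile_network(network)
  if (method == "dense") {
    out <- encoder_run(prep, params, config)
    return(out$H)
  }
  # sparse path: rowsum over edge lists, no adjacency materialization
  slope <- config$leaky_slope
  H <- Map(function(X, P) X %*% P, prep$X, params$proj[prep$types])
  by_tgt <- split(names(prep$dirs), vapply(prep$dirs, `[[`, character(1), "tgt"))
  for (l in seq_len(config$layers)) {
    W <- params$enc[[l]]
    Fs <- list()
    for (dn in names(prep$dirs)) {
      d <- prep$dirs[[dn]]
      Fs[[dn]] <- relation_message(
        h_src = H[[d$src]], h_tgt = H[[d$tgt]],
        edges = d$ei[, c("src", "tgt"), drop = FALSE],
        W_self = t(W[[dn]]$W_self), W_neigh = t(W[[dn]]$W_neigh))
      if (!all(is.finite(Fs[[dn]]))) {
        stop("non-finite embeddings at encoder layer ", l, call. = FALSE)
      }
    }
    Hnew <- list()
    for (t in names(by_tgt)) {
      z <- aggregate_relations(Fs[by_tgt[[t]]], config$aggregation)
      attr(z, "argselect") <- NULL
      Hnew[[t]] <- leaky_relu(z, slope)
    }
    if (!all(vapply(Hnew, function(m) all(is.finite(m)), logical(1)))) {
      stop("non-finite embeddings at encoder layer ", l, call. = FALSE)
    }
    H <- Hnew[names(H)]
  }
  H
}

# Backward pass through encoder (and input projections).  dH: gradient of
# the objective w.r.t. final embeddings.  Returns parameter gradients and,
# optionally, gradients w.r.t. the feature matrices and dense adjacencies
# actually passed to encoder_run (needed for integrated gradients).
encoder_backward <- function(prep, params, config, run, dH,
                             Xs = NULL, Amats = NULL, want_inputs = FALSE) {
  Xs <- Xs %||% prep$X
  Amats <- Amats %||% lapply(prep$dirs, `[[`, "A")
  slope <- config$leaky_slope
  strat <- config$aggregation
  cache <- run$cache
  by_tgt <- run$by_tgt
  g_enc <- tree_zero_like(params$enc)
  dA <- if (want_inputs) lapply(Amats, function(A) A * 0)
  for (l in rev(seq_len(config$layers))) {
    lc <- cache$layers[[l]]
    W <- params$enc[[l]]
    dZ <- list()
    for (t in names(dH)) {
      dZ[[t]] <- dH[[t]] * leaky_relu_grad(lc$Z[[t]], slope)
    }
    dHprev <- lapply(lc$Hin, function(m) m * 0)
    for (t in names(by_tgt)) {
      dns <- by_tgt[[t]]
      K <- length(dns)
      for (k in seq_along(dns)) {
        dn <- dns[k]
        d <- prep$dirs[[dn]]
        dF <- switch(strat,
          sum  = dZ[[t]],
          mean = dZ[[t]] / K,
          min  = dZ[[t]] * (lc$arg[[t]] == k),
          max  = dZ[[t]] * (lc$arg[[t]] == k))
        g_enc[[l]][[dn]]$W_self <- g_enc[[l]][[dn]]$W_self +
          t(lc$Hin[[t]]) %*% dF
        dHprev[[t]] <- dHprev[[t]] + dF %*% t(W[[dn]]$W_self)
        G <- t(Amats[[dn]]) %*% dF            # n_src x h
        g_enc[[l]][[dn]]$W_neigh <- g_enc[[l]][[dn]]$W_neigh +
          t(lc$Hin[[d$src]]) %*% G
        dHprev[[d$src]] <- dHprev[[d$src]] + G %*% t(W[[dn]]$W_neigh)
        if (want_inputs) dA[[dn]] <- dA[[dn]] + dF %*% t(lc$Ms[[dn]])
      }
    }
    dH <- dHprev
  }
  g_proj <- Map(function(X, d0) t(X) %*% d0, Xs, dH[names(Xs)])
  out <- list(proj = g_proj, enc = g_enc)
  if (want_inputs) {
    out$dX <- Map(function(d0, P) d0 %*% t(P), dH[names(Xs)],
                  params$proj[names(Xs)])
    out$dA <- dA
  }
  out
}
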