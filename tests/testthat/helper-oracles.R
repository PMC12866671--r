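# Independent brute-force oracles and small fixture builders used across
# the suite.  Oracles deliberately share no code with the implementation.

options(ncdlink.verbose = FALSE)

RELATIONS <- ncdlink:::RELATIONS

# Kendall tau-b by exhaustive pair counting with explicit tie corrections.
oracle_kendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      dx <- sign(x[j] - x[i]); dy <- sign(y[j] - y[i])
      if (dx == 0 && dy == 0) next
      if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (dx == dy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  denom <- sqrt((conc + disc + tx) * (conc + disc + ty))
  if (denom == 0) return(NA_real_)
  (conc - disc) / denom
}

# AUC by exhaustive positive x negative comparison, ties 1/2.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# AUPR by direct precision/recall counting at every distinct threshold,
# rectangle (step) areas.
oracle_aupr <- function(scores, labels) {
  n_pos <- sum(labels == 1)
  ts <- sort(unique(scores), decreasing = TRUE)
  area <- 0; rec_prev <- 0
  for (t in ts) {
    sel <- scores >= t
    prec <- sum(labels[sel] == 1) / sum(sel)
    rec <- sum(labels[sel] == 1) / n_pos
    area <- area + (rec - rec_prev) * prec
    rec_prev <- rec
  }
  area
}

oracle_topk <- function(scores, labels, k) {
  ord <- order(-scores, seq_along(scores))
  lab <- labels[ord][seq_len(k)]
  npos <- sum(labels == 1)
  dcg <- sum(lab / log2(seq_len(k) + 1))
  idcg <- sum(1 / log2(seq_len(min(k, npos)) + 1))
  list(precision = sum(lab) / k, recall = sum(lab) / npos, ndcg = dcg / idcg)
}

# Exhaustive simple-path enumeration (independent DFS) for meta-paths.
oracle_paths <- function(edges, source, target, max_len) {
  # edges: data.frame id_a, id_b, rel, w (undirected)
  res <- list()
  walk <- function(node, visited, rels, score, depth) {
    if (node == target && depth > 0) {
      res[[length(res) + 1]] <<- list(path = visited, rels = rels, score = score)
      return(invisible(NULL))
    }
    if (depth >= max_len) return(invisible(NULL))
    for (i in seq_len(nrow(edges))) {
      nxt <- NULL
      if (edges$id_a[i] == node) nxt <- edges$id_b[i]
      if (edges$id_b[i] == node) nxt <- edges$id_a[i]
      if (is.null(nxt) || nxt %in% visited) next
      walk(nxt, c(visited, nxt), c(rels, edges$rel[i]),
           score + edges$w[i], depth + 1)
    }
  }
  walk(source, source, character(0), 0, 0)
  res
}

# A small random heterogeneous network (all six relations possible).
rand_net <- function(seed, n_l = 4, n_m = 3, n_d = 3, f_l = 3, f_m = 3,
                     f_d = 2, edge_p = 0.4) {
  set.seed(seed)
  ids <- list(lncRNA = sprintf("L%02d", seq_len(n_l)),
              miRNA = sprintf("M%02d", seq_len(n_m)),
              drug = sprintf("D%02d", seq_len(n_d)))
  X <- list(lncRNA = matrix(rnorm(n_l * f_l), n_l, f_l),
            miRNA = matrix(rnorm(n_m * f_m), n_m, f_m),
            drug = matrix(rnorm(n_d * f_d), n_d, f_d))
  for (t in names(X)) rownames(X[[t]]) <- ids[[t]]
  intra <- function(id) {
    cmb <- t(combn(id, 2))
    df <- data.frame(id_a = cmb[, 1], id_b = cmb[, 2], score = 0.9,
                     stringsAsFactors = FALSE)
    df[runif(nrow(df)) < edge_p, , drop = FALSE]
  }
  cross <- function(ia, ib) {
    g <- expand.grid(id_a = ia, id_b = ib, stringsAsFactors = FALSE)
    g$score <- 1
    g[runif(nrow(g)) < edge_p, , drop = FALSE]
  }
  hetero_network(ids, X, list(
    ll = intra(ids$lncRNA), mm = intra(ids$miRNA), dd = intra(ids$drug),
    lm = cross(ids$lncRNA, ids$miRNA), ld = cross(ids$lncRNA, ids$drug),
    md = cross(ids$miRNA, ids$drug)))
}

# A quickly trained small model on a planted instance (for attribution and
# evaluation tests).
quick_model <- function(seed = 1, epochs = 30) {
  pd <- synth_planted_edge(seed)
  model <- train_model(pd$network, pd$dataset,
                       train_config(epochs = epochs, seed = seed))
  list(model = model, pd = pd)
}

write_tsv_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
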