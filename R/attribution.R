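# Integrated-gradients attribution of a pair's association logit to input
# node features and to network edges, plus top-k edge subnetworks and
# meta-path enumeration.
#
# Features are attributed against a zero baseline; edges through a
# continuous mask relaxation (adjacency entries scaled jointly with the
# features from 0 to 1 along the straight-line path).  The attribution
# target is the pre-sigmoid logit, so attributions are additive and the
# completeness identity sum(attr) = f(input) - f(baseline) holds up to the
# path-integral discretization.

#' Integrated-gradients attribution for one ncRNA-drug pair
#'
#' @param model A fitted `ncd_model` (an untrained model is allowed; the
#'   result is flagged via its `trained` field).
#' @param pair Character vector `c(ncrna_id, drug_id)`.
#' @param network Network to explain over; defaults to the model's training
#'   graph.
#' @param steps Path-integral resolution (midpoint rule; default 50).
#' @return An `attribution_result`: per-type feature attribution matrices,
#'   per-relation edge attribution tables (`id_a`, `id_b`, `attribution`),
#'   type-level totals, the explained logit `f_input`, the baseline logit
#'   `f_baseline`, and the completeness gap.
#' @export
attribute_prediction <- function(model, pair, network = NULL, steps = 50) {
  network <- network %||% model$network
  cfg <- model$enc_config
  prep <- compile_network(network)
  nt <- ncrna_type_for_task(cfg$task)
  assert_that(pair[1] %in% prep$ids[[nt]], paste("unknown ncRNA id:", pair[1]))
  assert_that(pair[2] %in% prep$ids[["drug"]], paste("unknown drug id:", pair[2]))
  idx <- cbind(match(pair[1], prep$ids[[nt]]), match(pair[2], prep$ids[["drug"]]))

  A1 <- lapply(prep$dirs, `[[`, "A")
  X1 <- prep$X
  f_input <- model_forward(prep, model$params, cfg, idx)$logits
  f_base <- model_forward(prep, model$params, cfg, idx,
                          Xs = lapply(X1, function(m) m * 0),
                          Amats = lapply(A1, function(m) m * 0))$logits

  gX <- lapply(X1, function(m) m * 0)
  gA <- lapply(A1, function(m) m * 0)
  for (s in seq_len(steps)) {
    a <- (s - 0.5) / steps
    Xs <- lapply(X1, function(m) m * a)
    As <- lapply(A1, function(m) m * a)
    fwd <- model_forward(prep, model$params, cfg, idx, Xs = Xs, Amats = As,
                         want_cache = TRUE)
    bk <- model_backward(prep, model$params, cfg, fwd, idx, dlogits = 1,
                         Xs = Xs, Amats = As, want_inputs = TRUE)
    gX <- tree_map2(`+`, gX, bk$dX)
    gA <- tree_map2(`+`, gA, bk$dA)
  }
  feature_attr <- Map(function(X, g) X * g / steps, X1, gX[names(X1)])

  # fold directed adjacency gradients back onto undirected edges
  edge_attr <- list()
  for (r in RELATIONS) {
    ed <- network$edges[[r]]
    if (is.null(ed) || nrow(ed) == 0) {
      edge_attr[[r]] <- data.frame(id_a = character(0), id_b = character(0),
                                   attribution = numeric(0))
      next
    }
    acc <- numeric(nrow(ed))
    for (dn in names(prep$dirs)) {
      d <- prep$dirs[[dn]]
      if (d$und != r || nrow(d$ei) == 0) next
      g <- gA[[dn]][d$ei] / steps            # gradient at each directed entry
      acc <- acc + as.numeric(rowsum(g, group = d$und_row,
                                     reorder = TRUE)[
        match(seq_len(nrow(ed)), sort(unique(d$und_row))), 1])
    }
    edge_attr[[r]] <- data.frame(id_a = ed$id_a, id_b = ed$id_b,
                                 attribution = acc, stringsAsFactors = FALSE)
  }

  total <- sum(vapply(feature_attr, sum, numeric(1))) +
    sum(vapply(edge_attr, function(e) sum(e$attribution), numeric(1)))
  structure(list(
    pair = pair,
    feature_attr = feature_attr,
    edge_attr = edge_attr,
    node_type_totals = vapply(feature_attr, function(m) sum(abs(m)), numeric(1)),
    edge_type_totals = vapply(edge_attr, function(e) sum(abs(e$attribution)),
                              numeric(1)),
    f_input = f_input, f_baseline = f_base,
    attribution_sum = total,
    completeness_gap = total - (f_input - f_base),
    steps = steps,
    trained = !is.null(model$history),
    network = network), class = "attribution_result")
}

#' @export
print.attribution_result <- function(x, ...) {
  cat(sprintf("Attribution for <%s, %s>%s\n", x$pair[1], x$pair[2],
              if (x$trained) "" else " [UNTRAINED MODEL]"))
  cat(sprintf("  logit %.4f (baseline %.4f), completeness gap %.2e at %d steps\n",
              x$f_input, x$f_baseline, x$completeness_gap, x$steps))
  invisible(x)
}

#' Type-level contribution shares
#'
#' Normalizes absolute attribution mass to percentages, separately within
#' node types (feature attributions) and edge types (relations).  Each
#' table sums to 100.  Signed totals are returned alongside.
#'
#' @param result An `attribution_result`.
#' @return List with `node_types` and `edge_types` percentage vectors and
#'   the signed totals.
#' @export
type_contribution_shares <- function(result) {
  nm <- result$node_type_totals
  em <- result$edge_type_totals
  assert_that(sum(nm) + sum(em) > 0, "all attributions are zero")
  shares <- function(v) if (sum(v) == 0) v else 100 * v / sum(v)
  list(node_types = shares(nm), edge_types = shares(em),
       node_types_signed = vapply(result$feature_attr, sum, numeric(1)),
       edge_types_signed = vapply(result$edge_attr,
                                  function(e) sum(e$attribution), numeric(1)))
}

# Flat table of all scored edges.
attribution_edge_table <- function(result) {
  do.call(rbind, lapply(RELATIONS, function(r) {
    e <- result$edge_attr[[r]]
    if (nrow(e) == 0) return(NULL)
    data.frame(relation = r, e, stringsAsFactors = FALSE)
  }))
}

#' Top-k edge-contribution subnetwork
#'
#' The `k` edges of largest absolute attribution plus their incident nodes,
#' as a valid `hetero_network` whose edge `score` column carries the signed
#' attribution.
#'
#' @param result An `attribution_result`.
#' @param k Edge count (default 300).  If the network has fewer edges, all
#'   are returned with a warning.
#' @return A `hetero_network`.
#' @export
top_k_edge_subnetwork <- function(result, k = 300) {
  tab <- attribution_edge_table(result)
  if (is.null(tab) || nrow(tab) == 0) stop("no scored edges", call. = FALSE)
  if (nrow(tab) < k) {
    warning("network has only ", nrow(tab), " edges (< k = ", k, ")",
            call. = FALSE)
    k <- nrow(tab)
  }
  ord <- order(-abs(tab$attribution), tab$relation, tab$id_a, tab$id_b)
  top <- tab[ord[seq_len(k)], ]
  net <- result$network
  rt <- relation_types()
  nodes <- list(); edges <- list()
  for (r in RELATIONS) {
    sel <- top[top$relation == r, ]
    edges[[r]] <- data.frame(id_a = sel$id_a, id_b = sel$id_b,
                             score = sel$attribution, stringsAsFactors = FALSE)
    i <- match(r, rt$rel)
    nodes[[rt$type_a[i]]] <- union(nodes[[rt$type_a[i]]] %||% character(0),
                                   sel$id_a)
    nodes[[rt$type_b[i]]] <- union(nodes[[rt$type_b[i]]] %||% character(0),
                                   sel$id_b)
  }
  features <- list()
  for (t in names(nodes)) {
    keep <- intersect(net$nodes[[t]], nodes[[t]])   # preserve network order
    nodes[[t]] <- keep
    features[[t]] <- net$features[[t]][keep, , drop = FALSE]
  }
  sub <- hetero_network(nodes, features, edges)
  validate_network(sub)
  sub
}

#' Enumerate meta-paths in an attribution subnetwork
#'
#' All simple paths of at most `max_len` edges between a source and a
#' target node, ranked by path score (sum of absolute edge attributions
#' along the path; the subnetwork's `score` column), ties broken
#' lexicographically on the path string.
#'
#' @param subnetwork A `hetero_network`, typically from
#'   [top_k_edge_subnetwork()].
#' @param source,target Node ids.
#' @param max_len Maximum path length in edges (default 3).
#' @return Data.frame `path` (ids joined by `" | "`), `relations`, `score`,
#'   ordered by decreasing score.  Empty when no path exists.
#' @export
enumerate_meta_paths <- function(subnetwork, source, target, max_len = 3) {
  all_ids <- unlist(subnetwork$nodes, use.names = FALSE)
  assert_that(source %in% all_ids, paste("source not in subnetwork:", source))
  assert_that(target %in% all_ids, paste("target not in subnetwork:", target))
  # undirected adjacency list with relation and |score|
  adj <- list()
  add <- function(u, v, rel, w) {
    adj[[u]] <<- rbind(adj[[u]] %||% NULL,
                       data.frame(to = v, rel = rel, w = w,
                                  stringsAsFactors = FALSE))
  }
  for (r in RELATIONS) {
    e <- subnetwork$edges[[r]]
    for (i in seq_len(nrow(e))) {
      w <- abs(e$score[i])
      add(e$id_a[i], e$id_b[i], r, w)
      add(e$id_b[i], e$id_a[i], r, w)
    }
  }
  out <- list()
  dfs <- function(node, visited, rels, score, depth) {
    if (node == target && depth > 0) {
      out[[length(out) + 1]] <<- list(path = visited, rels = rels, score = score)
      return()
    }
    if (depth >= max_len) return()
    nb <- adj[[node]]
    if (is.null(nb)) return()
    for (i in seq_len(nrow(nb))) {
      v <- nb$to[i]
      if (v %in% visited) next
      dfs(v, c(visited, v), c(rels, nb$rel[i]), score + nb$w[i], depth + 1)
    }
  }
  if (max_len >= 1) dfs(source, source, character(0), 0, 0)
  if (length(out) == 0) {
    return(data.frame(path = character(0), relations = character(0),
                      score = numeric(0)))
  }
  df <- data.frame(
    path = vapply(out, function(p) paste(p$path, collapse = " | "), character(1)),
    relations = vapply(out, function(p) paste(p$rels, collapse = "|"), character(1)),
    score = vapply(out, `[[`, numeric(1), "score"),
    stringsAsFactors = FALSE)
  df[order(-df$score, df$path), , drop = FALSE]
}

#' Export attribution edges and meta-paths
#'
#' Writes the scored edge list (GraphML-compatible source/target/relation/
#' attribution TSV) and, optionally, a meta-path table.
#'
#' @param result An `attribution_result`.
#' @param path Destination TSV for edges.
#' @export
write_attribution_edges <- function(result, path) {
  tab <- attribution_edge_table(result)
  utils::write.table(
    data.frame(source = tab$id_a, target = tab$id_b, relation = tab$relation,
               attribution = tab$attribution),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
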