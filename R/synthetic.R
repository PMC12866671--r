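# Synthetic heterogeneous networks with planted, recoverable association
# structure.  A latent inner-product generative model: every node draws a
# latent factor vector -- a sparse non-negative community-membership
# profile (soft pathway membership) scaled by a lognormal per-node
# activity, which reproduces the hub-dominated degree distributions of
# curated association databases.  Node attributes are a noisy linear
# readout of the factors (so attribute similarity tracks latent
# similarity); similarity edges come from thresholded latent correlations
# (scale-invariant, so activity does not distort them); lncRNA-miRNA edges
# link pairs sharing factors; true ncRNA-drug associations are the pairs
# whose latent inner product exceeds a quantile cut (the order statistic
# giving an exact positive count), with a tunable fraction of labels
# flipped.

#' Synthetic network configuration
#'
#' Defaults define the reference benchmark: 200 lncRNAs, 100 miRNAs, 30
#' drugs, 8 latent factors, 5% label noise, 10 positives per drug and task,
#' similarity threshold 0.5.
#'
#' @param n_lnc,n_mi,n_drug Node counts (all >= 2).
#' @param latent_dim Latent factor (community) dimensionality.
#' @param feature_dim Named attribute widths per type.
#' @param noise Fraction of association labels flipped, in `[0, 1)`.
#' @param positives_per_drug Average planted positives per drug per task.
#' @param sim_threshold Latent-correlation threshold for similarity edges.
#' @param feature_noise_sd Gaussian noise added to the attribute readout.
#' @param membership_prob Per-community membership probability (each node
#'   belongs to `latent_dim * membership_prob` communities on average; a
#'   node with no community is assigned one at random).
#' @param activity_sd Lognormal sdlog of the per-node activity scale
#'   (degree heterogeneity; 0 disables it).
#' @param seed Mandatory master seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_lnc = 200, n_mi = 100, n_drug = 30, latent_dim = 8,
                         feature_dim = c(lncRNA = 32, miRNA = 32, drug = 16),
                         noise = 0.05, positives_per_drug = 10,
                         sim_threshold = 0.5, feature_noise_sd = 0.1,
                         membership_prob = 0.375, activity_sd = 0.75,
                         seed = NULL) {
  assert_that(!is.null(seed), "synth_config: seed is mandatory")
  assert_that(min(n_lnc, n_mi, n_drug) >= 2, "node counts must be >= 2")
  assert_that(noise >= 0 && noise < 1, "noise must be in [0, 1)")
  structure(list(n_lnc = n_lnc, n_mi = n_mi, n_drug = n_drug,
                 latent_dim = latent_dim, feature_dim = feature_dim,
                 noise = noise, positives_per_drug = positives_per_drug,
                 sim_threshold = sim_threshold,
                 feature_noise_sd = feature_noise_sd,
                 membership_prob = membership_prob, activity_sd = activity_sd,
                 seed = seed),
            class = "synth_config")
}

# Edges between rows of Za and (optionally distinct) Zb where the latent
# Pearson correlation exceeds the threshold.
latent_cor_edges <- function(Za, Zb = NULL, ids_a, ids_b = NULL, threshold) {
  C <- suppressWarnings(stats::cor(t(Za), t(Zb %||% Za)))
  C[is.na(C)] <- 0
  if (is.null(Zb)) {
    sel <- which(upper.tri(C) & C > threshold, arr.ind = TRUE)
  } else {
    sel <- which(C > threshold, arr.ind = TRUE)
  }
  if (nrow(sel) == 0) return(empty_edges())
  data.frame(id_a = ids_a[sel[, 1]], id_b = (ids_b %||% ids_a)[sel[, 2]],
             score = C[sel], stringsAsFactors = FALSE)
}

# Top-n_pos entries of a score matrix as positive (row, col) pairs; the cut
# is the n_pos-th largest order statistic, so the count is exact.
top_pairs <- function(S, n_pos, row_ids, col_ids) {
  ord <- order(S, decreasing = TRUE)[seq_len(n_pos)]
  data.frame(source_id = row_ids[(ord - 1) %% nrow(S) + 1],
             target_id = col_ids[(ord - 1) %/% nrow(S) + 1],
             stringsAsFactors = FALSE)
}

flip_labels <- function(pos, n_row_ids, n_col_ids, noise, seed) {
  n_flip <- round(noise * nrow(pos))
  if (n_flip == 0) return(pos)
  with_seed(seed, {
    drop_i <- sample(nrow(pos), n_flip)
    kept <- pos[-drop_i, , drop = FALSE]
    key <- paste(pos$source_id, pos$target_id)
    grid <- expand.grid(source_id = n_row_ids, target_id = n_col_ids,
                        stringsAsFactors = FALSE)
    unknown <- grid[!(paste(grid$source_id, grid$target_id) %in% key), ]
    add <- unknown[sample(nrow(unknown), n_flip), ]
    rbind(kept, add)
  })
}

#' Generate a synthetic heterogeneous network with planted associations
#'
#' @param config A [synth_config()].
#' @return List of class `synth_data`: `network` (a `hetero_network` whose
#'   `ld`/`md` relations hold the noisy planted positives), `truth` (list
#'   of positive pair data.frames per task, `LD` and `MD`), `latent` (the
#'   generating factors) and `config`.
#' @export
synth_generate <- function(config) {
  assert_that(inherits(config, "synth_config"), "need a synth_config")
  k <- config$latent_dim
  ids <- list(lncRNA = sprintf("L%03d", seq_len(config$n_lnc)),
              miRNA = sprintf("M%03d", seq_len(config$n_mi)),
              drug = sprintf("D%03d", seq_len(config$n_drug)))
  n <- c(lncRNA = config$n_lnc, miRNA = config$n_mi, drug = config$n_drug)
  Z <- list(); X <- list()
  for (i in seq_along(n)) {
    t <- names(n)[i]
    Z[[t]] <- with_seed(child_seed(config$seed, i), {
      m <- n[[t]]
      memb <- matrix(stats::rbinom(m * k, 1, config$membership_prob), m, k)
      none <- rowSums(memb) == 0
      if (any(none)) {
        memb[cbind(which(none), sample(k, sum(none), replace = TRUE))] <- 1
      }
      act <- exp(stats::rnorm(m, 0, config$activity_sd))
      act * (memb * matrix(stats::runif(m * k, 0.9, 1.1), m, k))
    })
    rownames(Z[[t]]) <- ids[[t]]
    f <- config$feature_dim[[t]]
    X[[t]] <- with_seed(child_seed(config$seed, 10 + i), {
      B <- matrix(stats::rnorm(k * f), k, f) / sqrt(k)
      Z[[t]] %*% B + config$feature_noise_sd * matrix(stats::rnorm(n[t] * f),
                                                      n[t], f)
    })
    rownames(X[[t]]) <- ids[[t]]
  }
  thr <- config$sim_threshold
  edges <- list(
    ll = latent_cor_edges(Z$lncRNA, ids_a = ids$lncRNA, threshold = thr),
    mm = latent_cor_edges(Z$miRNA, ids_a = ids$miRNA, threshold = thr),
    dd = latent_cor_edges(Z$drug, ids_a = ids$drug, threshold = thr),
    lm = latent_cor_edges(Z$lncRNA, Z$miRNA, ids$lncRNA, ids$miRNA, thr))

  n_pos_ld <- config$positives_per_drug * config$n_drug
  n_pos_md <- config$positives_per_drug * config$n_drug
  assert_that(n_pos_ld <= config$n_lnc * config$n_drug &&
              n_pos_md <= config$n_mi * config$n_drug,
              "positives_per_drug infeasible for the given node counts")
  truth <- list(
    LD = flip_labels(top_pairs(Z$lncRNA %*% t(Z$drug), n_pos_ld,
                               ids$lncRNA, ids$drug),
                     ids$lncRNA, ids$drug, config$noise,
                     child_seed(config$seed, 21)),
    MD = flip_labels(top_pairs(Z$miRNA %*% t(Z$drug), n_pos_md,
                               ids$miRNA, ids$drug),
                     ids$miRNA, ids$drug, config$noise,
                     child_seed(config$seed, 22)))
  edges$ld <- data.frame(id_a = truth$LD$source_id, id_b = truth$LD$target_id,
                         score = 1, stringsAsFactors = FALSE)
  edges$md <- data.frame(id_a = truth$MD$source_id, id_b = truth$MD$target_id,
                         score = 1, stringsAsFactors = FALSE)
  net <- hetero_network(ids, X, edges)
  validate_network(net)
  structure(list(network = net, truth = truth, latent = Z, config = config),
            class = "synth_data")
}

#' Reproducible corruption of a synthetic benchmark
#'
#' Modes: `shuffle_labels` replaces each task's positive set with uniformly
#' random pairs of the same size (and rewires the corresponding association
#' relations), destroying any learnable signal; `remove_relation` empties
#' one named relation and touches nothing else; `randomize_features`
#' replaces all attribute matrices with standard Gaussian noise of the same
#' shape.
#'
#' @param sim A `synth_data` object (or a `hetero_network` for modes that
#'   only touch the network).
#' @param mode `"shuffle_labels"`, `"remove_relation"` or
#'   `"randomize_features"`.
#' @param seed RNG seed.
#' @param relation Relation name for `remove_relation`.
#' @return An object of the same class as `sim`, corrupted.
#' @export
synth_degrade <- function(sim, mode = c("shuffle_labels", "remove_relation",
                                        "randomize_features"),
                          seed = 1, relation = "lm") {
  if (!inherits(sim, c("synth_data", "hetero_network"))) {
    stop("unknown input for synth_degrade", call. = FALSE)
  }
  mode <- match.arg(mode)
  net <- if (inherits(sim, "synth_data")) sim$network else sim
  if (mode == "remove_relation") {
    assert_that(relation %in% RELATIONS, paste("unknown relation:", relation))
    net$edges[[relation]] <- empty_edges()
  } else if (mode == "randomize_features") {
    for (i in seq_along(net$features)) {
      t <- names(net$features)[i]
      X <- net$features[[t]]
      net$features[[t]] <- with_seed(child_seed(seed, 30 + i),
        matrix(stats::rnorm(length(X)), nrow(X), ncol(X)))
      rownames(net$features[[t]]) <- net$nodes[[t]]
    }
  } else { # shuffle_labels
    assert_that(inherits(sim, "synth_data"),
                "shuffle_labels needs a synth_data object")
    for (j in seq_along(sim$truth)) {
      task <- names(sim$truth)[j]
      src_ids <- if (task == "LD") net$nodes$lncRNA else net$nodes$miRNA
      n_pos <- nrow(sim$truth[[task]])
      lin <- with_seed(child_seed(seed, 40 + j),
                       sample(length(src_ids) * length(net$nodes$drug), n_pos))
      sim$truth[[task]] <- data.frame(
        source_id = src_ids[(lin - 1) %% length(src_ids) + 1],
        target_id = net$nodes$drug[(lin - 1) %/% length(src_ids) + 1],
        stringsAsFactors = FALSE)
      rel <- if (task == "LD") "ld" else "md"
      net$edges[[rel]] <- canonicalize_edges(
        data.frame(id_a = sim$truth[[task]]$source_id,
                   id_b = sim$truth[[task]]$target_id, score = 1),
        intra = FALSE)
    }
  }
  if (inherits(sim, "synth_data")) {
    sim$network <- net
    sim
  } else {
    net
  }
}

#' Synthetic benchmark with a single signal-bottleneck lncRNA-miRNA edge
#'
#' Builds a small network where association labels are decided by the
#' latent factors of each lncRNA's unique miRNA partner: every lncRNA has
#' exactly one `lm` edge, lncRNA attributes are pure noise, and drugs are
#' identified by their own attributes.  For a designated target pair all of
#' the target lncRNA's positives are withheld from training, so the only
#' edge through which the pair's signal can flow is the target lncRNA's
#' single `lm` edge — the planted edge an attribution method should rank
#' first.
#'
#' @param seed Master seed.
#' @param n_lnc,n_mi,n_drug Node counts.
#' @return List of class `planted_edge_data`: `network`, `truth` (LD
#'   positives), `dataset` (split so the target's positives sit in the test
#'   split), `target_pair`, `planted_edge` (`c(lncRNA, miRNA)`), `config`.
#' @export
synth_planted_edge <- function(seed, n_lnc = 16, n_mi = 8, n_drug = 8) {
  k <- 4
  ids <- list(lncRNA = sprintf("L%02d", seq_len(n_lnc)),
              miRNA = sprintf("M%02d", seq_len(n_mi)),
              drug = sprintf("D%02d", seq_len(n_drug)))
  Zm <- with_seed(child_seed(seed, 1), matrix(stats::rnorm(n_mi * k), n_mi, k))
  Zd <- with_seed(child_seed(seed, 2), matrix(stats::rnorm(n_drug * k), n_drug, k))
  Xl <- with_seed(child_seed(seed, 3),
                  0.1 * matrix(stats::rnorm(n_lnc * k), n_lnc, k))
  partner <- with_seed(child_seed(seed, 4),
                       sample(n_mi, n_lnc, replace = TRUE))
  S <- Zm[partner, , drop = FALSE] %*% t(Zd)      # label scores per (l, d)
  n_pos <- round(0.3 * n_lnc * n_drug)
  truth <- top_pairs(S, n_pos, ids$lncRNA, ids$drug)

  X <- list(lncRNA = Xl, miRNA = Zm, drug = Zd)
  for (t in names(X)) rownames(X[[t]]) <- ids[[t]]
  edges <- list(
    lm = data.frame(id_a = ids$lncRNA, id_b = ids$miRNA[partner], score = 1),
    ld = data.frame(id_a = truth$source_id, id_b = truth$target_id, score = 1))
  net <- hetero_network(ids, X, edges)

  # choose a target lncRNA with >= 2 positives whose miRNA partner has no
  # other lncRNA attached (so the planted edge is a clean bottleneck); hold
  # all of the target's positives out of training
  tab <- table(truth$source_id)
  cand <- names(tab)[tab >= 2]
  assert_that(length(cand) > 0, "no lncRNA with >= 2 positives")
  m_deg <- table(partner)
  uniq <- cand[m_deg[as.character(partner[match(cand, ids$lncRNA)])] == 1]
  if (length(uniq) > 0) cand <- uniq
  target_l <- with_seed(child_seed(seed, 5), sample(cand, 1))

  rest <- truth[truth$source_id != target_l, ]
  held <- truth[truth$source_id == target_l, ]
  # among the held-out positives, explain the drug with the fewest training
  # associations, so the pair's signal is dominated by the planted lm edge
  # rather than by the drug's own association edges
  d_deg <- table(factor(rest$target_id, levels = ids$drug))
  target_d <- held$target_id[which.min(d_deg[held$target_id])]
  # negatives avoid ALL true positives (including the held-out ones)
  negs <- sample_negatives(truth, ids$lncRNA, ids$drug, ratio = 2,
                           seed = child_seed(seed, 6))
  labelled <- data.frame(
    ncrna_id = c(rest$source_id, negs$source_id),
    drug_id = c(rest$target_id, negs$target_id),
    label = c(rep(1L, nrow(rest)), rep(0L, nrow(negs))),
    stringsAsFactors = FALSE)
  ds <- split_dataset(labelled, seed = child_seed(seed, 7), task = "LD")
  held_rows <- data.frame(ncrna_id = held$source_id, drug_id = held$target_id,
                          label = 1L, split = "test", stringsAsFactors = FALSE)
  ds2 <- rbind(as.data.frame(ds), held_rows)
  attr(ds2, "task") <- "LD"
  class(ds2) <- c("association_dataset", "data.frame")

  structure(list(network = net, truth = truth, dataset = ds2,
                 target_pair = c(target_l, target_d),
                 planted_edge = c(target_l, ids$miRNA[partner[match(target_l,
                                                                    ids$lncRNA)]]),
                 seed = seed), class = "planted_edge_data")
}
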