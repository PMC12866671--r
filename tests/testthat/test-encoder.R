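test_that("relation_message computes self plus neighbour sums", {
  h <- matrix(c(1, 0, 0, 1, 1, 1), 3, 2, byrow = TRUE)
  I <- diag(2); Z <- matrix(0, 2, 2)
  # no edges, identity self: message is the embedding itself
  expect_equal(relation_message(h, h, matrix(integer(0), 0, 2), I, I), h)
  # single directed edge u=1 -> v=2 with zero self: target gets h_u, source 0
  e <- cbind(1L, 2L)
  m <- relation_message(h, h, e, Z, I)
  expect_equal(m[2, ], h[1, ])
  expect_equal(m[1, ], c(0, 0))
  # star: three neighbours (1,0), (0,1), (1,1) into centre node
  hs <- rbind(c(1, 0), c(0, 1), c(1, 1))
  ht <- matrix(0, 1, 2)
  star <- relation_message(hs, ht, cbind(1:3, 1L), Z, I)
  expect_equal(star[1, ], c(2, 2))
  expect_error(relation_message(hs, ht, cbind(9L, 1L), Z, I), "out of range")
})

test_that("aggregate_relations pools elementwise with a brute-force oracle", {
  A <- matrix(1:4, 2, 2)
  expect_equal(aggregate_relations(list(A, A, A), "mean"), A)
  expect_equal(aggregate_relations(list(matrix(1), matrix(3)), "sum"), matrix(4))
  expect_equal(unname(aggregate_relations(list(matrix(1), matrix(3)), "min")[1, 1]), 1)
  expect_equal(unname(aggregate_relations(list(matrix(1), matrix(3)), "max")[1, 1]), 3)
  set.seed(9)
  ms <- lapply(1:3, function(i) matrix(rnorm(8), 4, 2))
  for (strat in c("max", "mean", "sum", "min")) {
    got <- aggregate_relations(ms, strat)
    f <- switch(strat, max = max, min = min, sum = sum, mean = mean)
    for (i in 1:4) for (j in 1:2) {
      expect_equal(got[i, j], f(c(ms[[1]][i, j], ms[[2]][i, j], ms[[3]][i, j])))
    }
  }
  expect_error(aggregate_relations(list(matrix(0, 2, 2), matrix(0, 3, 2)), "sum"),
               "shape")
})

test_that("a one-layer forward pass matches a hand-computed toy example", {
  # 2 lncRNAs, 1 miRNA, 1 drug; identity-like weights, sum aggregation
  ids <- list(lncRNA = c("l1", "l2"), miRNA = "m1", drug = "d1")
  X <- list(lncRNA = rbind(c(1, 0), c(0, 1)), miRNA = rbind(c(1, 1)),
            drug = rbind(c(2, 0)))
  for (t in names(X)) rownames(X[[t]]) <- ids[[t]]
  net <- hetero_network(ids, X, list(
    ll = data.frame(id_a = "l1", id_b = "l2"),
    lm = data.frame(id_a = "l1", id_b = "m1"),
    ld = data.frame(id_a = "l2", id_b = "d1")))
  cfg <- encoder_config(hidden_dim = 2, layers = 1, aggregation = "sum",
                        leaky_slope = 0.5, seed = 1)
  params <- init_model_params(net, cfg)
  I2 <- diag(2)
  params$proj <- list(lncRNA = I2, miRNA = I2, drug = I2)
  for (dn in names(params$enc[[1]])) {
    params$enc[[1]][[dn]] <- list(W_self = I2, W_neigh = I2)
  }
  H <- encoder_forward(net, params, cfg)
  # l1: f_ll = h_l1 + h_l2 = (1,1); f_lm = h_l1 + h_m1 = (2,1);
  #     f_ld = h_l1 (no ld edge at l1) = (1,0); sum = (4,2)
  expect_equal(unname(H$lncRNA["l1", ]), c(4, 2))
  # l2: f_ll = (1,1); f_lm = (0,1); f_ld = (2,1); sum = (3,3)
  expect_equal(unname(H$lncRNA["l2", ]), c(3, 3))
  # m1: f_mm = (1,1); f_ml = (1,1)+(1,0)=(2,1); f_md = (1,1); sum = (4,3)
  expect_equal(unname(H$miRNA["m1", ]), c(4, 3))
  # d1: f_dd = (2,0); f_dl = (2,0)+(0,1)=(2,1); f_dm = (2,0); sum = (6,1)
  expect_equal(unname(H$drug["d1", ]), c(6, 1))
})

test_that("zero-edge networks mix nothing: equal features give equal embeddings", {
  ids <- list(lncRNA = c("a", "b", "c"), miRNA = "m", drug = "d")
  X <- list(lncRNA = rbind(c(1, 2), c(1, 2), c(3, 4)),
            miRNA = rbind(c(0, 0)), drug = rbind(c(1, 1)))
  for (t in names(X)) rownames(X[[t]]) <- ids[[t]]
  net <- hetero_network(ids, X)
  cfg <- encoder_config(hidden_dim = 3, seed = 2)
  H <- encoder_forward(net, init_model_params(net, cfg), cfg)
  expect_equal(H$lncRNA["a", ], H$lncRNA["b", ])
  expect_false(isTRUE(all.equal(H$lncRNA["a", ], H$lncRNA["c", ])))
})

test_that("encoder is permutation equivariant", {
  for (trial in 1:5) {
    net <- rand_net(trial, n_l = 4, n_m = 3, n_d = 3)
    cfg <- encoder_config(hidden_dim = 4, seed = trial)
    params <- init_model_params(net, cfg)
    H <- encoder_forward(net, params, cfg)
    # permute lncRNA node order consistently
    set.seed(trial + 100)
    perm <- sample(length(net$nodes$lncRNA))
    net2 <- net
    net2$nodes$lncRNA <- net$nodes$lncRNA[perm]
    net2$features$lncRNA <- net$features$lncRNA[perm, , drop = FALSE]
    net2$edges <- lapply(net$edges, function(e) e)  # ids are symbolic; edges unchanged
    net2 <- hetero_network(net2$nodes, net2$features, net2$edges)
    H2 <- encoder_forward(net2, params, cfg)
    expect_equal(H2$lncRNA[net$nodes$lncRNA, ], H$lncRNA[net$nodes$lncRNA, ],
                 tolerance = 1e-12)
    expect_equal(H2$drug, H$drug, tolerance = 1e-12)
  }
})

test_that("with tied weights and mean pooling a layer reduces to per-relation
           convolution averaged", {
  net <- rand_net(7, n_l = 6, n_m = 4, n_d = 4)
  h <- 3
  cfg <- encoder_config(hidden_dim = h, layers = 1, aggregation = "mean",
                        leaky_slope = 0.3, seed = 7)
  params <- init_model_params(net, cfg)
  Wself <- params$enc[[1]]$ll$W_self
  Wneigh <- params$enc[[1]]$ll$W_neigh
  for (dn in names(params$enc[[1]])) {
    params$enc[[1]][[dn]] <- list(W_self = Wself, W_neigh = Wneigh)
  }
  H <- encoder_forward(net, params, cfg)
  # naive dense reference: one shared-weight convolution per relation,
  # averaged per target type, then LeakyReLU
  prep <- ncdlink:::compile_network(net)
  H0 <- Map(function(X, P) X %*% P, prep$X, params$proj)
  for (t in names(H0)) {
    dirs <- Filter(function(d) d$tgt == t, prep$dirs)
    acc <- 0
    for (d in dirs) acc <- acc + (H0[[t]] %*% Wself + d$A %*% H0[[d$src]] %*% Wneigh)
    Z <- acc / length(dirs)
    ref <- ifelse(Z > 0, Z, 0.3 * Z)
    expect_equal(unname(H[[t]]), unname(ref), tolerance = 1e-10)
  }
})

test_that("relation-locality: under sum pooling removing a relation's edges
           shifts layer-1 pre-activations by exactly that message stream", {
  net <- rand_net(13, n_l = 5, n_m = 4, n_d = 3)
  cfg <- encoder_config(hidden_dim = 4, layers = 1, aggregation = "sum", seed = 13)
  params <- init_model_params(net, cfg)
  prep <- ncdlink:::compile_network(net)
  run_full <- ncdlink:::encoder_run(prep, params, cfg, want_cache = TRUE)
  net2 <- net; net2$edges$lm <- net$edges$lm[0, ]
  prep2 <- ncdlink:::compile_network(net2)
  run_wo <- ncdlink:::encoder_run(prep2, params, cfg, want_cache = TRUE)
  dZ_l <- run_full$cache$layers[[1]]$Z$lncRNA - run_wo$cache$layers[[1]]$Z$lncRNA
  H0m <- run_full$cache$H0$miRNA
  expected <- prep$dirs$lm$A %*% H0m %*% params$enc[[1]]$lm$W_neigh
  expect_equal(unname(dZ_l), unname(expected), tolerance = 1e-12)
  # drug stream untouched by lm removal at layer 1
  expect_equal(run_full$cache$layers[[1]]$Z$drug,
               run_wo$cache$layers[[1]]$Z$drug, tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  net <- rand_net(21, n_l = 4, n_m = 3, n_d = 3)
  prep <- ncdlink:::compile_network(net)
  pairs <- cbind(c(1L, 2L, 4L), c(1L, 3L, 2L))
  y <- c(1, 0, 1)
  for (strat in c("sum", "min")) {
    cfg <- encoder_config(hidden_dim = 3, layers = 2, aggregation = strat,
                          seed = 21)
    params <- init_model_params(net, cfg)
    fwd <- ncdlink:::model_forward(prep, params, cfg, pairs, want_cache = TRUE)
    dlog <- (ncdlink:::sigmoid(fwd$logits) - y) / length(y)
    gr <- ncdlink:::model_backward(prep, params, cfg, fwd, pairs, dlog)
    fobj <- function(p) bce_loss(ncdlink:::model_forward(prep, p, cfg, pairs)$logits, y)
    eps <- 1e-6
    set.seed(1)
    # a sample of parameter leaves across all components
    for (probe in 1:20) {
      comp <- sample(c("proj", "enc", "dec"), 1)
      if (comp == "proj") {
        t <- sample(names(params$proj), 1)
        i <- sample(length(params$proj[[t]]), 1)
        p1 <- params; p1$proj[[t]][i] <- p1$proj[[t]][i] + eps
        p2 <- params; p2$proj[[t]][i] <- p2$proj[[t]][i] - eps
        ana <- gr$proj[[t]][i]
      } else if (comp == "enc") {
        l <- sample(2, 1); dn <- sample(names(params$enc[[l]]), 1)
        w <- sample(c("W_self", "W_neigh"), 1)
        i <- sample(length(params$enc[[l]][[dn]][[w]]), 1)
        p1 <- params; p1$enc[[l]][[dn]][[w]][i] <- p1$enc[[l]][[dn]][[w]][i] + eps
        p2 <- params; p2$enc[[l]][[dn]][[w]][i] <- p2$enc[[l]][[dn]][[w]][i] - eps
        ana <- gr$enc[[l]][[dn]][[w]][i]
      } else {
        w <- sample(names(params$dec), 1)
        i <- sample(length(params$dec[[w]]), 1)
        p1 <- params; p1$dec[[w]][i] <- p1$dec[[w]][i] + eps
        p2 <- params; p2$dec[[w]][i] <- p2$dec[[w]][i] - eps
        ana <- gr$dec[[w]][i]
      }
      num <- (fobj(p1) - fobj(p2)) / (2 * eps)
      expect_equal(ana, num, tolerance = 1e-3)
    }
  }
})

test_that("every parameter receives gradient on a generic input", {
  net <- rand_net(31, n_l = 5, n_m = 4, n_d = 4, edge_p = 0.6)
  prep <- ncdlink:::compile_network(net)
  cfg <- encoder_config(hidden_dim = 4, aggregation = "sum", seed = 31)
  params <- init_model_params(net, cfg)
  pairs <- cbind(1:5, c(1L, 2L, 3L, 4L, 1L))
  y <- c(1, 0, 1, 0, 1)
  fwd <- ncdlink:::model_forward(prep, params, cfg, pairs, want_cache = TRUE)
  gr <- ncdlink:::model_backward(prep, params, cfg, fwd, pairs,
                                 (ncdlink:::sigmoid(fwd$logits) - y) / 5)
  walk <- function(g, path = "") {
    if (is.list(g)) {
      for (nm in names(g)) walk(g[[nm]], paste(path, nm))
    } else {
      expect_gt(sum(abs(g)), 0, label = paste("gradient at", path))
    }
  }
  walk(gr)
})

test_that("non-finite features abort with the offending layer named", {
  net <- rand_net(41)
  net$features$lncRNA[1, 1] <- Inf
  cfg <- encoder_config(hidden_dim = 3, seed = 41)
  params <- init_model_params(net, cfg)
  expect_error(encoder_forward(net, params, cfg), "layer 1")
})
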