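test_that("kendall_tau matches hand examples and the brute-force oracle", {
  expect_equal(kendall_tau(1:3, 1:3), 1)
  expect_equal(kendall_tau(1:3, 3:1), -1)
  expect_equal(kendall_tau(c(1, 2, 3, 4), c(1, 3, 2, 4)), 4 / 6,
               tolerance = 1e-12)
  # tie-corrected variant agrees with exhaustive counting on tied data
  set.seed(11)
  for (i in 1:25) {
    x <- sample(1:4, 8, replace = TRUE)
    y <- sample(1:4, 8, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(kendall_tau(x, y), oracle_kendall(x, y), tolerance = 1e-12)
    expect_equal(kendall_tau(x, y), kendall_tau(y, x))
    expect_lte(abs(kendall_tau(x, y)), 1)
  }
  expect_error(kendall_tau(1:3, 1:4), "length")
  expect_true(is.na(kendall_tau(c(1, 1, 1), 1:3)))
})

test_that("build_similarity_edges equals O(n^2) brute force and is monotone", {
  m <- matrix(c(1, 2, 3, 3, 2, 1, 1, 2, 3), 3, 3, byrow = TRUE)
  rownames(m) <- c("a", "b", "c")
  e <- build_similarity_edges(m, 0.5)
  expect_equal(nrow(e), 1L)
  expect_equal(e$id_a, "a"); expect_equal(e$id_b, "c")
  ident <- matrix(rep(c(1, 2, 3, 4), 3), 3, 4, byrow = TRUE)
  rownames(ident) <- c("x", "y", "z")
  e3 <- build_similarity_edges(ident, 0.5)
  expect_equal(nrow(e3), 3L)
  expect_true(all(e3$score == 1))

  set.seed(5)
  M <- matrix(sample(1:5, 10 * 6, replace = TRUE), 10, 6)
  rownames(M) <- sprintf("r%02d", 1:10)
  got <- build_similarity_edges(M, 0.3)
  # brute force over all pairs with the oracle tau
  exp_edges <- 0
  for (i in 1:9) for (j in (i + 1):10) {
    tau <- oracle_kendall(M[i, ], M[j, ])
    if (!is.na(tau) && tau > 0.3) {
      exp_edges <- exp_edges + 1
      row <- got[got$id_a == rownames(M)[i] & got$id_b == rownames(M)[j], ]
      expect_equal(nrow(row), 1L)
      expect_equal(row$score, tau, tolerance = 1e-12)
    }
  }
  expect_equal(nrow(got), exp_edges)
  # permutation invariance of the edge set
  perm <- sample(10)
  got_p <- build_similarity_edges(M[perm, ], 0.3)
  key <- function(d) sort(paste(d$id_a, d$id_b))
  expect_identical(key(got), key(got_p))
  # raising the threshold never adds edges
  expect_lte(nrow(build_similarity_edges(M, 0.5)), nrow(got))
  expect_warning(e1 <- build_similarity_edges(M[1, , drop = FALSE]), "fewer")
  expect_equal(nrow(e1), 0L)
})

test_that("tanimoto follows set arithmetic", {
  fp <- function(bits) structure(list(bits = bits, width = 16L),
                                 class = "fingerprint")
  expect_equal(tanimoto(fp(c(1, 2, 3)), fp(c(1, 2, 3))), 1)
  expect_equal(tanimoto(fp(c(1, 2)), fp(c(3, 4))), 0)
  expect_equal(tanimoto(fp(c(1, 2, 3)), fp(c(2, 3, 4))), 0.5)
  expect_equal(tanimoto(fp(integer(0)), fp(integer(0))), 0)
  expect_error(tanimoto(fp(1), structure(list(bits = 1, width = 8L),
                                         class = "fingerprint")), "width")
})

test_that("circular fingerprints are deterministic and canonicalization-invariant", {
  a <- fingerprint_from_smiles("CCO")
  expect_s3_class(a, "fingerprint")
  expect_identical(a, fingerprint_from_smiles("CCO"))
  # non-canonical SMILES of ethanol
  expect_identical(a$bits, fingerprint_from_smiles("OCC")$bits)
  m <- fingerprint_from_smiles("C")
  expect_gt(length(m$bits), 0)
  expect_true(all(m$bits >= 0 & m$bits < m$width))
  w <- fingerprint_from_smiles("c1ccccc1O", width = 512)
  expect_true(all(w$bits < 512))
  expect_error(fingerprint_from_smiles("not_a_molecule$$$"), "unparsable")
})

test_that("drug feature encoding is per-drug, 0/1, cached and pluggable", {
  tab <- data.frame(drug_id = c("d1", "d2", "d3"),
                    smiles = c("CCO", "CCO", "c1ccccc1"),
                    stringsAsFactors = FALSE)
  F <- encode_drug_features(tab, width = 256)
  expect_equal(dim(F), c(3L, 256L))
  expect_true(all(F %in% c(0, 1)))
  expect_equal(F["d1", ], F["d2", ])   # identical SMILES -> identical rows
  # pretrained mode: error without an encoder, cache round trip with one
  expect_error(encode_drug_features(tab, mode = "pretrained-embedding"),
               "fingerprint")
  enc <- function(s) matrix(seq_len(length(s) * 4), length(s), 4)
  cache <- tempfile(fileext = ".rds")
  E1 <- encode_drug_features(tab, mode = "pretrained-embedding",
                             encoder = enc, cache_path = cache)
  E2 <- encode_drug_features(tab, mode = "pretrained-embedding",
                             cache_path = cache)
  expect_identical(E1, E2)
})

test_that("assemble_network builds a valid six-relation network with ablations", {
  lnc <- matrix(rep(1:4, each = 5) + rnorm(20, sd = 0.01), 5, 4)
  rownames(lnc) <- paste0("L", 1:5)
  mi <- matrix(rnorm(20), 5, 4); rownames(mi) <- paste0("M", 1:5)
  drugs <- data.frame(drug_id = c("D1", "D2", "D3"),
                      smiles = c("CCO", "CCN", "c1ccccc1"),
                      stringsAsFactors = FALSE)
  pl <- function(s, t, lab) {
    out <- data.frame(source_id = s, target_id = t, stringsAsFactors = FALSE)
    attr(out, "relation_label") <- lab
    out
  }
  lm <- pl(c("L1", "L2", "LX"), c("M1", "M3", "M1"), "lncRNA-miRNA")
  ld <- pl(c("L1", "L4"), c("D1", "D2"), "lncRNA-drug")
  md <- pl("M2", "D3", "miRNA-drug")
  net <- assemble_network(structure(lnc, entity_type = "lncRNA"),
                          structure(mi, entity_type = "miRNA"),
                          drugs, lm, ld, md, config = list(task = "LD"))
  expect_silent(validate_network(net))
  expect_equal(nrow(net$edges$lm), 2L)    # unresolvable LX pair dropped
  expect_equal(nrow(net$edges$ld), 2L)
  # empty target association set is a hard error
  expect_error(assemble_network(lnc, mi, drugs, lm, NULL, md,
                                config = list(task = "LD")), "empty target")
  # w/o_LncMi-style ablation removes the non-target ncRNA type entirely
  ab <- assemble_network(lnc, mi, drugs, lm, ld, md,
                         config = list(task = "LD", drop_cross_ncrna = TRUE))
  expect_length(ab$nodes$miRNA, 0)
  expect_equal(nrow(ab$edges$lm), 0L)
  expect_equal(nrow(ab$edges$md), 0L)
  expect_gt(nrow(ab$edges$ld), 0L)
  # one-hot ablation replaces attributes by identity
  oh <- assemble_network(lnc, mi, drugs, lm, ld, md,
                         config = list(task = "LD", one_hot_attributes = TRUE))
  expect_equal(unname(oh$features$lncRNA), diag(5))
})

test_that("network directory round trip preserves the network", {
  net <- rand_net(3)
  dir <- tempfile()
  write_network_dir(net, dir)
  back <- read_network_dir(dir)
  expect_equal(back$nodes, net$nodes)
  for (t in names(net$features)) {
    expect_equal(back$features[[t]], net$features[[t]], tolerance = 1e-15)
  }
  for (r in names(net$edges)) {
    expect_equal(back$edges[[r]]$id_a, net$edges[[r]]$id_a)
    expect_equal(back$edges[[r]]$score, net$edges[[r]]$score)
  }
})

test_that("hetero_network enforces its invariants", {
  expect_error(hetero_network(list(lncRNA = c("a", "a")),
                              list(lncRNA = matrix(0, 2, 1))), "duplicate")
  expect_error(hetero_network(list(lncRNA = "a"),
                              list(lncRNA = matrix(0, 2, 1))), "rows")
  expect_error(hetero_network(list(lncRNA = c("a", "b")),
                              list(lncRNA = matrix(0, 2, 1)),
                              list(ll = data.frame(id_a = "a", id_b = "a"))),
               "self-edge")
  expect_error(hetero_network(list(lncRNA = c("a", "b")),
                              list(lncRNA = matrix(0, 2, 1)),
                              list(ll = data.frame(id_a = "a", id_b = "zz"))),
               "endpoint")
})
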