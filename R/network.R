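# Construction of the six-relation heterogeneous molecular network:
# ncRNA similarity by Kendall tau-b on expression profiles, drug similarity
# by Tanimoto on circular fingerprints (0.5 retention threshold), plus
# lncRNA-miRNA, lncRNA-drug and miRNA-drug cross-type relations.

NODE_TYPES <- c("lncRNA", "miRNA", "drug")
RELATIONS <- c("ll", "mm", "dd", "lm", "ld", "md")

relation_types <- function() {
  data.frame(
    rel    = RELATIONS,
    type_a = c("lncRNA", "miRNA", "drug", "lncRNA", "lncRNA", "miRNA"),
    type_b = c("lncRNA", "miRNA", "drug", "miRNA",  "drug",   "drug"),
    stringsAsFactors = FALSE
  )
}

empty_edges <- function() {
  data.frame(id_a = character(0), id_b = character(0), score = numeric(0),
             stringsAsFactors = FALSE)
}

# Canonicalize an edge table: intra-type pairs stored once with id_a < id_b;
# self-edges forbidden; duplicates collapsed (first score kept).
canonicalize_edges <- function(df, intra) {
  if (nrow(df) == 0) return(empty_edges())
  a <- as.character(df$id_a); b <- as.character(df$id_b)
  s <- if ("score" %in% names(df)) as.numeric(df$score) else rep(1, nrow(df))
  if (any(a == b)) stop("self-edge not allowed: ", a[which(a == b)[1]],
                        call. = FALSE)
  if (intra) {
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  }
  key <- paste(a, b, sep = "\r")
  keep <- !duplicated(key)
  out <- data.frame(id_a = a[keep], id_b = b[keep], score = s[keep],
                    stringsAsFactors = FALSE)
  out[order(out$id_a, out$id_b), , drop = FALSE]
}

#' Construct a heterogeneous molecular network
#'
#' The container consumed by the encoder, the trainer and the attribution
#' module: three typed node sets (lncRNA, miRNA, drug) with per-type
#' attribute matrices, and six undirected relation edge sets
#' `ll, mm, dd, lm, ld, md`.
#'
#' @param nodes Named list of character id vectors for `lncRNA`, `miRNA`,
#'   `drug` (types may be absent or empty).
#' @param features Named list of numeric matrices, one row per node id
#'   (rownames must equal the node ids).
#' @param edges Named list of data.frames with columns `id_a`, `id_b` and
#'   optionally `score`, keyed by relation name.
#' @return An object of class `hetero_network`.
#' @export
hetero_network <- function(nodes, features, edges = list()) {
  nodes <- nodes[intersect(NODE_TYPES, names(nodes))]
  net <- structure(list(nodes = list(), features = list(), edges = list()),
                   class = "hetero_network")
  for (t in NODE_TYPES) {
    ids <- as.character(nodes[[t]] %||% character(0))
    if (anyDuplicated(ids)) {
      stop("duplicate ", t, " id: ", ids[duplicated(ids)][1], call. = FALSE)
    }
    X <- features[[t]]
    if (is.null(X)) X <- matrix(numeric(0), nrow = length(ids), ncol = 0)
    X <- as.matrix(X)
    if (nrow(X) != length(ids)) {
      stop("feature matrix for ", t, " has ", nrow(X), " rows but ",
           length(ids), " node ids", call. = FALSE)
    }
    rownames(X) <- ids
    net$nodes[[t]] <- ids
    net$features[[t]] <- X
  }
  rt <- relation_types()
  for (i in seq_len(nrow(rt))) {
    rel <- rt$rel[i]
    df <- edges[[rel]] %||% empty_edges()
    df <- canonicalize_edges(df, intra = rt$type_a[i] == rt$type_b[i])
    ok_a <- df$id_a %in% net$nodes[[rt$type_a[i]]]
    ok_b <- df$id_b %in% net$nodes[[rt$type_b[i]]]
    if (!all(ok_a & ok_b)) {
      stop("relation ", rel, ": edge endpoint not found in node set (e.g. ",
           df$id_a[!(ok_a & ok_b)][1] %||% df$id_b[!(ok_a & ok_b)][1], ")",
           call. = FALSE)
    }
    net$edges[[rel]] <- df
  }
  net
}

#' Validate heterogeneous-network invariants
#'
#' Checks endpoint resolution, feature-row counts, canonical edge storage,
#' and absence of duplicates/self-edges.  Returns `TRUE` invisibly or stops.
#'
#' @param net A `hetero_network`.
#' @export
validate_network <- function(net) {
  assert_that(inherits(net, "hetero_network"), "not a hetero_network")
  rt <- relation_types()
  for (t in NODE_TYPES) {
    ids <- net$nodes[[t]]
    assert_that(!anyDuplicated(ids), paste("duplicate", t, "ids"))
    assert_that(nrow(net$features[[t]]) == length(ids),
                paste("feature rows !=", t, "node count"))
    assert_that(all(is.finite(net$features[[t]])) || length(ids) == 0,
                paste("non-finite features for", t))
  }
  for (i in seq_len(nrow(rt))) {
    rel <- rt$rel[i]
    df <- net$edges[[rel]]
    assert_that(all(df$id_a %in% net$nodes[[rt$type_a[i]]]),
                paste(rel, "edge id_a unresolved"))
    assert_that(all(df$id_b %in% net$nodes[[rt$type_b[i]]]),
                paste(rel, "edge id_b unresolved"))
    assert_that(!any(df$id_a == df$id_b), paste(rel, "self-edge"))
    if (rt$type_a[i] == rt$type_b[i]) {
      assert_that(all(df$id_a < df$id_b), paste(rel, "not canonically ordered"))
    }
    assert_that(!anyDuplicated(paste(df$id_a, df$id_b)),
                paste(rel, "duplicate edges"))
  }
  invisible(TRUE)
}

#' @export
print.hetero_network <- function(x, ...) {
  cat("Heterogeneous network\n")
  for (t in NODE_TYPES) {
    cat(sprintf("  %-7s %5d nodes, %d features\n", t, length(x$nodes[[t]]),
                ncol(x$features[[t]])))
  }
  for (r in RELATIONS) cat(sprintf("  %-3s %6d edges\n", r, nrow(x$edges[[r]])))
  invisible(x)
}

#' Kendall rank correlation (tau-b)
#'
#' Tie-corrected Kendall correlation between two equal-length vectors, as
#' used to build the ncRNA co-expression similarity networks.  Zero-variance
#' input (all values tied in either vector) has no defined tau; a logged
#' `NA` sentinel is returned so the caller records no edge.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return A scalar in `[-1, 1]`, or `NA` for undefined (zero-variance) input.
#' @export
kendall_tau <- function(x, y) {
  assert_that(length(x) == length(y), "kendall_tau: length mismatch")
  assert_that(length(x) >= 2, "kendall_tau: need at least 2 observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    ncd_log("kendall_tau undefined for zero-variance input; returning NA")
    return(NA_real_)
  }
  unname(stats::cor(x, y, method = "kendall"))
}

#' Build a similarity edge set by thresholded Kendall tau
#'
#' Computes tau-b between every unordered pair of rows of an expression
#' matrix and retains pairs with similarity strictly greater than
#' `threshold` (default 0.5).
#'
#' @param matrix An `expression_matrix` (or any numeric matrix with row ids).
#' @param threshold Retention threshold in `[0, 1)`; strict `>` applied.
#' @param transform Optional transform applied to values first: `"raw"`
#'   (default) or `"log"` (`log1p` of values shifted to be non-negative).
#' @return A data.frame `id_a, id_b, score` (canonical order), with a
#'   `relation` attribute left to the caller.
#' @export
build_similarity_edges <- function(matrix, threshold = 0.5, transform = c("raw", "log")) {
  transform <- match.arg(transform)
  assert_that(threshold >= 0 && threshold < 1, "threshold must be in [0, 1)")
  m <- as.matrix(matrix)
  if (transform == "log") m <- log1p(m - min(m))
  n <- nrow(m)
  ids <- rownames(m) %||% as.character(seq_len(n))
  if (n < 2) {
    warning("fewer than 2 entities; empty similarity edge set", call. = FALSE)
    return(empty_edges())
  }
  res <- vector("list", n * (n - 1) / 2)
  k <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      tau <- kendall_tau(m[i, ], m[j, ])
      if (!is.na(tau) && tau > threshold) {
        k <- k + 1L
        res[[k]] <- list(ids[i], ids[j], tau)
      }
    }
  }
  if (k == 0L) return(empty_edges())
  res <- res[seq_len(k)]
  out <- data.frame(id_a = vapply(res, `[[`, character(1), 1),
                    id_b = vapply(res, `[[`, character(1), 2),
                    score = vapply(res, `[[`, numeric(1), 3),
                    stringsAsFactors = FALSE)
  canonicalize_edges(out, intra = TRUE)
}

#' Circular fingerprint from a SMILES string
#'
#' Computes an ECFP4-style circular fingerprint (radius-2 atom environments)
#' via OpenBabel and folds it to `width` bits by index modulo.  Deterministic
#' for a given `(smiles, width)`; canonical and non-canonical SMILES of the
#' same molecule yield identical bit sets.
#'
#' @param smiles A single SMILES string.
#' @param width Folded fingerprint width in bits (default 2048).
#' @return Object of class `fingerprint`: list with `bits` (0-based sorted
#'   set-bit indices) and `width`.
#' @export
fingerprint_from_smiles <- function(smiles, width = 2048) {
  assert_that(is.character(smiles) && length(smiles) == 1 && nzchar(smiles),
              "smiles must be one non-empty string")
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("ChemmineOB is required for fingerprint computation", call. = FALSE)
  }
  mol <- tryCatch(
    suppressWarnings(ChemmineOB::forEachMol("SMILES", smiles, identity)),
    error = function(e) NULL)
  fp <- if (is.null(mol)) NULL else tryCatch(
    ChemmineOB::fingerprint_OB(mol, "ECFP4"), error = function(e) NULL)
  if (is.null(fp) || !any(fp > 0)) {
    stop("unparsable SMILES: ", smiles, call. = FALSE)
  }
  raw_bits <- which(as.numeric(fp) > 0) - 1L      # 0-based
  bits <- sort(unique(raw_bits %% as.integer(width)))
  structure(list(bits = bits, width = as.integer(width)),
            class = "fingerprint")
}

#' Tanimoto coefficient between two fingerprints
#'
#' `|A intersect B| / |A union B|` over set-bit indices.  Both-empty input is
#' defined as 0 (logged).
#'
#' @param a,b `fingerprint` objects of equal width.
#' @return Scalar in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  assert_that(inherits(a, "fingerprint") && inherits(b, "fingerprint"),
              "tanimoto expects fingerprint objects")
  assert_that(a$width == b$width, "fingerprint width mismatch")
  u <- length(union(a$bits, b$bits))
  if (u == 0) {
    ncd_log("tanimoto of two empty fingerprints defined as 0")
    return(0)
  }
  length(intersect(a$bits, b$bits)) / u
}

#' Encode drug features from SMILES
#'
#' `mode = "fingerprint"` (offline default) returns the folded circular
#' fingerprint as a 0/1 real matrix.  `mode = "pretrained-embedding"` calls a
#' pluggable external encoder function and caches the result to disk; absent
#' an encoder it errors, instructing fallback to fingerprint mode.
#'
#' @param table Data.frame from [load_smiles_table()].
#' @param mode `"fingerprint"` or `"pretrained-embedding"`.
#' @param width Fingerprint width (fingerprint mode).
#' @param encoder Optional function `(smiles_vector) -> matrix` for the
#'   pretrained mode.
#' @param cache_path Optional RDS cache file for the pretrained mode.
#' @return Numeric matrix, one row per drug (rownames = drug ids).  Drugs
#'   with unparsable SMILES get an all-zero row and are flagged in the
#'   `failed` attribute (they are excluded from dd similarity edges).
#' @export
encode_drug_features <- function(table,
                                 mode = c("fingerprint", "pretrained-embedding"),
                                 width = 2048, encoder = NULL,
                                 cache_path = NULL) {
  mode <- match.arg(mode)
  if (mode == "pretrained-embedding") {
    if (!is.null(cache_path) && file.exists(cache_path)) {
      return(readRDS(cache_path))
    }
    if (is.null(encoder)) {
      stop("pretrained-embedding mode needs an `encoder` function (offline ",
           "default is mode = \"fingerprint\")", call. = FALSE)
    }
    emb <- encoder(table$smiles)
    rownames(emb) <- table$drug_id
    if (!is.null(cache_path)) saveRDS(emb, cache_path)
    return(emb)
  }
  out <- matrix(0, nrow(table), width,
                dimnames = list(table$drug_id, NULL))
  failed <- character(0)
  for (i in seq_len(nrow(table))) {
    fp <- tryCatch(fingerprint_from_smiles(table$smiles[i], width),
                   error = function(e) NULL)
    if (is.null(fp)) {
      failed <- c(failed, table$drug_id[i])
    } else {
      out[i, fp$bits + 1L] <- 1
    }
  }
  if (length(failed) > 0) {
    ncd_log(length(failed), " drug(s) with unparsable SMILES excluded from ",
            "similarity: ", paste(failed, collapse = ", "))
  }
  attr(out, "failed") <- failed
  out
}

# Tanimoto similarity edges among drugs from a 0/1 feature matrix.
drug_similarity_edges <- function(fp_matrix, threshold = 0.5,
                                  exclude = character(0)) {
  ids <- rownames(fp_matrix)
  keep <- setdiff(ids, exclude)
  M <- fp_matrix[keep, , drop = FALSE] > 0
  n <- nrow(M)
  if (n < 2) return(empty_edges())
  pop <- rowSums(M)
  inter <- M %*% t(M)                        # pairwise intersection counts
  res <- list(); k <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      u <- pop[i] + pop[j] - inter[i, j]
      s <- if (u == 0) 0 else inter[i, j] / u
      if (s > threshold) {
        k <- k + 1L
        res[[k]] <- list(keep[i], keep[j], s)
      }
    }
  }
  if (k == 0L) return(empty_edges())
  out <- data.frame(id_a = vapply(res, `[[`, character(1), 1),
                    id_b = vapply(res, `[[`, character(1), 2),
                    score = vapply(res, `[[`, numeric(1), 3),
                    stringsAsFactors = FALSE)
  canonicalize_edges(out, intra = TRUE)
}

# Resolve a pair list against node sets, dropping (and counting) pairs with
# unresolvable endpoints.
resolve_pairs <- function(pairs, ids_a, ids_b, label) {
  ok <- pairs$source_id %in% ids_a & pairs$target_id %in% ids_b
  if (any(!ok)) ncd_log(sum(!ok), " unresolvable ", label, " pair(s) dropped")
  pairs[ok, , drop = FALSE]
}

#' Assemble the six-relation heterogeneous network
#'
#' Builds similarity subnetworks from attributes (Kendall tau-b for ncRNAs,
#' Tanimoto for drugs, both thresholded at `config$threshold`, strictly
#' greater) and attaches the three cross-type relations.  Ablation flags:
#' `drop_cross_ncrna` removes the ncRNA type not involved in the target task
#' together with its similarity/interaction/association edges;
#' `one_hot_attributes` replaces all node features with one-hot identity.
#'
#' @param lnc_expr,mi_expr `expression_matrix` objects (either may be `NULL`
#'   when ablated).
#' @param drug_table SMILES data.frame from [load_smiles_table()].
#' @param lm_pairs,ld_pairs,md_pairs `pair_list` objects (may be `NULL`).
#' @param config List: `threshold` (0.5), `fingerprint_width` (2048),
#'   `drug_feature_mode`, `transform` ("raw"/"log"), `drop_cross_ncrna`
#'   (FALSE), `one_hot_attributes` (FALSE), `task` ("LD"/"MD", used by
#'   `drop_cross_ncrna`).
#' @return A validated `hetero_network`.
#' @export
assemble_network <- function(lnc_expr, mi_expr, drug_table,
                             lm_pairs = NULL, ld_pairs = NULL, md_pairs = NULL,
                             config = list()) {
  threshold <- config$threshold %||% 0.5
  width <- config$fingerprint_width %||% 2048
  transform <- config$transform %||% "raw"
  task <- config$task %||% "LD"
  drop_cross <- isTRUE(config$drop_cross_ncrna)
  if (drop_cross) {
    if (task == "LD") mi_expr <- NULL else lnc_expr <- NULL
    lm_pairs <- NULL
    if (task == "LD") md_pairs <- NULL else ld_pairs <- NULL
  }
  target_pairs <- if (task == "LD") ld_pairs else md_pairs
  if (is.null(target_pairs) || nrow(target_pairs) == 0) {
    stop("empty target association set for task ", task, call. = FALSE)
  }

  nodes <- list(); features <- list(); edges <- list()
  if (!is.null(lnc_expr)) {
    nodes$lncRNA <- rownames(lnc_expr)
    features$lncRNA <- unclass(lnc_expr)
    edges$ll <- build_similarity_edges(lnc_expr, threshold, transform)
  }
  if (!is.null(mi_expr)) {
    nodes$miRNA <- rownames(mi_expr)
    features$miRNA <- unclass(mi_expr)
    edges$mm <- build_similarity_edges(mi_expr, threshold, transform)
  }
  fp <- encode_drug_features(drug_table,
                             mode = config$drug_feature_mode %||% "fingerprint",
                             width = width, encoder = config$drug_encoder,
                             cache_path = config$drug_feature_cache)
  nodes$drug <- drug_table$drug_id
  features$drug <- fp
  edges$dd <- drug_similarity_edges(fp, threshold,
                                    exclude = attr(fp, "failed") %||% character(0))

  if (!is.null(lm_pairs)) {
    p <- resolve_pairs(lm_pairs, nodes$lncRNA, nodes$miRNA, "lm")
    edges$lm <- data.frame(id_a = p$source_id, id_b = p$target_id, score = 1)
  }
  if (!is.null(ld_pairs)) {
    p <- resolve_pairs(ld_pairs, nodes$lncRNA, nodes$drug, "ld")
    edges$ld <- data.frame(id_a = p$source_id, id_b = p$target_id, score = 1)
  }
  if (!is.null(md_pairs)) {
    p <- resolve_pairs(md_pairs, nodes$miRNA, nodes$drug, "md")
    edges$md <- data.frame(id_a = p$source_id, id_b = p$target_id, score = 1)
  }

  if (isTRUE(config$one_hot_attributes)) {
    for (t in names(nodes)) {
      n <- length(nodes[[t]])
      features[[t]] <- diag(n)
      rownames(features[[t]]) <- nodes[[t]]
    }
  }
  net <- hetero_network(nodes, features, edges)
  validate_network(net)
  net
}

#' Serialize / load a network directory
#'
#' Writes `nodes_{type}.tsv`, `features_{type}.tsv` (id + numeric columns)
#' and `edges_{relation}.tsv` (`id_a`, `id_b`, `score`) under `dir`.
#'
#' @param net A `hetero_network`.
#' @param dir Directory (created if needed).
#' @export
write_network_dir <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (t in NODE_TYPES) {
    if (length(net$nodes[[t]]) == 0) next
    utils::write.table(data.frame(id = net$nodes[[t]]),
                       file.path(dir, paste0("nodes_", t, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    X <- net$features[[t]]
    vals <- apply(X, 2, function(col) sprintf("%.17g", col))
    vals <- matrix(vals, nrow = nrow(X),
                   dimnames = list(NULL, paste0("f", seq_len(ncol(X)))))
    df <- data.frame(id = net$nodes[[t]], vals,
                     stringsAsFactors = FALSE, check.names = FALSE)
    utils::write.table(df, file.path(dir, paste0("features_", t, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  for (r in RELATIONS) {
    utils::write.table(net$edges[[r]],
                       file.path(dir, paste0("edges_", r, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' @rdname write_network_dir
#' @export
read_network_dir <- function(dir) {
  nodes <- list(); features <- list(); edges <- list()
  for (t in NODE_TYPES) {
    nf <- file.path(dir, paste0("nodes_", t, ".tsv"))
    if (!file.exists(nf)) next
    nodes[[t]] <- utils::read.table(nf, sep = "\t", header = TRUE,
                                    stringsAsFactors = FALSE)$id
    ff <- file.path(dir, paste0("features_", t, ".tsv"))
    fd <- utils::read.table(ff, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, check.names = FALSE)
    X <- as.matrix(fd[, -1, drop = FALSE])
    storage.mode(X) <- "double"
    dimnames(X) <- list(fd$id, NULL)
    features[[t]] <- X
  }
  for (r in RELATIONS) {
    ef <- file.path(dir, paste0("edges_", r, ".tsv"))
    if (file.exists(ef)) {
      edges[[r]] <- utils::read.table(ef, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE,
                                      colClasses = c("character", "character",
                                                     "numeric"))
    }
  }
  hetero_network(nodes, features, edges)
}
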