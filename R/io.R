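# Readers/writers for tabular inputs, checkpoints and metric reports.

CHECKPOINT_FORMAT <- "ncdlink-checkpoint-1"

# Delimiter auto-detection between tab and comma, based on the header line.
detect_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0) stop("empty file: ", path, call. = FALSE)
  n_tab <- lengths(regmatches(first, gregexpr("\t", first)))
  n_com <- lengths(regmatches(first, gregexpr(",", first)))
  if (n_tab >= n_com) "\t" else ","
}

#' Load an ncRNA expression matrix
#'
#' Reads a delimited table whose first column holds entity identifiers and
#' whose remaining columns are numeric expression values (one column per
#' cancer cell line).  Identifiers are treated as opaque, case-sensitive
#' strings.  Rows containing any missing value are dropped with a warning
#' rather than imputed; duplicated identifiers are a hard error.
#'
#' @param path Path to a TSV/CSV file (delimiter auto-detected).
#' @param entity_type `"lncRNA"` or `"miRNA"`; recorded on the result.
#' @param header Does the file carry a header line? Default `TRUE`.
#' @return An object of class `expression_matrix`: a numeric matrix with
#'   entity ids as rownames and an `entity_type` attribute.
#' @export
load_expression_matrix <- function(path, entity_type = c("lncRNA", "miRNA"),
                                   header = TRUE) {
  entity_type <- match.arg(entity_type)
  delim <- detect_delim(path)
  df <- utils::read.table(path, sep = delim, header = header,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = NA, comment.char = "")
  if (nrow(df) == 0 || ncol(df) < 2) {
    stop("expression file has no data rows or no value columns: ", path,
         call. = FALSE)
  }
  ids <- as.character(df[[1]])
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate entity id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(!is.na(col) & is.na(num) & col != "NA")
      if (length(bad) > 0) {
        stop(sprintf("non-numeric value at row %d, column %d of %s",
                     bad[1], j + 1, path), call. = FALSE)
      }
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  incomplete <- !stats::complete.cases(m)
  if (any(incomplete)) {
    warning(sprintf("dropping %d row(s) with missing values from %s",
                    sum(incomplete), path), call. = FALSE)
    m <- m[!incomplete, , drop = FALSE]
    ids <- ids[!incomplete]
  }
  if (nrow(m) == 0) stop("no complete rows left in ", path, call. = FALSE)
  rownames(m) <- ids
  structure(m, entity_type = entity_type, class = c("expression_matrix", class(m)))
}

#' Load a drug SMILES table
#'
#' Two-column delimited file: drug identifier and SMILES string.
#'
#' @param path File path.
#' @param header Does the file carry a header line? Default `TRUE`.
#' @return A data.frame with columns `drug_id`, `smiles`.
#' @export
load_smiles_table <- function(path, header = TRUE) {
  delim <- detect_delim(path)
  df <- utils::read.table(path, sep = delim, header = header,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "", quote = "")
  if (ncol(df) < 2) stop("SMILES table needs two columns: ", path, call. = FALSE)
  smiles <- as.character(df[[2]])
  smiles[is.na(smiles)] <- ""
  out <- data.frame(drug_id = as.character(df[[1]]),
                    smiles = smiles,
                    stringsAsFactors = FALSE)
  dup <- out$drug_id[duplicated(out$drug_id)]
  if (length(dup) > 0) {
    stop("duplicate drug id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (any(!nzchar(out$smiles))) {
    stop("empty SMILES string for drug(s): ",
         paste(out$drug_id[!nzchar(out$smiles)], collapse = ", "), call. = FALSE)
  }
  out
}

#' Load a two-column pair list
#'
#' Reads association/interaction pairs (e.g. lncRNA-drug resistance pairs).
#' Duplicate pairs are removed with a logged count; self-pairs are an error.
#'
#' @param path File path.
#' @param relation_label One of `"lncRNA-drug"`, `"miRNA-drug"`,
#'   `"lncRNA-miRNA"`.
#' @param header Does the file carry a header line? Default `TRUE`.
#' @return A `pair_list`: data.frame with columns `source_id`, `target_id`
#'   and a `relation_label` attribute.
#' @export
load_pair_list <- function(path,
                           relation_label = c("lncRNA-drug", "miRNA-drug",
                                              "lncRNA-miRNA"),
                           header = TRUE) {
  relation_label <- match.arg(relation_label)
  delim <- detect_delim(path)
  lines <- readLines(path, warn = FALSE)
  if (header) lines <- lines[-1]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("no pairs in ", path, call. = FALSE)
  parts <- strsplit(lines, delim, fixed = TRUE)
  bad <- which(lengths(parts) < 2)
  if (length(bad) > 0) {
    stop(sprintf("malformed row at line %d of %s", bad[1] + as.integer(header),
                 path), call. = FALSE)
  }
  src <- vapply(parts, `[[`, character(1), 1)
  tgt <- vapply(parts, `[[`, character(1), 2)
  if (any(src == tgt)) {
    i <- which(src == tgt)[1]
    stop(sprintf("self-pair (%s, %s) at line %d of %s", src[i], tgt[i],
                 i + as.integer(header), path), call. = FALSE)
  }
  key <- paste(src, tgt, sep = "\r")
  dups <- duplicated(key)
  if (any(dups)) ncd_log(sum(dups), " duplicate pair(s) dropped from ", path)
  out <- data.frame(source_id = src[!dups], target_id = tgt[!dups],
                    stringsAsFactors = FALSE)
  attr(out, "relation_label") <- relation_label
  class(out) <- c("pair_list", class(out))
  out
}

#' Save / load a model checkpoint
#'
#' A checkpoint stores all encoder and decoder weights together with the
#' training configuration; a round trip reproduces every weight bit-exactly.
#' Checkpoints carry a format version; loading a checkpoint written by an
#' incompatible format is a hard error.
#'
#' @param object A fitted `ncd_model` (or any list of finite parameter
#'   matrices plus config).
#' @param path Destination file.
#' @export
save_checkpoint <- function(object, path) {
  if (!is.null(object$params)) {
    assert_that(tree_all_finite(object$params),
                "refusing to checkpoint non-finite parameters")
  }
  saveRDS(list(format = CHECKPOINT_FORMAT, payload = object), file = path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop("unreadable checkpoint ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  if (!is.list(obj) || !identical(obj$format, CHECKPOINT_FORMAT)) {
    stop("checkpoint format mismatch in ", path, " (expected ",
         CHECKPOINT_FORMAT, ")", call. = FALSE)
  }
  obj$payload
}

#' Write a metrics report as flat JSON
#'
#' Flattens a metrics report (see [evaluate_split()]) into a single JSON
#' object keyed by metric name and k, e.g. `"precision_at_10"`.
#'
#' @param report A `metrics_report`.
#' @param path Destination JSON file.
#' @export
write_metrics_report <- function(report, path) {
  flat <- list(auc = report$auc, aupr = report$aupr,
               n_pos = report$n_pos, n_neg = report$n_neg)
  for (nm in c("precision_at_k", "recall_at_k", "ndcg_at_k")) {
    vals <- report[[nm]]
    stem <- sub("_k$", "", nm)
    for (k in names(vals)) flat[[paste0(stem, "_", k)]] <- vals[[k]]
  }
  jsonlite::write_json(flat, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
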