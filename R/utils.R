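# Internal helpers: activations, seeded RNG scopes, parameter-tree arithmetic.

`%||%` <- function(a, b) if (is.null(a)) b else a

leaky_relu <- function(x, slope = 0.01) {
  ifelse(x > 0, x, slope * x)
}

# Subgradient convention: slope at exactly zero (consistent forward/backward).
leaky_relu_grad <- function(x, slope = 0.01) {
  ifelse(x > 0, 1, slope)
}

ncd_verbose <- function() isTRUE(getOption("ncdlink.verbose", TRUE))

ncd_log <- function(...) {
  if (ncd_verbose()) message("ncdlink: ", ...)
  invisible(NULL)
}

#' @noRd
assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  assert_that(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
              "seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Counter-based seed splitting: derive independent, reproducible sub-stream
# seeds from one master seed.  Kept inside 32-bit signed range.
child_seed <- function(seed, index) {
  s <- (as.double(seed) %% 2147483647) + 1
  x <- (s * 48271) %% 2147483647
  x <- (x + as.double(index) * 69621) %% 2147483647
  as.integer(x)
}

# ---- parameter trees: nested lists with numeric (matrix/vector) leaves ----

tree_map <- function(f, x) {
  if (is.list(x)) lapply(x, function(e) tree_map(f, e)) else f(x)
}

tree_map2 <- function(f, x, y) {
  if (is.list(x)) {
    out <- vector("list", length(x))
    names(out) <- names(x)
    for (i in seq_along(x)) out[[i]] <- tree_map2(f, x[[i]], y[[i]])
    out
  } else {
    f(x, y)
  }
}

tree_zero_like <- function(x) tree_map(function(e) e * 0, x)

tree_leaves <- function(x) {
  if (is.list(x)) unlist(lapply(x, tree_leaves), use.names = FALSE) else list(x)
}

tree_all_finite <- function(x) {
  if (is.list(x)) all(vapply(x, tree_all_finite, logical(1))) else all(is.finite(x))
}

# Glorot-uniform init scaled by fan-in/fan-out.
glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# Stable log(1 + exp(x)).
log1pexp <- function(x) {
  ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
}

sigmoid <- function(x) 1 / (1 + exp(-x))
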