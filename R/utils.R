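# Small numerical helpers shared across the networks.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Row-wise softmax
#' @param x numeric matrix of logits.
#' @return matrix of the same shape whose rows sum to 1.
#' @keywords internal
softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' All stochastic operations in the package route their randomness through
#' this helper so that no call mutates the caller's RNG state.
#' @keywords internal
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

# Uniform(-r, r) matrix initialisation used for all weight matrices.
runif_mat <- function(nr, nc, r) {
  matrix(stats::runif(nr * nc, -r, r), nrow = nr, ncol = nc)
}

# Glorot-style range for a weight matrix with the given fan-in/out.
glorot_r <- function(fan_in, fan_out) sqrt(6 / (fan_in + fan_out))

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop("non-finite values in ", what, call. = FALSE)
}

# Map over two parallel nested lists of numeric arrays, preserving structure.
nl_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- mapply(nl_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    names(out) <- names(a)
    out
  } else {
    f(a, b)
  }
}

nl_map <- function(a, f) {
  if (is.list(a)) {
    out <- lapply(a, nl_map, f = f)
    names(out) <- names(a)
    out
  } else {
    f(a)
  }
}

# Sum of all elements across a nested list of arrays.
nl_sum <- function(a) {
  if (is.list(a)) sum(vapply(a, nl_sum, numeric(1))) else sum(a)
}

# Zero-filled copy of a nested parameter list.
nl_zeros <- function(a) nl_map(a, function(x) x * 0)
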