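# BiLSTM post encoder: encodes each post's (frozen) word embeddings into a
# fixed vector p^t = [h_fwd_final ; h_bwd_final] of dimension 2u. PAD
# positions (token id 0) are masked: the recurrence carries the state
# through them unchanged, so right-padding never alters the encoding and
# an all-PAD post encodes to the zero vector.
#
# The backward pass (truncated nowhere — full BPTT over the padded length)
# is hand-derived and validated against finite differences in the tests.

lstm_dir_init <- function(d, u, seed) {
  with_seed(seed, {
    r <- glorot_r(u + d, u)
    list(Wf = runif_mat(u + d, u, r), Wi = runif_mat(u + d, u, r),
         Wo = runif_mat(u + d, u, r), Wc = runif_mat(u + d, u, r),
         # forget-gate bias starts at 1 to ease early gradient flow
         bf = rep(1, u), bi = numeric(u), bo = numeric(u), bc = numeric(u))
  })
}

#' Initialise BiLSTM parameters
#'
#' @param d input (word-embedding) dimension.
#' @param u hidden units per direction (default 200).
#' @param seed RNG seed.
#' @return a `bilstm` object with forward/backward direction parameters.
#' @export
bilstm_init <- function(d, u = 200L, seed = 1L) {
  structure(list(fwd = lstm_dir_init(d, u, seed),
                 bwd = lstm_dir_init(d, u, seed + 1L),
                 d = as.integer(d), u = as.integer(u)),
            class = "bilstm")
}

#' @export
print.bilstm <- function(x, ...) {
  cat(sprintf("<bilstm: d=%d, u=%d (post vectors of dimension %d)>\n",
              x$d, x$u, 2L * x$u))
  invisible(x)
}

#' One LSTM step
#'
#' Standard LSTM cell on the concatenation `[h_prev, x]`: sigmoid forget /
#' input / output gates, tanh candidate, `c = f*c_prev + i*g`,
#' `h = o * tanh(c)`.
#'
#' @param x input vector (embedding of the current token).
#' @param h_prev,c_prev previous hidden and cell state (length `u`).
#' @param params one direction's parameter list (`Wf`, `Wi`, `Wo`, `Wc`,
#'   `bf`, `bi`, `bo`, `bc`), e.g. `bilstm$fwd`.
#' @return list with `h` and `c`.
#' @export
lstm_step <- function(x, h_prev, c_prev, params) {
  u <- length(h_prev)
  if (length(c_prev) != u) stop("h_prev and c_prev lengths differ", call. = FALSE)
  if (nrow(params$Wf) != u + length(x))
    stop("parameter shape mismatch: expected input of length ",
         nrow(params$Wf) - u, ", got ", length(x), call. = FALSE)
  hx <- c(h_prev, x)
  f <- sigmoid(drop(hx %*% params$Wf) + params$bf)
  i <- sigmoid(drop(hx %*% params$Wi) + params$bi)
  o <- sigmoid(drop(hx %*% params$Wo) + params$bo)
  g <- tanh(drop(hx %*% params$Wc) + params$bc)
  c_new <- f * c_prev + i * g
  list(h = o * tanh(c_new), c = c_new)
}

# Batched one-direction pass over embedding blocks (list of B x d matrices,
# one per position) in the given position order, carrying state through
# masked (PAD) positions. Returns the final hidden state and step caches.
lstm_run_dir <- function(blocks, mask, order, params, u, want_cache = FALSE) {
  B <- nrow(mask)
  h <- matrix(0, B, u); c <- matrix(0, B, u)
  cache <- if (want_cache) vector("list", length(order)) else NULL
  for (step in seq_along(order)) {
    k <- order[[step]]
    HX <- cbind(h, blocks[[k]])
    f <- sigmoid(HX %*% params$Wf + rep(params$bf, each = B))
    i <- sigmoid(HX %*% params$Wi + rep(params$bi, each = B))
    o <- sigmoid(HX %*% params$Wo + rep(params$bo, each = B))
    g <- tanh(HX %*% params$Wc + rep(params$bc, each = B))
    c_new <- f * c + i * g
    tanh_c <- tanh(c_new)
    h_new <- o * tanh_c
    m <- mask[, k]
    if (want_cache)
      cache[[step]] <- list(HX = HX, f = f, i = i, o = o, g = g,
                            c_prev = c, tanh_c = tanh_c, m = m)
    h <- h_new * m + h * (1 - m)
    c <- c_new * m + c * (1 - m)
  }
  list(h = h, cache = cache)
}

# BPTT for one direction. dh_final is B x u; gradient flows only through
# unmasked steps; embeddings are frozen so input gradients are dropped.
lstm_backward_dir <- function(cache, dh_final, params, u) {
  gr <- nl_zeros(params)
  dh <- dh_final
  dc <- matrix(0, nrow(dh_final), u)
  for (step in rev(seq_along(cache))) {
    cc <- cache[[step]]
    m <- cc$m
    dh_k <- dh * m
    dc_k <- dc * m
    do_ <- dh_k * cc$tanh_c
    dz_o <- do_ * cc$o * (1 - cc$o)
    dc_tot <- dc_k + dh_k * cc$o * (1 - cc$tanh_c^2)
    dz_f <- (dc_tot * cc$c_prev) * cc$f * (1 - cc$f)
    dz_i <- (dc_tot * cc$g) * cc$i * (1 - cc$i)
    dz_g <- (dc_tot * cc$i) * (1 - cc$g^2)
    gr$Wf <- gr$Wf + crossprod(cc$HX, dz_f); gr$bf <- gr$bf + colSums(dz_f)
    gr$Wi <- gr$Wi + crossprod(cc$HX, dz_i); gr$bi <- gr$bi + colSums(dz_i)
    gr$Wo <- gr$Wo + crossprod(cc$HX, dz_o); gr$bo <- gr$bo + colSums(dz_o)
    gr$Wc <- gr$Wc + crossprod(cc$HX, dz_g); gr$bc <- gr$bc + colSums(dz_g)
    dHX <- dz_f %*% t(params$Wf) + dz_i %*% t(params$Wi) +
      dz_o %*% t(params$Wo) + dz_g %*% t(params$Wc)
    dh <- dHX[, seq_len(u), drop = FALSE] + dh * (1 - m)
    dc <- dc_tot * cc$f + dc * (1 - m)
  }
  gr
}

# Batched BiLSTM encoding of a B x n id matrix -> B x 2u post vectors.
bilstm_encode_batch <- function(ids, vocab, params, want_cache = FALSE) {
  B <- nrow(ids); n <- ncol(ids)
  emb <- vocab$embeddings[c(ids) + 1L, , drop = FALSE]
  blocks <- lapply(seq_len(n), function(k)
    emb[((k - 1L) * B + 1L):(k * B), , drop = FALSE])
  mask <- matrix(as.numeric(ids != 0L), B, n)
  fw <- lstm_run_dir(blocks, mask, seq_len(n), params$fwd, params$u, want_cache)
  bw <- lstm_run_dir(blocks, mask, rev(seq_len(n)), params$bwd, params$u, want_cache)
  P <- cbind(fw$h, bw$h)
  if (want_cache)
    attr(P, "cache") <- list(fwd = fw$cache, bwd = bw$cache, u = params$u)
  P
}

# Gradients of BiLSTM parameters given dP (B x 2u) and the forward cache.
bilstm_backward_batch <- function(cache, dP, params) {
  u <- cache$u
  list(fwd = lstm_backward_dir(cache$fwd, dP[, seq_len(u), drop = FALSE],
                               params$fwd, u),
       bwd = lstm_backward_dir(cache$bwd, dP[, u + seq_len(u), drop = FALSE],
                               params$bwd, u))
}

#' Encode posts with the BiLSTM
#'
#' Runs the forward direction over the non-PAD prefix and the backward
#' direction over its reverse, and concatenates the two final hidden
#' states. An all-PAD post encodes to the zero vector (documented
#' degenerate case).
#'
#' @param token_ids integer vector of 0-based token ids for one post, or a
#'   `B x n` matrix for a batch.
#' @param vocab the `vocabulary` holding the embeddings.
#' @param params a `bilstm`.
#' @return numeric vector of length `2u` (or a `B x 2u` matrix).
#' @export
bilstm_encode <- function(token_ids, vocab, params) {
  if (is.matrix(token_ids)) return(bilstm_encode_batch(token_ids, vocab, params))
  drop(bilstm_encode_batch(matrix(as.integer(token_ids), nrow = 1L),
                           vocab, params))
}
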