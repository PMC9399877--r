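# Sentence-level attention over the selected posts, fusion with the
# user-level emotion vector, and the final 2-class softmax classifier.
#
# Scoring follows the hierarchical-attention design: a tanh projection
# u_t = tanh(W_s p_t + b_s) scored against a trainable context vector u_s,
# softmax-normalised over the non-PAD slots. A bilinear form (no tanh, no
# bias) is available behind `form = "bilinear"`.

#' Initialise sentence-level attention parameters
#'
#' @param in_dim dimension of the post vectors (2u).
#' @param a_dim dimension of the projected space and the context vector.
#' @param seed RNG seed (the context vector `u_s` is randomly initialised
#'   and trained with the rest of the model).
#' @return list with `W_s`, `b_s`, `u_s`.
#' @export
attention_init <- function(in_dim, a_dim = in_dim, seed = 1L) {
  with_seed(seed, {
    list(W_s = runif_mat(in_dim, a_dim, glorot_r(in_dim, a_dim)),
         b_s = numeric(a_dim),
         u_s = stats::runif(a_dim, -0.1, 0.1))
  })
}

#' Initialise the fused output classifier
#'
#' @param in_dim dimension of the fused representation
#'   (`2u + d_e`, or `2u` when the emotion network is ablated).
#' @param seed RNG seed.
#' @return list with `W` (`in_dim x 2`) and `b` (length 2). Output order is
#'   (non-depressed, depressed).
#' @export
classifier_init <- function(in_dim, seed = 1L) {
  with_seed(seed, list(W = runif_mat(in_dim, 2L, glorot_r(in_dim, 2L)),
                       b = numeric(2L)))
}

#' Attention weights over selected posts
#'
#' Computes the masked softmax attention distribution: PAD slots get
#' weight exactly 0 and the remaining weights sum to 1.
#'
#' @param post_vectors `M x 2u` matrix of (padded) selected post vectors.
#' @param params attention parameters from [attention_init()].
#' @param mask logical vector of length `M`, `TRUE` for real posts;
#'   defaults to all `TRUE`.
#' @param form `"tanh"` (tanh-projected dot product, default) or
#'   `"bilinear"`.
#' @return numeric weight vector of length `M`.
#' @export
attention_weights <- function(post_vectors, params, mask = NULL,
                              form = c("tanh", "bilinear")) {
  form <- match.arg(form)
  P <- if (is.matrix(post_vectors)) post_vectors else matrix(post_vectors, nrow = 1L)
  M <- nrow(P)
  if (is.null(mask)) mask <- rep(TRUE, M)
  if (!any(mask)) stop("attention needs at least one non-PAD post", call. = FALSE)
  ut <- if (form == "tanh")
    tanh(P %*% params$W_s + rep(params$b_s, each = M))
  else
    P %*% params$W_s
  logits <- as.numeric(ut %*% params$u_s)
  logits[!mask] <- -Inf
  w <- exp(logits - max(logits[mask]))
  w[!mask] <- 0
  w / sum(w)
}

#' Attention pooling
#'
#' Weighted sum of post vectors under an attention distribution.
#'
#' @param post_vectors `M x 2u` matrix.
#' @param weights attention weights of length `M`.
#' @return pooled vector of length `2u`.
#' @export
attention_pool <- function(post_vectors, weights) {
  P <- if (is.matrix(post_vectors)) post_vectors else matrix(post_vectors, nrow = 1L)
  drop(crossprod(P, weights))
}

#' Classify one user from the pooled posts and the emotion expectation
#'
#' Concatenates the attention-pooled post representation with `v_emo` and
#' applies a 2-class softmax layer.
#'
#' @param pooled attention-pooled post vector.
#' @param v_emo user emotion expectation, or `NULL` when the emotion
#'   network is ablated.
#' @param params classifier parameters from [classifier_init()].
#' @return named probability vector `(nondepressed, depressed)` summing to 1.
#' @export
classify_user <- function(pooled, v_emo, params) {
  fused <- c(pooled, v_emo)
  if (length(fused) != nrow(params$W))
    stop("fused representation has dimension ", length(fused),
         ", classifier expects ", nrow(params$W), call. = FALSE)
  p <- softmax_vec(drop(fused %*% params$W) + params$b)
  stats::setNames(p, c("nondepressed", "depressed"))
}

#' Categorical cross-entropy loss
#'
#' `-mean_i log(probs[i, gold_i])` over the batch (averaging, rather than
#' the plain sum over users, keeps the scale independent of batch size; the
#' constant factor is absorbed by the learning rate).
#'
#' @param probs `B x 2` matrix of class probabilities, columns
#'   (nondepressed, depressed); rows must sum to 1.
#' @param labels integer vector of gold labels in \{0, 1\}.
#' @return non-negative scalar; 0 iff every prediction is one-hot correct.
#' @export
classification_loss <- function(probs, labels) {
  if (!is.matrix(probs)) probs <- matrix(probs, nrow = 1L)
  stopifnot(ncol(probs) == 2L, nrow(probs) == length(labels))
  p_gold <- probs[cbind(seq_len(nrow(probs)), as.integer(labels) + 1L)]
  if (any(p_gold < 1e-12)) {
    warning("clamping zero gold-class probabilities to 1e-12")
    p_gold <- pmax(p_gold, 1e-12)
  }
  -mean(log(p_gold))
}

# --- internal fused head: forward + backward -------------------------------

# Forward pass of attention + fusion + softmax for one user.
# P: M x 2u selected-post vectors (possibly 0 rows = empty selection, in
# which case the pooled vector is zero); v_emo may be NULL (emotion
# ablation); uniform = TRUE replaces attention with plain averaging.
head_forward <- function(P, v_emo, att, cls, uniform = FALSE, form = "tanh") {
  M <- if (is.null(P)) 0L else nrow(P)
  dim2u <- nrow(cls$W) - length(v_emo)
  if (M == 0L) {
    w <- numeric(0)
    pooled <- numeric(dim2u)
  } else if (uniform) {
    w <- rep(1 / M, M)
    pooled <- attention_pool(P, w)
  } else {
    w <- attention_weights(P, att, form = form)
    pooled <- attention_pool(P, w)
  }
  fused <- c(pooled, v_emo)
  logits <- drop(fused %*% cls$W) + cls$b
  probs <- stats::setNames(softmax_vec(logits), c("nondepressed", "depressed"))
  list(probs = probs, weights = w, pooled = pooled, fused = fused,
       cache = list(P = P, w = w, fused = fused, M = M, dim2u = dim2u,
                    uniform = uniform, form = form))
}

# Backward pass given dlogits (length 2). Returns gradients for the
# attention and classifier parameters plus dP (M x 2u) for BPTT into the
# encoder. v_emo is produced by the frozen emotion net; its gradient is
# dropped.
head_backward <- function(cache, dlogits, att, cls) {
  fused <- cache$fused
  dW <- outer(fused, dlogits)
  db <- dlogits
  dfused <- drop(cls$W %*% dlogits)
  dpooled <- dfused[seq_len(cache$dim2u)]
  datt <- list(W_s = att$W_s * 0, b_s = att$b_s * 0, u_s = att$u_s * 0)
  if (cache$M == 0L)
    return(list(datt = datt, dcls = list(W = dW, b = db),
                dP = matrix(0, 0L, cache$dim2u)))
  P <- cache$P
  w <- cache$w
  dP <- outer(w, dpooled)               # direct path through the weighted sum
  if (!cache$uniform) {
    dw <- drop(P %*% dpooled)           # d pooled / d w_t = p_t . dpooled
    dlog <- w * (dw - sum(w * dw))      # softmax backward
    if (cache$form == "tanh") {
      ut <- tanh(P %*% att$W_s + rep(att$b_s, each = cache$M))
      datt$u_s <- drop(crossprod(ut, dlog))
      dz <- outer(dlog, att$u_s) * (1 - ut^2)
      datt$W_s <- crossprod(P, dz)
      datt$b_s <- colSums(dz)
      dP <- dP + dz %*% t(att$W_s)
    } else {
      ut <- P %*% att$W_s
      datt$u_s <- drop(crossprod(ut, dlog))
      dut <- outer(dlog, att$u_s)
      datt$W_s <- crossprod(P, dut)
      dP <- dP + dut %*% t(att$W_s)
    }
  }
  list(datt = datt, dcls = list(W = dW, b = db), dP = dP)
}
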