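# Emotion extraction network: a convolutional text classifier (TextCNN)
# pretrained on a 3-class emotion task (positive/negative/neutral). Its
# last fully-connected hidden layer is the per-post emotion vector e^t;
# the arithmetic mean of a user's e^t is the user-level emotion
# representation v_emo. After pretraining the network is frozen.
#
# Forward/backward passes are written batched in base R: convolution is a
# matrix product of unfolded embedding windows with the filter bank,
# followed by ReLU and max-over-time pooling, one fully-connected ReLU
# layer, and a 3-class head (per-class sigmoid by default, softmax behind
# a switch).

#' Single convolution feature
#'
#' Applies one filter to one window of word embeddings:
#' `activation(sum(filter * window) + bias)`.
#'
#' @param window `h x d` matrix of consecutive word embeddings.
#' @param filter `h x d` matrix (one convolution kernel).
#' @param bias scalar.
#' @param activation elementwise nonlinearity (default ReLU).
#' @return scalar feature.
#' @export
conv_feature <- function(window, filter, bias, activation = function(x) pmax(x, 0)) {
  window <- as.matrix(window); filter <- as.matrix(filter)
  if (!all(dim(window) == dim(filter)))
    stop("window and filter shapes differ: ",
         paste(dim(window), collapse = "x"), " vs ",
         paste(dim(filter), collapse = "x"), call. = FALSE)
  activation(sum(filter * window) + bias)
}

#' Feature map of one filter over a post
#'
#' Slides a height-`h` filter over the `n` embedded tokens, producing
#' `n - h + 1` features.
#'
#' @param X `n x d` matrix of word embeddings for one post.
#' @param filter `h x d` matrix.
#' @param bias scalar.
#' @param activation elementwise nonlinearity (default ReLU).
#' @return numeric vector of length `n - h + 1`.
#' @export
conv_feature_map <- function(X, filter, bias, activation = function(x) pmax(x, 0)) {
  h <- nrow(filter)
  n <- nrow(X)
  if (n < h) stop("post too short for filter height ", h,
                  "; pad posts to n >= max filter height", call. = FALSE)
  vapply(seq_len(n - h + 1L), function(j)
    conv_feature(X[j:(j + h - 1L), , drop = FALSE], filter, bias, activation),
    numeric(1))
}

#' Max-over-time pooling
#'
#' @param feature_map non-empty numeric vector (one filter's feature map).
#' @return the maximum entry.
#' @export
max_over_time <- function(feature_map) {
  if (length(feature_map) == 0L)
    stop("empty feature map: pad posts to n >= max filter height", call. = FALSE)
  max(feature_map)
}

#' Initialise TextCNN parameters
#'
#' @param d word-embedding dimension.
#' @param n padded post length (must be >= the largest filter height).
#' @param heights three distinct filter heights (default 3, 4, 5).
#' @param Z number of filters per height (default 100).
#' @param d_e dimension of the fully-connected hidden layer — the emotion
#'   vector (default 128).
#' @param head `"sigmoid"` (independent per-class sigmoid, the default) or
#'   `"softmax"` for the 3-class output layer.
#' @param seed RNG seed for initialisation.
#' @return a `textcnn` object (untrained).
#' @export
textcnn_init <- function(d, n, heights = c(3L, 4L, 5L), Z = 100L, d_e = 128L,
                         head = c("sigmoid", "softmax"), seed = 1L) {
  head <- match.arg(head)
  heights <- as.integer(heights)
  if (length(heights) != 3L || anyDuplicated(heights))
    stop("exactly 3 distinct filter heights are required", call. = FALSE)
  if (n < max(heights))
    stop("padded length n (", n, ") must be >= max filter height (",
         max(heights), ")", call. = FALSE)
  params <- with_seed(seed, {
    filt <- lapply(heights, function(h)
      runif_mat(h * d, Z, glorot_r(h * d, Z)))
    names(filt) <- paste0("h", heights)
    fb <- lapply(heights, function(h) numeric(Z))
    names(fb) <- paste0("h", heights)
    nZ <- length(heights) * Z
    list(filters = filt, fbias = fb,
         W_fc = runif_mat(nZ, d_e, glorot_r(nZ, d_e)), b_fc = numeric(d_e),
         W_out = runif_mat(d_e, 3L, glorot_r(d_e, 3L)), b_out = numeric(3L))
  })
  structure(list(params = params, d = as.integer(d), n = as.integer(n),
                 heights = heights, Z = as.integer(Z), d_e = as.integer(d_e),
                 head = head),
            class = "textcnn")
}

#' @export
print.textcnn <- function(x, ...) {
  cat(sprintf("<textcnn: d=%d, n=%d, heights=%s, Z=%d, d_e=%d, %s head>\n",
              x$d, x$n, paste(x$heights, collapse = "/"), x$Z, x$d_e, x$head))
  invisible(x)
}

# Batched forward over a B x n id matrix. Returns class probabilities,
# hidden (emotion) vectors and, when want_cache, everything the backward
# pass needs.
textcnn_batch_forward <- function(ids, vocab, net, want_cache = FALSE) {
  B <- nrow(ids); n <- ncol(ids)
  if (n < max(net$heights))
    stop("padded length n (", n, ") must be >= max filter height (",
         max(net$heights), ")", call. = FALSE)
  p <- net$params
  emb <- vocab$embeddings[c(ids) + 1L, , drop = FALSE]  # (B*n) x d, position-major
  blocks <- lapply(seq_len(n), function(k)
    emb[((k - 1L) * B + 1L):(k * B), , drop = FALSE])
  pooled <- vector("list", length(net$heights))
  argmax <- vector("list", length(net$heights))
  for (q in seq_along(net$heights)) {
    h <- net$heights[[q]]
    Fq <- p$filters[[q]]; bq <- p$fbias[[q]]
    W <- n - h + 1L
    mx <- matrix(-Inf, B, net$Z)
    am <- matrix(1L, B, net$Z)
    for (j in seq_len(W)) {
      Xj <- do.call(cbind, blocks[j:(j + h - 1L)])
      a <- pmax(Xj %*% Fq + rep(bq, each = B), 0)
      upd <- a > mx
      if (any(upd)) { mx[upd] <- a[upd]; am[upd] <- j }
    }
    pooled[[q]] <- mx
    argmax[[q]] <- am
  }
  o <- do.call(cbind, pooled)                       # B x 3Z
  hidden <- pmax(o %*% p$W_fc + rep(p$b_fc, each = B), 0)
  scores <- hidden %*% p$W_out + rep(p$b_out, each = B)
  probs <- if (net$head == "sigmoid") sigmoid(scores) else softmax_rows(scores)
  out <- list(probs = probs, hidden = hidden)
  if (want_cache)
    out$cache <- list(blocks = blocks, pooled = pooled, argmax = argmax,
                      o = o, hidden = hidden, B = B, n = n, ids = ids)
  out
}

# Backward pass for pretraining; dscores is B x 3 (d loss / d pre-head
# scores). When want_demb, also returns the gradient of the embedding
# matrix (PAD row held at zero).
textcnn_batch_backward <- function(dscores, cache, net, want_demb = FALSE,
                                   n_vocab = NULL) {
  p <- net$params
  B <- cache$B; n <- cache$n
  dW_out <- crossprod(cache$hidden, dscores)
  db_out <- colSums(dscores)
  dhidden <- (dscores %*% t(p$W_out)) * (cache$hidden > 0)
  dW_fc <- crossprod(cache$o, dhidden)
  db_fc <- colSums(dhidden)
  do_ <- dhidden %*% t(p$W_fc)
  dfilters <- vector("list", length(net$heights))
  dfbias <- vector("list", length(net$heights))
  demb <- if (want_demb) matrix(0, n_vocab, net$d) else NULL
  for (q in seq_along(net$heights)) {
    h <- net$heights[[q]]
    cols <- ((q - 1L) * net$Z + 1L):(q * net$Z)
    dO <- do_[, cols, drop = FALSE]
    dO[cache$pooled[[q]] <= 0] <- 0          # ReLU dead at the pooled max
    dF <- matrix(0, h * net$d, net$Z)
    db <- numeric(net$Z)
    W <- n - h + 1L
    for (j in seq_len(W)) {
      sel <- cache$argmax[[q]] == j
      if (!any(sel & dO != 0)) next
      dA <- dO * sel
      Xj <- do.call(cbind, cache$blocks[j:(j + h - 1L)])
      dF <- dF + crossprod(Xj, dA)
      db <- db + colSums(dA)
      if (want_demb) {
        dX <- dA %*% t(p$filters[[q]])       # B x (h*d)
        for (r in seq_len(h)) {
          idx <- cache$ids[, j + r - 1L] + 1L
          dpart <- dX[, (r - 1L) * net$d + seq_len(net$d), drop = FALSE]
          acc <- rowsum(dpart, idx)
          demb[as.integer(rownames(acc)), ] <-
            demb[as.integer(rownames(acc)), , drop = FALSE] + acc
        }
      }
    }
    dfilters[[q]] <- dF
    dfbias[[q]] <- db
  }
  names(dfilters) <- names(p$filters)
  names(dfbias) <- names(p$fbias)
  out <- list(filters = dfilters, fbias = dfbias,
              W_fc = dW_fc, b_fc = db_fc, W_out = dW_out, b_out = db_out)
  if (want_demb) {
    demb[1L, ] <- 0                          # PAD embedding stays zero
    out$demb <- demb
  }
  out
}

# Loss and dscores for one batch; y is B x 3 one-hot.
emotion_loss_grad <- function(probs, y, head) {
  B <- nrow(y)
  p <- pmin(pmax(probs, 1e-12), 1 - 1e-12)
  if (head == "sigmoid") {
    loss <- -sum(y * log(p) + (1 - y) * log(1 - p)) / B
  } else {
    loss <- -sum(y * log(p)) / B
  }
  # For both heads d loss / d score reduces to (probs - y) / B.
  list(loss = loss, dscores = (probs - y) / B)
}

#' Forward pass of the emotion TextCNN for one post
#'
#' @param token_ids integer vector of exactly `net$n` 0-based token ids.
#' @param net a `textcnn`.
#' @param vocab the `vocabulary` the ids refer to.
#' @return list with `class_probs` (length-3, named) and `hidden`
#'   (the emotion vector, length `d_e`).
#' @export
textcnn_forward <- function(token_ids, net, vocab) {
  if (length(token_ids) != net$n)
    stop("expected ", net$n, " token ids, got ", length(token_ids), call. = FALSE)
  fw <- textcnn_batch_forward(matrix(as.integer(token_ids), nrow = 1L), vocab, net)
  list(class_probs = stats::setNames(drop(fw$probs), EMOTION_CLASSES),
       hidden = drop(fw$hidden))
}

#' Pretrain the emotion classifier
#'
#' Trains the TextCNN on a positive/negative/neutral corpus with Adam and
#' per-class binary cross-entropy (categorical cross-entropy under the
#' softmax head), holding out a validation split and stopping when the
#' held-out loss stops improving. Word embeddings stay frozen. The
#' returned network is what the main model consumes — frozen thereafter.
#'
#' @param corpus data.frame with `text`, `label` (from
#'   [read_emotion_corpus()] or [generate_emotion_corpus()]).
#' @param vocab a `vocabulary`; built from the corpus when `NULL`.
#' @param n padded post length.
#' @param heights,Z,d_e,head architecture, see [textcnn_init()].
#' @param d embedding dimension used when `vocab` is `NULL`.
#' @param lr,batch_size,max_epochs,patience optimisation settings.
#' @param val_frac held-out fraction for the stopping criterion.
#' @param train_embeddings also train the word embeddings (non-static
#'   variant, default). This matters most when embeddings are randomly
#'   initialised: the emotion task then doubles as embedding pretraining,
#'   clustering words by emotion class the way distributionally pretrained
#'   vectors arrive pre-clustered. The PAD embedding stays zero.
#' @param seed RNG seed (initialisation, split, shuffling).
#' @param verbose print per-epoch losses.
#' @return a trained `textcnn` with attributes `val_accuracy` and `vocab`
#'   (the vocabulary carrying the possibly updated embeddings — use it for
#'   every later encoding step).
#' @export
pretrain_emotion_classifier <- function(corpus, vocab = NULL, n = 32L,
                                        heights = c(3L, 4L, 5L), Z = 100L,
                                        d_e = 128L, head = "sigmoid",
                                        d = 300L, lr = 1e-3, batch_size = 32L,
                                        max_epochs = 60L, patience = 5L,
                                        val_frac = 0.1,
                                        train_embeddings = TRUE, seed = 1L,
                                        verbose = FALSE) {
  tab <- table(factor(corpus$label, levels = EMOTION_CLASSES))
  if (any(tab < 2L))
    stop("corpus must contain at least 2 examples of every emotion class",
         call. = FALSE)
  if (is.null(vocab)) vocab <- build_vocabulary(corpus$text, d = d, seed = seed)
  net <- textcnn_init(ncol(vocab$embeddings), n, heights, Z, d_e, head,
                      seed = seed)
  ids <- encode_posts(corpus$text, vocab, n)
  y <- matrix(0, nrow(ids), 3L)
  y[cbind(seq_len(nrow(ids)), match(corpus$label, EMOTION_CLASSES))] <- 1
  with_seed(seed + 1L, {
    B <- nrow(ids)
    n_val <- max(3L, round(val_frac * B))
    ord <- sample.int(B)
    val <- ord[seq_len(n_val)]
    tr <- ord[-seq_len(n_val)]
    pars <- list(net = net$params)
    if (train_embeddings) pars$emb <- vocab$embeddings
    opt <- adam_init(pars)
    best <- list(loss = Inf, pars = pars, acc = NA_real_)
    stall <- 0L
    for (epoch in seq_len(max_epochs)) {
      perm <- sample(tr)
      for (start in seq(1L, length(perm), by = batch_size)) {
        bi <- perm[start:min(start + batch_size - 1L, length(perm))]
        fw <- textcnn_batch_forward(ids[bi, , drop = FALSE], vocab, net,
                                    want_cache = TRUE)
        lg <- emotion_loss_grad(fw$probs, y[bi, , drop = FALSE], net$head)
        gr <- textcnn_batch_backward(lg$dscores, fw$cache, net,
                                     want_demb = train_embeddings,
                                     n_vocab = vocab_size(vocab))
        grads <- list(net = gr[setdiff(names(gr), "demb")])
        if (train_embeddings) grads$emb <- gr$demb
        st <- adam_step(pars, grads, opt, lr = lr)
        pars <- st$params; opt <- st$state
        net$params <- pars$net
        if (train_embeddings) {
          pars$emb[1L, ] <- 0
          vocab$embeddings <- pars$emb
        }
      }
      vfw <- textcnn_batch_forward(ids[val, , drop = FALSE], vocab, net)
      vl <- emotion_loss_grad(vfw$probs, y[val, , drop = FALSE], net$head)$loss
      vacc <- mean(max.col(vfw$probs) == max.col(y[val, , drop = FALSE]))
      if (verbose)
        message(sprintf("epoch %d: val loss %.4f, val acc %.3f", epoch, vl, vacc))
      if (vl < best$loss - 1e-5) {
        best <- list(loss = vl, pars = pars, acc = vacc)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    }
    net$params <- best$pars$net
    if (train_embeddings) vocab$embeddings <- best$pars$emb
    attr(net, "val_accuracy") <- best$acc
  })
  attr(net, "vocab") <- vocab
  net
}

#' Per-post emotion vectors for a set of posts
#'
#' @param texts character vector of posts.
#' @param net a trained `textcnn`.
#' @param vocab the matching `vocabulary`.
#' @return matrix with one `d_e`-dimensional emotion vector per row.
#' @export
emotion_vectors <- function(texts, net, vocab) {
  ids <- encode_posts(texts, vocab, net$n)
  textcnn_batch_forward(ids, vocab, net)$hidden
}

#' User-level emotion expectation
#'
#' The arithmetic mean of a user's per-post emotion vectors.
#'
#' @param emotion_vectors matrix (posts in rows) or list of equal-length
#'   numeric vectors.
#' @return numeric vector `v_emo` of dimension `d_e`.
#' @export
user_emotion_expectation <- function(emotion_vectors) {
  if (is.list(emotion_vectors)) {
    if (length(emotion_vectors) == 0L)
      stop("at least one emotion vector is required", call. = FALSE)
    dims <- lengths(emotion_vectors)
    if (length(unique(dims)) != 1L)
      stop("emotion vectors differ in dimension", call. = FALSE)
    emotion_vectors <- do.call(rbind, emotion_vectors)
  }
  if (nrow(emotion_vectors) == 0L)
    stop("at least one emotion vector is required", call. = FALSE)
  colMeans(emotion_vectors)
}
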