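test_that("attention weights are a masked softmax over post scores", {
  att <- attention_init(3L, 2L, seed = 7)
  p <- c(0.2, -0.4, 0.6)
  expect_equal(attention_weights(matrix(p, 1), att), 1.0)
  two <- rbind(p, p)
  expect_equal(attention_weights(two, att), c(0.5, 0.5))
  # hand-computed softmax oracle on a 3-post fixture
  set.seed(3)
  P <- matrix(rnorm(9), 3, 3)
  ut <- tanh(P %*% att$W_s + matrix(att$b_s, 3, 2, byrow = TRUE))
  logits <- as.numeric(ut %*% att$u_s)
  oracle <- exp(logits) / sum(exp(logits))
  expect_equal(attention_weights(P, att), oracle, tolerance = 1e-8)
  # masked slots get exactly zero and the rest renormalises
  w <- attention_weights(P, att, mask = c(TRUE, FALSE, TRUE))
  expect_identical(w[2], 0)
  expect_equal(sum(w), 1, tolerance = 1e-6)
  expect_error(attention_weights(P, att, mask = rep(FALSE, 3)), "non-PAD")
})

test_that("masked-softmax normalisation holds for random batches", {
  att <- attention_init(4L, 3L, seed = 11)
  set.seed(12)
  for (k in 1:30) {
    M <- sample(2:7, 1)
    P <- matrix(rnorm(M * 4), M, 4)
    mask <- stats::runif(M) > 0.4
    if (!any(mask)) mask[1] <- TRUE
    w <- attention_weights(P, att, mask = mask,
                           form = sample(c("tanh", "bilinear"), 1))
    expect_true(all(w >= 0))
    expect_true(all(w[!mask] == 0))
    expect_equal(sum(w[mask]), 1, tolerance = 1e-6)
  }
})

test_that("attention pooling is the weighted sum of post vectors", {
  P <- rbind(c(1, 2, 3), c(4, 5, 6))
  expect_equal(attention_pool(P, c(1, 0)), c(1, 2, 3))
  v <- c(2, -1, 0.5)
  expect_equal(attention_pool(rbind(v, v, v), rep(1 / 3, 3)), v)
  set.seed(5)
  Q <- matrix(rnorm(12), 4, 3)
  w <- stats::runif(4); w <- w / sum(w)
  naive <- rep(0, 3)
  for (t in 1:4) naive <- naive + w[t] * Q[t, ]
  expect_equal(attention_pool(Q, w), naive, tolerance = 1e-6)
})

test_that("the fused classifier is a shift-invariant softmax", {
  cls <- classifier_init(5L, seed = 3)
  cls$W[] <- 0; cls$b[] <- 0
  expect_equal(unname(classify_user(c(1, 2, 3), c(4, 5), cls)), c(0.5, 0.5))
  cls2 <- classifier_init(5L, seed = 4)
  pr <- classify_user(c(1, 2, 3), c(4, 5), cls2)
  expect_equal(sum(pr), 1)
  cls3 <- cls2; cls3$b <- cls3$b + 7          # common shift of both logits
  expect_equal(classify_user(c(1, 2, 3), c(4, 5), cls3), pr, tolerance = 1e-12)
  expect_error(classify_user(c(1, 2), c(4, 5), cls2), "dimension")
})

test_that("cross-entropy loss matches its closed forms and a naive loop", {
  expect_equal(classification_loss(rbind(c(0, 1), c(1, 0)), c(1L, 0L)), 0)
  expect_equal(classification_loss(rbind(c(0.5, 0.5)), 1L), log(2))
  set.seed(8)
  B <- 12L
  logits <- matrix(rnorm(B * 2), B, 2)
  probs <- exp(logits) / rowSums(exp(logits))
  labels <- sample(0:1, B, replace = TRUE)
  naive <- 0
  for (i in seq_len(B)) naive <- naive - log(probs[i, labels[i] + 1])
  expect_equal(classification_loss(probs, labels), naive / B, tolerance = 1e-10)
  expect_warning(classification_loss(rbind(c(1, 0)), 1L), "clamping")
})

test_that("uniform averaging equals attention with forced-uniform weights", {
  set.seed(21)
  P <- matrix(rnorm(5 * 4), 5, 4)
  att <- attention_init(4L, 3L, seed = 22)
  cls <- classifier_init(6L, seed = 23)
  v_emo <- rnorm(2)
  hf_uniform <- eran:::head_forward(P, v_emo, att, cls, uniform = TRUE)
  pooled_forced <- attention_pool(P, rep(1 / 5, 5))
  expect_identical(hf_uniform$pooled, pooled_forced)
  expect_identical(hf_uniform$probs,
                   classify_user(pooled_forced, v_emo, cls))
})

test_that("the attention head gradient matches finite differences", {
  set.seed(31)
  P <- matrix(rnorm(4 * 4), 4, 4)
  att <- attention_init(4L, 3L, seed = 32)
  cls <- classifier_init(6L, seed = 33)
  v_emo <- rnorm(2)
  gold <- 1L
  for (form in c("tanh", "bilinear")) {
    pars <- list(att = att, cls = cls)
    loss_at <- function(x) {
      p2 <- nl_unflatten(x, pars)
      hf <- eran:::head_forward(P, v_emo, p2$att, p2$cls, FALSE, form)
      -log(hf$probs[[gold + 1L]])
    }
    hf <- eran:::head_forward(P, v_emo, att, cls, FALSE, form)
    y <- c(0, 0); y[gold + 1L] <- 1
    hb <- eran:::head_backward(hf$cache, hf$probs - y, att, cls)
    an <- nl_flatten(list(att = hb$datt, cls = hb$dcls))
    fd <- fd_gradient(loss_at, nl_flatten(pars))
    expect_lt(rel_err(an, fd), 1e-4)
    # and dP, the path into the encoder
    loss_P <- function(pvec) {
      hf2 <- eran:::head_forward(matrix(pvec, 4, 4), v_emo, att, cls, FALSE, form)
      -log(hf2$probs[[gold + 1L]])
    }
    fdP <- fd_gradient(loss_P, as.numeric(P))
    expect_lt(rel_err(as.numeric(hb$dP), fdP), 1e-4)
  }
})
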