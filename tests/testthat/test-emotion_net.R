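test_that("conv_feature matches the hand-computed window product", {
  w <- matrix(0.5, 2, 2)
  expect_equal(conv_feature(w, matrix(0, 2, 2), 0), 0)
  # all-ones filter over a constant window: relu(h*d*const + bias)
  expect_equal(conv_feature(w, matrix(1, 2, 2), 0.1), 2 * 2 * 0.5 + 0.1)
  expect_equal(conv_feature(-w, matrix(1, 2, 2), 0), 0)  # ReLU clips
  expect_error(conv_feature(w, matrix(1, 3, 2), 0), "shapes differ")
})

test_that("feature maps cover exactly the n - h + 1 windows", {
  set.seed(4)
  X <- matrix(rnorm(7 * 3), 7, 3)
  for (h in c(1L, 2L, 3L, 5L)) {
    fm <- conv_feature_map(X, matrix(rnorm(h * 3), h, 3), 0.2)
    expect_length(fm, 7L - h + 1L)
  }
  expect_error(conv_feature_map(X[1:2, ], matrix(0, 3, 3), 0), "pad posts")
})

test_that("max-over-time pooling takes the maximum and rejects empty maps", {
  expect_equal(max_over_time(c(0.1, 0.9, 0.3)), 0.9)
  expect_equal(max_over_time(rep(0.4, 6)), 0.4)
  expect_error(max_over_time(numeric(0)), "pad posts")
  set.seed(1)
  m <- rnorm(10)
  expect_equal(max_over_time(sample(m)), max_over_time(m))  # permutation-invariant
})

test_that("TextCNN forward has the documented shapes and degenerate cases", {
  vocab <- build_vocabulary("a b c d e", d = 5, seed = 2)
  net <- textcnn_init(5, 8, heights = c(2, 3, 4), Z = 4, d_e = 6, seed = 3)
  out <- textcnn_forward(tokenize_and_pad("a b c d", vocab, 8), net, vocab)
  expect_length(out$class_probs, 3L)
  expect_true(all(out$class_probs > 0 & out$class_probs < 1))
  expect_length(out$hidden, 6L)
  # pooled vector is 3*Z wide
  fw <- eran:::textcnn_batch_forward(matrix(c(2L, 3L, 4L, 0L, 0L, 0L, 0L, 0L),
                                            nrow = 1), vocab, net,
                                     want_cache = TRUE)
  expect_equal(ncol(fw$cache$o), 3L * 4L)
  # all-PAD post, zero PAD embedding, zero biases, ReLU -> zero hidden vector
  allpad <- textcnn_forward(rep(0L, 8), net, vocab)
  expect_equal(unname(allpad$hidden), rep(0, 6))
  expect_error(textcnn_init(5, 3, heights = c(2, 3, 4)), "filter height")
  expect_error(textcnn_init(5, 8, heights = c(2, 3)), "3 distinct")
})

test_that("TextCNN analytic gradients match finite differences", {
  vocab <- build_vocabulary(c("a b c d e f", "g h i j"), d = 5, seed = 2)
  net <- textcnn_init(5, 8, heights = c(2, 3, 4), Z = 3, d_e = 4, seed = 3)
  ids <- rbind(tokenize_and_pad("a b c d e f", vocab, 8),
               tokenize_and_pad("g h i j a", vocab, 8))
  y <- rbind(c(1, 0, 0), c(0, 1, 0))
  fw <- eran:::textcnn_batch_forward(ids, vocab, net, want_cache = TRUE)
  lg <- eran:::emotion_loss_grad(fw$probs, y, net$head)
  gr <- eran:::textcnn_batch_backward(lg$dscores, fw$cache, net,
                                      want_demb = TRUE,
                                      n_vocab = length(vocab$tokens))
  loss_at <- function(x_net, x_emb) {
    n2 <- net; n2$params <- nl_unflatten(x_net, net$params)
    v2 <- vocab; v2$embeddings[] <- x_emb
    f2 <- eran:::textcnn_batch_forward(ids, v2, n2)
    eran:::emotion_loss_grad(f2$probs, y, n2$head)$loss
  }
  x0 <- nl_flatten(net$params)
  e0 <- as.numeric(vocab$embeddings)
  fd_net <- fd_gradient(function(x) loss_at(x, e0), x0)
  expect_lt(rel_err(nl_flatten(gr[names(net$params)]), fd_net), 1e-4)
  fd_emb <- fd_gradient(function(e) loss_at(x0, e), e0)
  # PAD row is pinned at zero, so compare the remaining rows only
  live <- as.numeric(row(vocab$embeddings) != 1L)
  expect_lt(rel_err(as.numeric(gr$demb) * live, fd_emb * live), 1e-4)
})

test_that("pretraining separates the synthetic emotion classes", {
  gen <- generator_config(corpus_size = 600L, noise_rate = 0.05, seed = 21)
  corp <- generate_emotion_corpus(gen)
  vocab <- build_vocabulary(corp$text, d = 24, seed = 1)
  net <- pretrain_emotion_classifier(corp, vocab, n = 12, heights = c(2, 3, 4),
                                     Z = 8, d_e = 16, lr = 0.01,
                                     max_epochs = 80, patience = 10,
                                     val_frac = 0.15, seed = 5)
  expect_gte(attr(net, "val_accuracy"), 0.95)
  # deterministic: same seed, bitwise-identical parameters
  net2 <- pretrain_emotion_classifier(corp, vocab, n = 12, heights = c(2, 3, 4),
                                      Z = 8, d_e = 16, lr = 0.01,
                                      max_epochs = 80, patience = 10,
                                      val_frac = 0.15, seed = 5)
  expect_identical(net$params, net2$params)
  expect_identical(attr(net, "vocab")$embeddings, attr(net2, "vocab")$embeddings)
  # missing class errors
  expect_error(pretrain_emotion_classifier(corp[corp$label != "neutral", ]),
               "every emotion class")
})

test_that("the user emotion expectation is the arithmetic mean", {
  v <- c(1, 2, 3)
  expect_equal(user_emotion_expectation(rbind(v, v, v)), v)
  expect_equal(user_emotion_expectation(list(c(1, 0), c(0, 1))), c(0.5, 0.5))
  set.seed(8)
  E <- matrix(rnorm(10 * 4), 10, 4)
  naive <- rep(0, 4)
  for (i in 1:10) naive <- naive + E[i, ]
  expect_equal(user_emotion_expectation(E), naive / 10, tolerance = 1e-6)
  expect_error(user_emotion_expectation(list()), "at least one")
  expect_error(user_emotion_expectation(list(c(1, 2), c(1, 2, 3))), "dimension")
})
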