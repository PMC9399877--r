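# Shared fixtures and independent oracles for the test suite.

# Flatten a nested list of numeric arrays to one vector, and back.
nl_flatten <- function(a) {
  if (is.list(a)) unlist(lapply(a, nl_flatten), use.names = FALSE) else as.numeric(a)
}

nl_unflatten <- function(vec, skeleton) {
  pos <- 0L
  fill <- function(a) {
    if (is.list(a)) return(lapply(a, fill))
    n <- length(a)
    out <- a
    out[] <- vec[pos + seq_len(n)]
    pos <<- pos + n
    out
  }
  fill(skeleton)
}

# Central finite-difference gradient of scalar f at flat parameter vector x.
fd_gradient <- function(f, x, eps = 1e-5) {
  vapply(seq_along(x), function(k) {
    x1 <- x; x1[k] <- x1[k] + eps
    x2 <- x; x2[k] <- x2[k] - eps
    (f(x1) - f(x2)) / (2 * eps)
  }, numeric(1))
}

rel_err <- function(a, b) {
  sqrt(sum((a - b)^2)) / max(1e-12, sqrt(sum(b^2)))
}

# Independent bag-of-words linear classifier (separability oracle):
# multinomial logistic regression on raw term counts via nnet.
bow_linear_accuracy <- function(train, test) {
  vocab <- sort(unique(unlist(strsplit(c(train$text, test$text), " "))))
  bow <- function(texts) {
    m <- matrix(0, length(texts), length(vocab))
    for (i in seq_along(texts)) {
      tab <- table(strsplit(texts[[i]], " ")[[1]])
      m[i, match(names(tab), vocab)] <- as.numeric(tab)
    }
    m
  }
  fit <- nnet::multinom(y ~ ., data = data.frame(y = factor(train$label),
                                                 bow(train$text)),
                        MaxNWts = 10000, decay = 0.1, trace = FALSE)
  mean(as.character(predict(fit, data.frame(bow(test$text)))) == test$label)
}

# Tiny BiLSTM/attention fixture shared by gradient and invariance tests.
tiny_fixture <- function(seed = 42L) {
  vocab <- build_vocabulary(c("a b c d e f g h"), d = 3, seed = 2)
  list(vocab = vocab,
       bl = bilstm_init(3, 2, seed = 4),
       ids = rbind(tokenize_and_pad("a b c", vocab, 5),
                   tokenize_and_pad("d e f g h", vocab, 5),
                   tokenize_and_pad("b d", vocab, 5)),
       att = attention_init(4, 3, seed = 5),
       cls = classifier_init(6, seed = 6),
       v_emo = c(0.3, -0.2))
}
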