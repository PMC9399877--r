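# Toy selection problems small enough to enumerate exhaustively.

toy_user <- function(T_ = 3L, u2 = 2L, d_e = 1L, seed = 31L) {
  withr::with_seed(seed, list(P = matrix(rnorm(T_ * u2), T_, u2),
                              E = matrix(rnorm(T_ * d_e), T_, d_e)))
}

toy_ctx <- function(user, seed = 32L) {
  list(P = user$P, v_emo = rep(0.1, 1),
       att = attention_init(ncol(user$P), 2L, seed = seed),
       cls = classifier_init(ncol(user$P) + 1L, seed = seed + 1L),
       uniform = FALSE, form = "tanh")
}

# Deterministic replay of an action sequence: states, action probabilities
# and episode probability under theta. Independent of sample_episode.
enumerate_episode <- function(user, theta, actions) {
  T_ <- nrow(user$P); dim2u <- ncol(user$P)
  run <- numeric(dim2u); cnt <- 0L
  states <- matrix(0, T_, nrow(theta$W1))
  p_act <- numeric(T_)
  for (t in seq_len(T_)) {
    s <- build_state(user$P[t, ],
                     if (cnt == 0L) matrix(0, 0L, dim2u) else
                       matrix(run / cnt, 1L, dim2u),
                     user$E[t, ])
    p1 <- policy_prob(s, theta)
    p_act[t] <- if (actions[t] == 1L) p1 else 1 - p1
    states[t, ] <- s
    if (actions[t] == 1L) { run <- run + user$P[t, ]; cnt <- cnt + 1L }
  }
  list(states = states, p = prod(p_act))
}

test_that("the policy state concatenates post, running mean and emotion", {
  p_t <- c(1, 2); e_t <- 0.5
  s0 <- build_state(p_t, list(), e_t)
  expect_equal(s0, c(1, 2, 0, 0, 0.5))       # empty selection -> zero middle
  s1 <- build_state(p_t, list(c(3, 4)), e_t)
  expect_equal(s1[3:4], c(3, 4))
  set.seed(6)
  vs <- lapply(1:5, function(i) rnorm(2))
  naive <- Reduce(`+`, vs) / 5
  expect_equal(build_state(p_t, vs, e_t)[3:4], naive, tolerance = 1e-6)
  # ablation hook: dropping e_t shrinks the state by d_e
  expect_length(build_state(p_t, vs, NULL), 4L)
  expect_error(build_state(p_t, list(c(1, 2, 3)), e_t), "dimension")
})

test_that("policy probabilities are a sigmoid of the MLP logit", {
  th <- policy_init(5L, hidden = 4L, seed = 1)
  th$W1[] <- 0; th$b1[] <- 0; th$w2[] <- 0; th$b2 <- 0
  expect_equal(policy_prob(rnorm(5), th), 0.5)
  set.seed(2)
  s <- rnorm(5)
  th2 <- policy_init(5L, hidden = 4L, seed = 3)
  p1 <- policy_prob(s, th2)
  expect_equal(p1 + (1 - p1), 1)             # the two actions exhaust the space
  th2$b2 <- th2$b2 + 1                       # +c on the logit raises P(a=1)
  expect_gt(policy_prob(s, th2), p1)
})

test_that("episodes partition the posts and respect forced policies", {
  user <- toy_user(T_ = 6L)
  th <- policy_init(5L, hidden = 4L, seed = 4)
  th$b2 <- 50                                 # forced select
  set.seed(1)
  ep <- sample_episode(user, th)
  expect_equal(ep$sel, 1:6)
  expect_length(ep$non, 0L)
  th$b2 <- -50                                # forced skip
  ep <- sample_episode(user, th)
  expect_length(ep$sel, 0L)
  # partition invariant over random policies
  set.seed(7)
  for (k in 1:20) {
    thr <- policy_init(5L, hidden = 4L, seed = 100 + k)
    ep <- sample_episode(user, thr)
    expect_equal(sort(c(ep$sel, ep$non)), 1:6)
    expect_length(intersect(ep$sel, ep$non), 0L)
  }
  g <- select_posts_greedy(user, policy_init(5L, 4L, seed = 9))
  expect_equal(sort(c(g$dep, g$non)), 1:6)
})

test_that("sampling frequency matches the policy probability", {
  user <- toy_user(T_ = 3L)
  th <- policy_init(5L, hidden = 4L, seed = 12)
  # first action's probability is state-independent of previous selections
  p1 <- policy_prob(build_state(user$P[1, ], list(), user$E[1, ]), th)
  set.seed(123)
  n <- 10000L
  hits <- 0L
  for (k in seq_len(n)) hits <- hits + (1L %in% sample_episode(user, th)$sel)
  se <- sqrt(p1 * (1 - p1) / n)
  expect_lt(abs(hits / n - p1), 3 * se)
})

test_that("rewards are the classifier's gold-label probability", {
  user <- toy_user()
  ctx <- toy_ctx(user)
  ep <- list(sel = c(1L, 3L))
  r1 <- compute_reward(ep, ctx, gold = 1L)
  expect_gt(r1, 0); expect_lt(r1, 1)
  expect_identical(r1, compute_reward(ep, ctx, gold = 1L))  # purity
  expect_equal(r1 + compute_reward(ep, list(P = ctx$P, v_emo = ctx$v_emo,
                                            att = ctx$att, cls = ctx$cls),
                                   gold = 0L), 1)
  # empty selection: zero pooled vector, penalised by -0.5
  hf <- eran:::head_forward(NULL, ctx$v_emo, ctx$att, ctx$cls, FALSE, "tanh")
  expect_equal(compute_reward(list(sel = integer(0)), ctx, 1L),
               unname(hf$probs[["depressed"]]) - 0.5)
})

test_that("equal rewards cancel against the baseline and leave theta fixed", {
  user <- toy_user()
  th <- policy_init(5L, hidden = 4L, seed = 5)
  set.seed(3)
  eps <- lapply(1:4, function(k) {
    e <- sample_episode(user, th); e$reward <- 0.7; e
  })
  upd <- reinforce_update(eps, th, alpha = 0.1)
  expect_equal(unclass(upd$theta), unclass(th))
  expect_equal(upd$baseline, 0.7)
  expect_error(reinforce_update(eps[1], th), "at least 2")
})

test_that("REINFORCE learns a two-post toy with known optimum", {
  # reward 0.9 when post 1 is selected, 0.1 otherwise; the exhaustive
  # 4-episode table makes (select post 1) optimal
  user <- toy_user(T_ = 2L, seed = 41L)
  th <- policy_init(5L, hidden = 8L, seed = 42)
  set.seed(99)
  for (it in 1:500) {
    eps <- lapply(1:8, function(k) {
      e <- sample_episode(user, th)
      e$reward <- if (1L %in% e$sel) 0.9 else 0.1
      e
    })
    th <- reinforce_update(eps, th, alpha = 0.3)$theta
  }
  p_sel1 <- policy_prob(build_state(user$P[1, ], list(), user$E[1, ]), th)
  expect_gt(p_sel1, 0.9)
})

test_that("the baseline keeps the gradient unbiased and shrinks its variance", {
  # exhaustive T=2 toy: mean sampled gradient ~ exact gradient either way,
  # variance strictly lower with the baseline
  user <- toy_user(T_ = 2L, seed = 51L)
  th <- policy_init(5L, hidden = 3L, seed = 52)
  reward_of <- function(sel) if (1L %in% sel) 0.8 else 0.2
  acts <- expand.grid(a1 = 0:1, a2 = 0:1)
  exact <- numeric(length(nl_flatten(unclass(th))))
  for (r in seq_len(nrow(acts))) {
    a <- as.integer(acts[r, ])
    en <- enumerate_episode(user, th, a)
    g <- eran:::reinforce_gradient(en$states, a, rep(reward_of(which(a == 1L)), 2),
                                   th, 1L)
    exact <- exact + en$p * nl_flatten(g)
  }
  set.seed(11)
  M <- 300L; N <- 10L
  gb <- gn <- matrix(0, M, length(exact))
  for (m in seq_len(M)) {
    eps <- lapply(seq_len(N), function(k) sample_episode(user, th))
    R <- vapply(eps, function(e) reward_of(e$sel), numeric(1))
    states <- do.call(rbind, lapply(eps, `[[`, "states"))
    a <- unlist(lapply(eps, `[[`, "actions"))
    gb[m, ] <- nl_flatten(eran:::reinforce_gradient(
      states, a, rep(R - mean(R), each = 2), th, N))
    gn[m, ] <- nl_flatten(eran:::reinforce_gradient(
      states, a, rep(R, each = 2), th, N))
  }
  mc_se <- sqrt(sum(apply(gn, 2, stats::var)) / M)
  expect_lt(sqrt(sum((colMeans(gn) - exact)^2)), 4 * mc_se)
  expect_lt(sqrt(sum((colMeans(gb) - exact)^2)), 4 * mc_se)
  expect_lt(sum(apply(gb, 2, stats::var)), sum(apply(gn, 2, stats::var)))
})
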