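# REINFORCE selection layer: a policy-gradient agent that walks a user's
# posts in order and decides, post by post, whether to add the current
# post to the depression-indicator set H^dep or to the remainder H^non.
#
# The state s^t concatenates the current post vector p^t, the running
# average of the post vectors already selected (zero vector while the
# selection is empty), and the current post's emotion vector e^t. The
# policy is a one-hidden-layer MLP with a sigmoid head; the terminal
# reward of an episode is the frozen classifier's probability of the
# user's gold label given the selected set.

#' Initialise the selection policy
#'
#' @param state_dim dimension of the policy state
#'   (`2u + 2u + d_e`, or `4u` when the emotion vector is ablated).
#' @param hidden hidden width of the policy MLP (default 128).
#' @param seed RNG seed.
#' @return a `policy` object.
#' @export
policy_init <- function(state_dim, hidden = 128L, seed = 1L) {
  theta <- with_seed(seed, {
    list(W1 = runif_mat(state_dim, hidden, glorot_r(state_dim, hidden)),
         b1 = numeric(hidden),
         w2 = stats::runif(hidden, -glorot_r(hidden, 1L), glorot_r(hidden, 1L)),
         b2 = 0)
  })
  structure(theta, class = "policy")
}

#' Build the policy state for one step
#'
#' @param p_t post vector of the current post.
#' @param selected list (or matrix rows) of post vectors already selected;
#'   the average block is the zero vector when empty.
#' @param e_t emotion vector of the current post, or `NULL` when the
#'   emotion-in-state ablation is active.
#' @return state vector `s^t = [p_t ; avg(selected) ; e_t]`.
#' @export
build_state <- function(p_t, selected, e_t = NULL) {
  if (is.matrix(selected)) {
    avg <- if (nrow(selected) == 0L) numeric(length(p_t)) else colMeans(selected)
  } else if (length(selected) == 0L) {
    avg <- numeric(length(p_t))
  } else {
    dims <- lengths(selected)
    if (any(dims != length(p_t)))
      stop("selected post vectors differ in dimension from p_t", call. = FALSE)
    avg <- colMeans(do.call(rbind, selected))
  }
  c(p_t, avg, e_t)
}

#' Selection probability of the policy
#'
#' @param s state vector, or a matrix of states in rows.
#' @param theta a `policy`.
#' @return `P(a = 1 | s)` in (0, 1), one value per state.
#' @export
policy_prob <- function(s, theta) {
  S <- if (is.matrix(s)) s else matrix(s, nrow = 1L)
  if (ncol(S) != nrow(theta$W1))
    stop("state dimension ", ncol(S), " does not match policy (",
         nrow(theta$W1), ")", call. = FALSE)
  h <- tanh(S %*% theta$W1 + rep(theta$b1, each = nrow(S)))
  drop(sigmoid(h %*% theta$w2 + theta$b2))
}

#' Sample one selection episode for a user
#'
#' Walks posts in order, sampling `a^t ~ Bernoulli(policy_prob(s^t))` and
#' rebuilding the state after each selection. Uses the caller's RNG
#' stream.
#'
#' @param user_enc list with `P` (`T x 2u` post vectors) and optionally
#'   `E` (`T x d_e` emotion vectors; `NULL` for the state ablation).
#' @param theta a `policy`.
#' @return an `episode`: `states` (T x state_dim), `actions` (0/1),
#'   `probs`, `sel` / `non` (the H^dep / H^non index partition), and
#'   `reward` (`NA` until [compute_reward()] fills it).
#' @export
sample_episode <- function(user_enc, theta) {
  P <- user_enc$P
  E <- user_enc$E
  T_ <- nrow(P)
  dim2u <- ncol(P)
  run <- numeric(dim2u); cnt <- 0L
  sdim <- nrow(theta$W1)
  states <- matrix(0, T_, sdim)
  actions <- integer(T_); probs <- numeric(T_)
  for (t in seq_len(T_)) {
    avg <- if (cnt == 0L) numeric(dim2u) else run / cnt
    s <- c(P[t, ], avg, if (!is.null(E)) E[t, ])
    pr <- policy_prob(s, theta)
    a <- as.integer(stats::runif(1) < pr)
    states[t, ] <- s; probs[t] <- pr; actions[t] <- a
    if (a == 1L) { run <- run + P[t, ]; cnt <- cnt + 1L }
  }
  structure(list(states = states, actions = actions, probs = probs,
                 sel = which(actions == 1L), non = which(actions == 0L),
                 reward = NA_real_),
            class = "episode")
}

# Sample N episodes for one user in lockstep (vectorised over episodes).
# Returns states as a ((T*N) x sdim) matrix in t-major order, an N x T
# action matrix, and the per-episode selections.
sample_episodes_batch <- function(user_enc, theta, n_episodes) {
  P <- user_enc$P; E <- user_enc$E
  T_ <- nrow(P); dim2u <- ncol(P); N <- n_episodes
  run <- matrix(0, N, dim2u); cnt <- numeric(N)
  sdim <- nrow(theta$W1)
  states <- matrix(0, T_ * N, sdim)
  actions <- matrix(0L, N, T_)
  probs <- matrix(0, N, T_)
  for (t in seq_len(T_)) {
    avg <- run / pmax(cnt, 1)
    S <- cbind(matrix(P[t, ], N, dim2u, byrow = TRUE), avg,
               if (!is.null(E)) matrix(E[t, ], N, ncol(E), byrow = TRUE))
    pr <- policy_prob(S, theta)
    a <- as.integer(stats::runif(N) < pr)
    states[(t - 1L) * N + seq_len(N), ] <- S
    actions[, t] <- a
    probs[, t] <- pr
    run <- run + a * matrix(P[t, ], N, dim2u, byrow = TRUE)
    cnt <- cnt + a
  }
  list(states = states, actions = actions, probs = probs,
       sel = lapply(seq_len(N), function(nn) which(actions[nn, ] == 1L)))
}

#' Terminal reward of an episode
#'
#' The frozen classifier's predicted probability of the user's gold label
#' given the selected posts `H^dep`. An empty selection is scored on the
#' zero pooled vector and additionally penalised by -0.5, which keeps the
#' early policy away from degenerate all-skip behaviour.
#'
#' @param episode an `episode` (or any list with a `sel` index vector).
#' @param ctx classifier context: list with `P` (the user's post vectors),
#'   `v_emo` (or `NULL`), `att`, `cls`, `uniform`, `form`.
#' @param gold gold label in \{0, 1\}.
#' @return scalar reward.
#' @export
compute_reward <- function(episode, ctx, gold) {
  sel <- episode$sel
  uniform <- isTRUE(ctx$uniform)
  form <- if (is.null(ctx$form)) "tanh" else ctx$form
  if (length(sel) == 0L) {
    hf <- head_forward(NULL, ctx$v_emo, ctx$att, ctx$cls, uniform, form)
    return(unname(hf$probs[[gold + 1L]]) - 0.5)
  }
  hf <- head_forward(ctx$P[sel, , drop = FALSE], ctx$v_emo, ctx$att, ctx$cls,
                     uniform, form)
  unname(hf$probs[[gold + 1L]])
}

# REINFORCE gradient of the expected-reward objective (ascent direction).
# states: stacked states (rows aligned with c(actions)); actions: 0/1
# vector; adv: advantage per row. Baseline subtraction happens upstream.
reinforce_gradient <- function(states, actions, adv, theta, n_episodes) {
  h <- tanh(states %*% theta$W1 + rep(theta$b1, each = nrow(states)))
  p1 <- drop(sigmoid(h %*% theta$w2 + theta$b2))
  # d log pi(a|s) / d logit = a - p1; weight rows by advantage / N
  wrow <- adv * (actions - p1) / n_episodes
  dw2 <- drop(crossprod(h, wrow))
  db2 <- sum(wrow)
  dh <- outer(wrow, theta$w2) * (1 - h^2)
  list(W1 = crossprod(states, dh), b1 = colSums(dh), w2 = dw2, b2 = db2)
}

#' One REINFORCE update from N sampled episodes
#'
#' Uses the within-batch mean reward as the baseline `b`, forms the
#' advantage-weighted score-function gradient of the expected reward, and
#' takes one plain gradient-ascent step of size `alpha`:
#' `theta <- theta + alpha * (1/N) * sum_n (R_n - b) * sum_t d log pi`.
#'
#' @param episodes list of at least 2 `episode`s for one user, each with
#'   its `reward` filled in (see [compute_reward()]).
#' @param theta a `policy`.
#' @param alpha learning rate.
#' @return list with the updated `theta`, the surrogate `loss1`
#'   (negated objective), and the `baseline`.
#' @export
reinforce_update <- function(episodes, theta, alpha = 1e-3) {
  N <- length(episodes)
  if (N < 2L) stop("need at least 2 episodes for the baseline", call. = FALSE)
  R <- vapply(episodes, function(e) e$reward, numeric(1))
  if (anyNA(R)) stop("episodes carry no rewards; call compute_reward first",
                     call. = FALSE)
  b <- mean(R)
  adv <- R - b
  states <- do.call(rbind, lapply(episodes, `[[`, "states"))
  actions <- unlist(lapply(episodes, `[[`, "actions"))
  adv_row <- rep(adv, vapply(episodes, function(e) length(e$actions), integer(1)))
  gr <- reinforce_gradient(states, actions, adv_row, theta, N)
  loss1 <- -mean(adv * vapply(episodes, function(e) {
    sum(log(ifelse(e$actions == 1L, e$probs, 1 - e$probs)))
  }, numeric(1)))
  theta_new <- nl_map2(unclass(theta), gr, function(p, g) p + alpha * g)
  class(theta_new) <- "policy"
  list(theta = theta_new, loss1 = loss1, baseline = b)
}

#' Greedy (deterministic) post selection
#'
#' Inference-time determinisation of the stochastic policy: walks posts in
#' order and selects a post iff its selection probability exceeds 0.5,
#' with states built from the greedily selected set.
#'
#' @param user_enc list with `P` and optionally `E` (see [sample_episode()]).
#' @param theta a trained `policy`.
#' @return list with `dep` and `non` (index partition of `1..T`) and
#'   `probs` (per-post selection probabilities).
#' @export
select_posts_greedy <- function(user_enc, theta) {
  P <- user_enc$P; E <- user_enc$E
  T_ <- nrow(P); dim2u <- ncol(P)
  run <- numeric(dim2u); cnt <- 0L
  probs <- numeric(T_); actions <- integer(T_)
  for (t in seq_len(T_)) {
    avg <- if (cnt == 0L) numeric(dim2u) else run / cnt
    s <- c(P[t, ], avg, if (!is.null(E)) E[t, ])
    pr <- policy_prob(s, theta)
    probs[t] <- pr
    if (pr > 0.5) { actions[t] <- 1L; run <- run + P[t, ]; cnt <- cnt + 1L }
  }
  list(dep = which(actions == 1L), non = which(actions == 0L), probs = probs)
}
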