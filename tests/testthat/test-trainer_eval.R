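# Small shared experiment: 60 users, desk-scale model. Built once at file
# load and reused across blocks to keep the suite fast.
gen60 <- generator_config(n_users = 60L, posts_per_user = c(15L, 20L),
                          corpus_size = 300L, seed = 7)
dat60 <- generate_user_histories(gen60)
cfg_small <- eran_validation_config()
res60 <- eran_experiment(gen60, cfg_small, seed = 3, data = dat60)

test_that("evaluation reports are internally consistent", {
  set.seed(13)
  for (k in 1:20) {
    cm <- sample(0:30, 4, replace = TRUE)
    if (sum(cm) == 0) cm[1] <- 1
    r <- suppressWarnings(eval_report(cm[1], cm[2], cm[3], cm[4]))
    expect_equal(r$accuracy, (cm[1] + cm[4]) / sum(cm))
    if (r$precision + r$recall > 0)
      expect_equal(r$f1, 2 * r$precision * r$recall / (r$precision + r$recall),
                   tolerance = 1e-9)
  }
  expect_warning(eval_report(0, 0, 3, 5), "no predicted positives")
  r <- suppressWarnings(eval_report(0, 0, 3, 5))
  expect_equal(r$precision, 0)
})

test_that("stratified splitting covers every user exactly once", {
  labs <- vapply(dat60$histories, `[[`, integer(1), "label")
  sp <- split_histories(dat60$histories, seed = 5)
  ids <- function(hs) sort(vapply(hs, `[[`, character(1), "user_id"))
  all_ids <- ids(dat60$histories)
  expect_equal(sort(c(ids(sp$train), ids(sp$dev), ids(sp$test))), all_ids)
  lab_of <- function(hs) vapply(hs, `[[`, integer(1), "label")
  # stratification: both classes present everywhere, ~80/20 split
  expect_equal(sum(lab_of(sp$test) == 1L), sum(labs == 1L) * 0.2, tolerance = 0.35)
  expect_gt(length(sp$train) + length(sp$dev), length(sp$test))
  for (part in sp) expect_length(unique(lab_of(part)), 2L)
})

test_that("warm-up training reduces the classification loss", {
  h <- res60$model$history
  warm <- h[h$phase == "warmup", ]
  expect_gt(warm$loss2[1], warm$loss2[nrow(warm)])
})

test_that("the full model learns the planted structure", {
  expect_gte(res60$report$f1, 0.8)
  expect_gte(res60$indicator_recall, 0.8)
})

test_that("training is exactly reproducible under a fixed seed", {
  cfg <- eran_validation_config(warmup_epochs = 2L, rl_epochs = 2L)
  sp <- res60$splits
  r1 <- train_eran(sp$train[1:20], sp$dev, res60$vocab, res60$emotion_net,
                   cfg, seed = 77)
  r2 <- train_eran(sp$train[1:20], sp$dev, res60$vocab, res60$emotion_net,
                   cfg, seed = 77)
  e1 <- evaluate(r1, sp$test)
  e2 <- evaluate(r2, sp$test)
  expect_identical(e1[c("accuracy", "precision", "recall", "f1")],
                   e2[c("accuracy", "precision", "recall", "f1")])
  expect_identical(r1$params, r2$params)
  expect_identical(unclass(r1$theta), unclass(r2$theta))
})

test_that("the frozen emotion network is untouched by main training", {
  expect_identical(res60$model$emotion_net$params, res60$emotion_net$params)
})

test_that("ablation variants have the documented structure", {
  sp <- res60$splits
  cfg_fast <- eran_validation_config(warmup_epochs = 2L, rl_epochs = 1L)
  # EBAtt: no selection; the selected set is all posts by construction
  cfg_eb <- eran_validation_config(warmup_epochs = 2L, rl_epochs = 1L,
                                   no_rl = TRUE)
  m_eb <- train_eran(sp$train[1:16], NULL, res60$vocab, res60$emotion_net,
                     cfg_eb, seed = 5)
  sel <- selected_indices(m_eb, sp$test[1:4])
  for (i in seq_along(sel))
    expect_equal(sel[[i]], seq_len(length(sp$test[[i]]$posts)))
  # RLAtt: fused representation shrinks by d_e
  cfg_rl <- eran_validation_config(warmup_epochs = 2L, rl_epochs = 1L,
                                   no_emotion = TRUE)
  m_rl <- train_eran(sp$train[1:16], NULL, res60$vocab, NULL, cfg_rl, seed = 5)
  m_full <- train_eran(sp$train[1:16], NULL, res60$vocab, res60$emotion_net,
                       cfg_fast, seed = 5)
  expect_equal(nrow(m_full$params$cls$W) - nrow(m_rl$params$cls$W),
               res60$emotion_net$d_e)
  # emotion-in-state ablation shrinks the policy state by d_e
  cfg_st <- eran_validation_config(warmup_epochs = 2L, rl_epochs = 1L,
                                   no_emotion_in_state = TRUE)
  m_st <- train_eran(sp$train[1:16], NULL, res60$vocab, res60$emotion_net,
                     cfg_st, seed = 5)
  expect_equal(m_full$state_dim - m_st$state_dim, res60$emotion_net$d_e)
})

test_that("greedy selection partitions every user's posts", {
  sel <- attr(res60$report, "selected")
  for (h in res60$splits$test) {
    s <- sel[[h$user_id]]
    expect_true(all(s %in% seq_along(h$posts)))
    expect_false(anyDuplicated(s) > 0)
  }
})

test_that("attention export sums to one per user and keeps post order", {
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- export_attention_viz(res60$model, res60$splits$test[1:6], f)
  expect_true(file.exists(f))
  back <- utils::read.delim(f)
  expect_equal(names(back), c("user_id", "post_index", "weight", "text"))
  for (uid in unique(df$user_id)) {
    d <- df[df$user_id == uid, ]
    expect_equal(sum(d$weight), 1, tolerance = 1e-6)
    expect_false(is.unsorted(d$post_index))
  }
  f2 <- withr::local_tempfile(fileext = ".tsv")
  sr <- export_selection_report(res60$model, res60$splits$test[1:4], f2)
  expect_true(all(sr$policy_prob > 0 & sr$policy_prob < 1))
  expect_true(all(sr$action %in% 0:1))
})

test_that("top-weight posts of depressed users are planted indicators", {
  dep_test <- Filter(function(h) h$label == 1L, res60$splits$test)
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- export_attention_viz(res60$model, dep_test, f)
  hit <- 0L
  for (uid in unique(df$user_id)) {
    d <- df[df$user_id == uid, ]
    top <- d$post_index[which.max(d$weight)]
    hit <- hit + (top %in% dat60$truth[[uid]])
  }
  expect_gte(hit / length(unique(df$user_id)), 0.8)
})
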