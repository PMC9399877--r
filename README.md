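# eran

Depression detection from social-media post histories with an
emotion-based reinforcement attention network (ERAN), implemented and
validated entirely in R.

## The problem

A user's post history is a long, mostly mundane stream in which only a
small minority of posts signal depressive state, and supervision exists
only at the user level — nothing marks *which* posts matter. `eran`
classifies users as depressed/non-depressed by learning, with
user-level labels alone, to pick out the depression-indicator posts and
weigh them.

The model combines three parts:

* **Emotion extraction network** — a TextCNN (three filter heights,
  max-over-time pooling) pretrained on a positive/negative/neutral
  emotion task; its last hidden layer is the per-post emotion vector
  `e^t`, and the mean over a user's posts is the emotion expectation
  `v_emo`. Frozen after pretraining.
* **RL selection layer** — a REINFORCE policy walks the posts in order;
  its state `s^t = [p^t ; avg(selected) ; e^t]` combines the current
  post's BiLSTM vector `p^t`, the running mean of already-selected post
  vectors, and the post's emotion vector. The terminal reward of an
  episode is the classifier's probability of the user's gold label given
  the selected set `H^dep`, with the within-batch mean reward as
  baseline:
  `∇J(θ) = (1/N) Σ_n (R(τ_n) − b) Σ_t ∇ log π(a_n^t | s_n^t; θ)`.
* **Sentence-level attention + fused classifier** — selected posts are
  scored by `u_t = tanh(W_s p_t + b_s)` against a trainable context
  vector `u_s`, softmax-normalised (`α_t`), pooled as `Σ_t α_t p_t`,
  concatenated with `v_emo`, and classified by a 2-class softmax with
  categorical cross-entropy. Metrics follow `P = TP/(TP+FP)`,
  `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)` on the depressed class.

All forward and backward passes (TextCNN, BiLSTM with PAD masking,
attention head, policy gradient) are hand-written in base R and verified
against finite differences and exhaustive-enumeration oracles in the
test suite. A synthetic-data generator with planted indicator posts
makes every stage testable without access to any real cohort.

## Worked example

Train on a synthetic cohort of 200 balanced users, 20 posts each, in
which depressed users hide 3 indicator posts (depression words mixed
with negative-emotion words) among everyday filler, neutral, positive
and plain-negative posts (about half a minute on one CPU):

```r
library(eran)

gen <- generator_config(n_users = 200L, posts_per_user = c(20L, 20L),
                        indicator_fraction = 0.15, noise_rate = 0.05,
                        corpus_size = 600L, seed = 13)
res <- eran_experiment(gen, eran_validation_config(), seed = 13)

res$report
#> acc 0.925  P 0.870  R 1.000  F1 0.930  (TP 20 FP 3 FN 0 TN 17)
round(res$indicator_recall, 3)
#> [1] 1
round(attr(res$emotion_net, "val_accuracy"), 3)
#> [1] 1
```

The emotion network separates the pretraining corpus perfectly, the
model reaches F1 0.93 on held-out users, and every planted indicator
post of the test users ends up in the selected set (`indicator_recall`
= 1). Attention weights over a test user's selected posts show where
the classifier looks:

```r
f <- tempfile(fileext = ".tsv")
df <- export_attention_viz(res$model, res$splits$test[1:2], f)
head(df[order(df$user_id, -df$weight), ], 3)
#>  user_id post_index     weight                                            text
#>    u0017         12 0.13985496           out ashamed just worry worried broken
#>    u0017         13 0.13924106                            worst angry into has
#>    u0017          8 0.11162553 much video team two shop into like office still
```

`run_ablation()` trains the EBAtt (no selection), RLAtt (no emotion
network) and ERN (uniform averaging) variants under shared seeds, and
`subset_experiment()` retrains a plain BiLSTM baseline on the selected
(`H^dep`), original (`H^orig`) and unselected (`H^non`) post sets to
show that selection concentrates the signal.

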