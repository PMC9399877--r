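# Synthetic study data: a 3-class emotion corpus and labelled user
# histories with planted depression-indicator posts, so the whole pipeline
# (emotion pretraining, selection, classification) is testable end to end
# without access to any real social-media dataset.

#' Built-in word lexicons for the synthetic generator
#'
#' Five pairwise-disjoint word lists: the three emotion classes
#' (positive, negative, neutral), a depression-indicator list, and
#' semantically empty filler. Around 40 words per class, in the spirit of
#' short social-media vocabulary ("depressed", "suck", "die", "nice", ...).
#'
#' @return named list of character vectors.
#' @export
eran_lexicons <- function() {
  list(
    positive = c("happy", "nice", "great", "awesome", "love", "proud",
                 "excited", "fun", "amazing", "wonderful", "joy", "smile",
                 "laugh", "blessed", "grateful", "beautiful", "win",
                 "winning", "best", "sunshine", "cheerful", "delighted",
                 "fantastic", "glad", "brilliant", "cool", "sweet",
                 "thrilled", "yay", "celebrate", "enjoy", "lovely",
                 "perfect", "super", "terrific", "upbeat", "warm", "bliss",
                 "cheers", "sunny"),
    negative = c("sad", "suck", "sucks", "angry", "hate", "awful",
                 "terrible", "cry", "crying", "tired", "miserable",
                 "horrible", "upset", "mad", "annoyed", "pain", "hurt",
                 "lonely", "alone", "fear", "afraid", "scared", "gloomy",
                 "bad", "worst", "sick", "stress", "stressed", "frustrated",
                 "anxious", "worry", "worried", "broken", "dark", "empty",
                 "numb", "tears", "bitter", "regret", "ashamed"),
    neutral = c("today", "weather", "coffee", "lunch", "train", "meeting",
                "news", "phone", "book", "movie", "game", "traffic",
                "morning", "afternoon", "monday", "tuesday", "office",
                "email", "shop", "store", "street", "city", "music",
                "song", "video", "photo", "recipe", "dinner", "breakfast",
                "bus", "work", "school", "class", "homework", "weekend",
                "match", "score", "team", "update", "schedule"),
    depression_indicator = c("depressed", "depression", "depressive", "die",
                 "dying", "suicide", "suicidal", "worthless", "hopeless",
                 "helpless", "insomnia", "sleepless", "meds", "medication",
                 "antidepressant", "therapy", "therapist", "diagnosed",
                 "disorder", "relapse", "selfharm", "overdose", "despair",
                 "pointless", "useless", "burden", "drained", "exhausted",
                 "unloved", "unwanted", "trapped", "numbness", "grieving",
                 "psychiatrist", "breakdown", "panic", "void", "misery",
                 "endless", "suffering"),
    filler = c("the", "a", "and", "so", "just", "really", "very", "with",
               "this", "that", "for", "about", "some", "then", "when",
               "what", "going", "got", "get", "have", "has", "was", "were",
               "will", "can", "out", "over", "here", "there", "now",
               "still", "also", "been", "from", "into", "like", "much",
               "more", "one", "two")
  )
}

#' Configuration for the synthetic-data generator
#'
#' The defaults define the study conditions used throughout the package's
#' validation: balanced cohorts in which depressed users plant a small
#' minority of indicator posts (depression words mixed with
#' negative-emotion words) among everyday filler.
#'
#' @param n_users number of users (must be even; classes are balanced).
#' @param posts_per_user length-2 range `c(min, max)` of posts per user;
#'   histories shorter than 15 posts mimic nothing seen in practice, so the
#'   default starts there.
#' @param indicator_fraction fraction of a depressed user's posts that are
#'   indicator posts (default 0.15; only a small share of a depressed
#'   user's feed touches on depression).
#' @param noise_rate word-level label noise in (0, 1): probability that an
#'   emotion-class word is swapped for a word of another emotion class.
#' @param corpus_size number of posts in the emotion pretraining corpus.
#' @param lexicons named list as from [eran_lexicons()].
#' @param seed integer seed; every generator call is deterministic in it.
#' @return a `generator_config` object.
#' @export
generator_config <- function(n_users = 200L,
                             posts_per_user = c(15L, 25L),
                             indicator_fraction = 0.15,
                             noise_rate = 0.05,
                             corpus_size = 300L,
                             lexicons = eran_lexicons(),
                             seed = 1L) {
  if (length(posts_per_user) == 1L) posts_per_user <- rep(posts_per_user, 2L)
  if (posts_per_user[[1]] < 1L)
    stop("posts_per_user minimum must be >= 1", call. = FALSE)
  if (indicator_fraction <= 0 || indicator_fraction >= 1)
    stop("indicator_fraction must be in (0, 1)", call. = FALSE)
  if (noise_rate < 0 || noise_rate >= 1)
    stop("noise_rate must be in [0, 1)", call. = FALSE)
  needed <- c("positive", "negative", "neutral", "depression_indicator", "filler")
  missing <- setdiff(needed, names(lexicons))
  if (length(missing))
    stop("lexicons missing: ", paste(missing, collapse = ", "), call. = FALSE)
  if (any(lengths(lexicons[needed]) == 0L))
    stop("all lexicons must be non-empty", call. = FALSE)
  structure(list(n_users = as.integer(n_users),
                 posts_per_user = as.integer(posts_per_user),
                 indicator_fraction = indicator_fraction,
                 noise_rate = noise_rate,
                 corpus_size = as.integer(corpus_size),
                 lexicons = lexicons,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# One synthetic post for an emotion class: 2-4 class-lexicon words mixed
# with filler. Noise is additive contamination: with probability
# noise_rate * length(words) the post gains one out-of-class emotion
# word. The own-class words always outnumber the contaminant, so the
# corpus stays linearly separable at every validation noise rate while
# the contamination still confuses word-level feature detectors.
# Caller supplies RNG state.
synth_emotion_post <- function(class, lex, noise_rate) {
  n_class <- 2L + stats::rbinom(1L, 2L, 0.5)
  words <- c(sample(lex[[class]], n_class, replace = TRUE),
             sample(lex$filler, sample(2:5, 1L), replace = TRUE))
  if (noise_rate > 0 &&
      stats::runif(1) < min(1, noise_rate * length(words))) {
    others <- unlist(lex[setdiff(c("positive", "negative", "neutral"), class)])
    words <- c(words, sample(others, 1L))
  }
  paste(sample(words), collapse = " ")
}

# Indicator post: depression words plus negative-emotion words plus filler;
# with probability noise_rate each depression word softens to a plain
# negative word.
synth_indicator_post <- function(lex, noise_rate) {
  dep <- sample(lex$depression_indicator, 2L, replace = TRUE)
  if (noise_rate > 0) {
    flip <- stats::runif(2L) < noise_rate
    if (any(flip)) dep[flip] <- sample(lex$negative, sum(flip), replace = TRUE)
  }
  words <- c(dep,
             sample(lex$negative, sample(1:2, 1L), replace = TRUE),
             sample(lex$filler, sample(1:3, 1L), replace = TRUE))
  paste(sample(words), collapse = " ")
}

#' Generate a balanced three-class emotion corpus
#'
#' Deterministic given `cfg$seed`. Classes are balanced (sizes differ by at
#' most one when `corpus_size` is not divisible by 3).
#'
#' @param cfg a [generator_config()].
#' @return data.frame with columns `text`, `label` — the same shape
#'   [read_emotion_corpus()] returns.
#' @export
generate_emotion_corpus <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  n <- cfg$corpus_size
  counts <- rep(n %/% 3L, 3L)
  if (n %% 3L) counts[seq_len(n %% 3L)] <- counts[seq_len(n %% 3L)] + 1L
  labels <- rep(c("positive", "negative", "neutral"), counts)
  with_seed(cfg$seed, {
    labels <- sample(labels)
    text <- vapply(labels, function(lab) {
      post <- synth_emotion_post(lab, cfg$lexicons, cfg$noise_rate)
      if (lab == "negative") {
        # depressive vocabulary is negative-sentiment vocabulary: some
        # negative posts carry it, which is how emotion pretraining gives
        # depression words emotion-bearing embeddings
        k <- stats::rbinom(1L, 2L, 0.4)
        if (k > 0)
          post <- paste(c(post, sample(cfg$lexicons$depression_indicator, k)),
                        collapse = " ")
      }
      post
    }, character(1))
    data.frame(text = unname(text), label = labels, stringsAsFactors = FALSE)
  })
}

#' Generate labelled user histories with planted indicator posts
#'
#' Half the users are labelled depressed and carry
#' `ceiling(indicator_fraction * T)` indicator posts at random positions;
#' all remaining posts (and every post of a non-depressed user) are
#' filler/neutral/positive content containing no depression-lexicon words.
#'
#' @param cfg a [generator_config()]; `n_users` must be even.
#' @return list with `histories` (list of [user_history()]) and `truth`
#'   (named list: user_id -> integer indices of planted indicator posts,
#'   empty for non-depressed users).
#' @export
generate_user_histories <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (cfg$n_users %% 2L != 0L)
    stop("n_users must be even so classes balance", call. = FALSE)
  lex <- cfg$lexicons
  # Non-indicator content: everyday filler/neutral/positive posts. Users of
  # both classes additionally post plain negative-emotion content now and
  # then (bad days happen to everyone) — such posts carry negative words
  # but never depression words, so they are emotional confusers the
  # selector must tell apart from true indicator posts.
  bg_classes <- c("positive", "neutral", "filler", "negative")
  with_seed(cfg$seed, {
    labels <- sample(rep(c(1L, 0L), each = cfg$n_users / 2L))
    histories <- vector("list", cfg$n_users)
    truth <- vector("list", cfg$n_users)
    T_range <- seq(cfg$posts_per_user[[1]], cfg$posts_per_user[[2]])
    for (i in seq_len(cfg$n_users)) {
      T_i <- if (length(T_range) == 1L) T_range else sample(T_range, 1L)
      posts <- character(T_i)
      idx <- integer(0)
      if (labels[[i]] == 1L) {
        n_ind <- ceiling(cfg$indicator_fraction * T_i)
        idx <- sort(sample.int(T_i, n_ind))
      }
      for (t in seq_len(T_i)) {
        if (t %in% idx) {
          posts[[t]] <- synth_indicator_post(lex, cfg$noise_rate)
        } else {
          cls <- sample(bg_classes, 1L)
          posts[[t]] <- if (cls == "filler")
            paste(sample(lex$filler, sample(4:8, 1L), replace = TRUE),
                  collapse = " ")
          else
            synth_emotion_post(cls, lex, cfg$noise_rate)
        }
      }
      uid <- sprintf("u%04d", i)
      histories[[i]] <- user_history(uid, labels[[i]], posts)
      truth[[uid]] <- idx
    }
    list(histories = histories, truth = truth)
  })
}

#' Recall of planted indicator posts under a selection
#'
#' Micro-averaged over depressed users: the number of planted indicator
#' posts that were selected, divided by the total number planted.
#'
#' @param selected named list: user_id -> integer indices the selector chose.
#' @param truth named list as returned by [generate_user_histories()].
#' @return scalar in \[0, 1\].
#' @export
indicator_recall <- function(selected, truth) {
  planted <- sum(lengths(truth))
  if (planted == 0L)
    stop("no planted indicator posts: recall is undefined", call. = FALSE)
  hit <- 0L
  for (uid in names(truth)) {
    if (length(truth[[uid]]) == 0L) next
    sel <- selected[[uid]]
    if (!is.null(sel) && length(sel)) {
      if (any(sel < 1L)) stop("invalid post index for user ", uid, call. = FALSE)
      hit <- hit + length(intersect(truth[[uid]], sel))
    }
  }
  hit / planted
}
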