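# Reading/writing user histories and emotion corpora, embedding loading,
# vocabulary construction, tokenisation and padding.
#
# File formats:
#  * user histories — JSON lines, one user per line with fields
#    user_id (string), label (0/1), posts (array of strings);
#  * emotion corpus — two-column TSV (text <TAB> label), no header,
#    labels in {positive, negative, neutral};
#  * embeddings — word2vec text format (header "count dim", then one
#    "token v1 ... vd" line per token).

EMOTION_CLASSES <- c("positive", "negative", "neutral")

#' Construct a user history
#'
#' A user history is the unit of classification: one user's ordered posts
#' (chronological order as given) plus a binary label, 1 = depressed.
#'
#' @param user_id character scalar.
#' @param label 0 or 1 (1 = depressed).
#' @param posts character vector of at least one post.
#' @return an object of class `user_history`.
#' @export
user_history <- function(user_id, label, posts) {
  label <- as.integer(label)
  if (length(label) != 1L || is.na(label) || !label %in% c(0L, 1L))
    stop("label must be 0 or 1, got: ", label, call. = FALSE)
  posts <- as.character(posts)
  if (length(posts) < 1L) stop("a user history needs at least one post", call. = FALSE)
  structure(list(user_id = as.character(user_id), label = label, posts = posts),
            class = "user_history")
}

#' @export
print.user_history <- function(x, ...) {
  cat(sprintf("<user_history %s: label=%d, T=%d posts>\n",
              x$user_id, x$label, length(x$posts)))
  invisible(x)
}

#' Read user histories from a JSON-lines file
#'
#' @param path path to a UTF-8 JSONL file, one user per line.
#' @return list of [user_history()] objects, in file order.
#' @export
read_user_histories <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                    error = function(e)
                      stop("malformed JSON on line ", i, ": ",
                           conditionMessage(e), call. = FALSE))
    if (!all(c("user_id", "label", "posts") %in% names(rec)))
      stop("line ", i, ": missing user_id/label/posts field", call. = FALSE)
    lab <- suppressWarnings(as.integer(rec$label))
    if (is.na(lab) || !lab %in% c(0L, 1L))
      stop("line ", i, ": label must be 0 or 1, got ", rec$label, call. = FALSE)
    out[[i]] <- user_history(rec$user_id, lab, unlist(rec$posts))
  }
  out
}

#' Write user histories as JSON lines
#'
#' Inverse of [read_user_histories()]: the round trip reproduces the file
#' record for record.
#' @param histories list of `user_history` objects.
#' @param path output path.
#' @export
write_user_histories <- function(histories, path) {
  lines <- vapply(histories, function(h) {
    jsonlite::toJSON(list(user_id = jsonlite::unbox(h$user_id),
                          label = jsonlite::unbox(h$label),
                          posts = h$posts))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a three-class emotion corpus from TSV
#'
#' @param path two-column TSV (text, label), no header; labels must be
#'   `positive`, `negative` or `neutral`.
#' @return data.frame with columns `text`, `label`.
#' @export
read_emotion_corpus <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("emotion corpus is empty: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop("line ", bad[1L], ": expected exactly one tab separator", call. = FALSE)
  text <- vapply(parts, `[[`, character(1), 1L)
  label <- vapply(parts, `[[`, character(1), 2L)
  unknown <- setdiff(unique(label), EMOTION_CLASSES)
  if (length(unknown))
    stop("unknown emotion label(s): ", paste(unknown, collapse = ", "),
         " (expected positive/negative/neutral)", call. = FALSE)
  data.frame(text = text, label = label, stringsAsFactors = FALSE)
}

#' Write an emotion corpus as TSV
#' @param corpus data.frame with `text` and `label` columns.
#' @param path output path.
#' @export
write_emotion_corpus <- function(corpus, path) {
  writeLines(paste(corpus$text, corpus$label, sep = "\t"), path, useBytes = TRUE)
  invisible(path)
}

#' Tokenize a post
#'
#' Lowercases, replaces URLs with the token `urltok` and \code{@}-mentions
#' with `usertok`, then splits on non-alphanumeric characters.
#' Deterministic; no external resources.
#'
#' @param text character scalar.
#' @return character vector of tokens (possibly empty).
#' @export
tokenize <- function(text) {
  x <- tolower(text)
  x <- gsub("https?://\\S+|www\\.\\S+", " urltok ", x, perl = TRUE)
  x <- gsub("@[A-Za-z0-9_]+", " usertok ", x, perl = TRUE)
  toks <- strsplit(x, "[^a-z0-9]+")[[1]]
  toks[nzchar(toks)]
}

#' Build a vocabulary with randomly initialised embeddings
#'
#' Id 0 is reserved for PAD (zero embedding), id 1 for UNK. All other
#' embedding rows are initialised uniformly in \[-0.25, 0.25\] with a
#' seeded generator; use [load_embeddings()] when pretrained word2vec
#' vectors are available.
#'
#' @param texts character vector whose tokens populate the vocabulary.
#' @param d embedding dimension (default 300, the usual word2vec size).
#' @param seed RNG seed for the random rows.
#' @return a `vocabulary` object: `tokens` (id-ordered, starting at PAD),
#'   `index` (token to 0-based id), `embeddings` (vocab_size x d matrix).
#' @export
build_vocabulary <- function(texts, d = 300L, seed = 1L) {
  toks <- unique(unlist(lapply(texts, tokenize)))
  tokens <- c("<pad>", "<unk>", sort(toks))
  V <- length(tokens)
  emb <- with_seed(seed, {
    m <- matrix(stats::runif(V * d, -0.25, 0.25), nrow = V, ncol = d)
    m[1L, ] <- 0                 # PAD stays zero so masking is "id != 0"
    m
  })
  new_vocabulary(tokens, emb)
}

new_vocabulary <- function(tokens, embeddings) {
  index <- seq_along(tokens) - 1L  # 0-based ids
  names(index) <- tokens
  structure(list(tokens = tokens, index = index, embeddings = embeddings),
            class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("<vocabulary: %d tokens, d=%d>\n",
              length(x$tokens), ncol(x$embeddings)))
  invisible(x)
}

vocab_size <- function(vocab) length(vocab$tokens)

#' Load word embeddings in word2vec text format
#'
#' The file must start with a header line `count dim` followed by one
#' `token v1 ... vd` line per token. A PAD row (all zeros, id 0) and an
#' UNK row (the mean of the loaded vectors, id 1) are prepended.
#'
#' @param path path to a word2vec text file.
#' @param d expected dimension; checked against the header when given.
#' @return a `vocabulary` object.
#' @export
load_embeddings <- function(path, d = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  header <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  if (length(header) != 2L)
    stop("expected word2vec header 'count dim', got: ", lines[[1]], call. = FALSE)
  V <- as.integer(header[[1]]); dim_hdr <- as.integer(header[[2]])
  if (!is.null(d) && d != dim_hdr)
    stop("embedding dimension mismatch: header says ", dim_hdr,
         ", expected ", d, call. = FALSE)
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  if (length(body) != V)
    stop("header promises ", V, " vectors, file has ", length(body), call. = FALSE)
  toks <- character(V)
  mat <- matrix(NA_real_, nrow = V, ncol = dim_hdr)
  for (i in seq_len(V)) {
    parts <- strsplit(trimws(body[[i]]), "\\s+")[[1]]
    if (length(parts) != dim_hdr + 1L)
      stop("line ", i + 1L, ": expected ", dim_hdr + 1L,
           " fields, got ", length(parts), call. = FALSE)
    toks[[i]] <- parts[[1]]
    mat[i, ] <- as.numeric(parts[-1L])
  }
  stopifnot_finite(mat, "embedding file")
  emb <- rbind(0, colMeans(mat), mat)  # PAD, UNK, then loaded rows
  new_vocabulary(c("<pad>", "<unk>", toks), emb)
}

#' Write embeddings in word2vec text format (PAD/UNK rows excluded)
#' @keywords internal
write_embeddings <- function(vocab, path) {
  keep <- seq_len(vocab_size(vocab))[-(1:2)]
  lines <- c(paste(length(keep), ncol(vocab$embeddings)),
             vapply(keep, function(i) {
               paste(c(vocab$tokens[[i]],
                       formatC(vocab$embeddings[i, ], format = "g", digits = 8)),
                     collapse = " ")
             }, character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Tokenize a post and pad/truncate to a fixed length
#'
#' @param text character scalar.
#' @param vocab a `vocabulary`.
#' @param n target length (>= 1).
#' @return integer vector of exactly `n` 0-based token ids; out-of-vocabulary
#'   tokens map to UNK (1), trailing slots are PAD (0).
#' @export
tokenize_and_pad <- function(text, vocab, n) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  toks <- tokenize(text)
  ids <- unname(vocab$index[toks])
  ids[is.na(ids)] <- 1L  # UNK
  ids <- as.integer(ids)
  if (length(ids) >= n) ids[seq_len(n)] else c(ids, integer(n - length(ids)))
}

# Token-id matrix (B x n) for a character vector of posts.
encode_posts <- function(texts, vocab, n) {
  out <- matrix(0L, nrow = length(texts), ncol = n)
  for (i in seq_along(texts)) out[i, ] <- tokenize_and_pad(texts[[i]], vocab, n)
  out
}
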