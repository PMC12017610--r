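#' Word-timestamped transcript container
#'
#' The shape produced by automatic-speech-recognition backends: an ordered
#' list of words with onset/offset seconds, plus the task clock origin.
#'
#' @param words Data frame with columns `token`, `onset_s`, `offset_s`
#'   (zero rows allowed). Words must be sorted by onset, non-overlapping,
#'   with `onset < offset`.
#' @param task_start_s Clock origin of the task (s), default 0.
#' @return A `timed_transcript`.
#' @export
timed_transcript <- function(words, task_start_s = 0) {
  words <- as.data.frame(words)
  if (nrow(words) == 0)
    words <- data.frame(token = character(0), onset_s = numeric(0),
                        offset_s = numeric(0))
  stopifnot(all(c("token", "onset_s", "offset_s") %in% names(words)))
  if (nrow(words) > 0) {
    if (any(words$offset_s <= words$onset_s))
      stop("each word must have onset_s < offset_s")
    if (is.unsorted(words$onset_s))
      stop("words must be sorted by onset_s")
    if (nrow(words) > 1 &&
        any(words$onset_s[-1] < words$offset_s[-nrow(words)]))
      stop("word intervals must not overlap")
  }
  structure(list(words = words[, c("token", "onset_s", "offset_s")],
                 task_start_s = task_start_s),
            class = "timed_transcript")
}

#' @export
print.timed_transcript <- function(x, ...) {
  cat(sprintf("<timed_transcript: %d words, task start %.2f s>\n",
              nrow(x$words), x$task_start_s))
  invisible(x)
}

#' Read a transcript from JSON
#'
#' Schema: `{"task_start_s": float, "words": [{"w": str, "start_s": float,
#' "end_s": float}, ...]}`.
#'
#' @param path JSON file path.
#' @return A [timed_transcript()].
#' @export
read_transcript_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  words <- j$words
  if (is.null(words) || (is.data.frame(words) && nrow(words) == 0) ||
      length(words) == 0) {
    return(timed_transcript(data.frame(), task_start_s = j$task_start_s %||% 0))
  }
  timed_transcript(
    data.frame(token = words$w, onset_s = words$start_s, offset_s = words$end_s),
    task_start_s = j$task_start_s %||% 0)
}

#' Write a transcript to JSON
#' @param transcript A [timed_transcript()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcript_json <- function(transcript, path) {
  w <- transcript$words
  jsonlite::write_json(
    list(task_start_s = transcript$task_start_s,
         words = data.frame(w = w$token, start_s = w$onset_s, end_s = w$offset_s)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize text to a token list
#'
#' Lowercases, strips punctuation (any character that is not a letter,
#' digit or whitespace becomes a separator) and splits on whitespace.
#' Deterministic and idempotent.
#'
#' @param text Character scalar (or vector, concatenated with spaces).
#' @return Character vector of tokens (possibly empty).
#' @export
normalize_tokens <- function(text) {
  s <- tolower(paste(text, collapse = " "))
  s <- gsub("[^\\p{L}\\p{N}]+", " ", s, perl = TRUE)
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Reference story for the prose-recall task
#'
#' @param raw_text The story as plain text (character scalar).
#' @return A `reference_story` with `raw_text` and normalized `tokens`
#'   (must be nonempty).
#' @export
reference_story <- function(raw_text) {
  tokens <- normalize_tokens(raw_text)
  if (length(tokens) == 0) stop("story normalizes to zero tokens")
  structure(list(raw_text = raw_text, tokens = tokens),
            class = "reference_story")
}

#' Read a reference story from a UTF-8 text file
#' @param path File path.
#' @return A [reference_story()].
#' @export
read_story <- function(path) {
  reference_story(paste(readLines(path, encoding = "UTF-8", warn = FALSE),
                        collapse = "\n"))
}

#' Word count and story-match count
#'
#' `n_words` is the number of transcript words; `n_matched` counts the
#' transcript tokens whose normalized form occurs in the story's token set
#' (type-level membership; each transcript token counts once).
#'
#' @param transcript A [timed_transcript()].
#' @param story A [reference_story()].
#' @return One-row tibble `n_words`, `n_matched`.
#' @export
count_features <- function(transcript, story) {
  stopifnot(inherits(transcript, "timed_transcript"),
            inherits(story, "reference_story"))
  toks <- unlist(lapply(transcript$words$token, normalize_tokens))
  story_set <- unique(story$tokens)
  tibble::tibble(n_words = nrow(transcript$words),
                 n_matched = sum(toks %in% story_set))
}

#' Latency time and mean intraword time
#'
#' Latency is the delay from the task clock origin to the first word onset.
#' Mean intraword time is, by default, the mean onset-to-onset interval
#' between consecutive words (per-word production time including
#' articulation); set `intraword = "gap"` for the offset-to-next-onset
#' convention instead.
#'
#' @param transcript A [timed_transcript()].
#' @param intraword `"onset"` (default) or `"gap"`.
#' @return One-row tibble `latency_s`, `mean_intraword_s` (`NA` when not
#'   defined: no words for latency, fewer than two words for intraword).
#' @export
timing_scores <- function(transcript, intraword = c("onset", "gap")) {
  stopifnot(inherits(transcript, "timed_transcript"))
  intraword <- match.arg(intraword)
  w <- transcript$words
  n <- nrow(w)
  latency <- if (n >= 1) w$onset_s[1] - transcript$task_start_s else NA_real_
  miw <- if (n >= 2) {
    if (intraword == "onset") mean(diff(w$onset_s))
    else mean(w$onset_s[-1] - w$offset_s[-n])
  } else NA_real_
  tibble::tibble(latency_s = latency, mean_intraword_s = miw)
}

#' Read a word-embedding table
#'
#' Whitespace-delimited text, one word followed by its vector per line
#' (word2vec text format); an optional first line `"<n> <d>"` (two integer
#' fields) is treated as a count header and skipped. Duplicate words are an
#' error; all vectors must share one dimension.
#'
#' @param path File path.
#' @return An `embedding_table`: numeric matrix, one row per word, words as
#'   rownames.
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty embedding file: ", path)
  first <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(first) == 2 && !anyNA(suppressWarnings(as.integer(first))))
    lines <- lines[-1]
  parts <- strsplit(trimws(lines), "\\s+")
  words <- vapply(parts, `[`, character(1), 1)
  if (anyDuplicated(words))
    stop("duplicate words in embedding table: ",
         paste(unique(words[duplicated(words)]), collapse = ", "))
  vecs <- lapply(parts, function(p) as.numeric(p[-1]))
  d <- unique(lengths(vecs))
  if (length(d) != 1 || d == 0 || anyNA(unlist(vecs)))
    stop("embedding vectors must be numeric and share one dimension")
  m <- do.call(rbind, vecs)
  rownames(m) <- words
  embedding_table(m)
}

#' Construct an embedding table from a matrix
#' @param m Numeric matrix with words as rownames.
#' @return An `embedding_table`.
#' @export
embedding_table <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m), !is.null(rownames(m)),
            !anyDuplicated(rownames(m)), ncol(m) >= 1)
  structure(m, class = c("embedding_table", "matrix", "array"))
}

#' Full language feature panel for one transcript
#'
#' @param transcript A [timed_transcript()].
#' @param story A [reference_story()].
#' @param embeddings An `embedding_table` (or `NULL` to skip WMD).
#' @param intraword Convention passed to [timing_scores()].
#' @return One-row tibble: `n_words`, `n_matched`, `latency_s`,
#'   `mean_intraword_s`, `wmd`.
#' @export
language_features <- function(transcript, story, embeddings = NULL,
                              intraword = "onset") {
  counts <- count_features(transcript, story)
  timing <- timing_scores(transcript, intraword = intraword)
  wmd <- NA_real_
  if (!is.null(embeddings)) {
    doc <- unlist(lapply(transcript$words$token, normalize_tokens))
    wmd_res <- tryCatch(
      word_movers_distance(doc, story$tokens, embeddings),
      error = function(e) NA_real_)
    wmd <- as.numeric(wmd_res)
  }
  tibble::as_tibble(cbind(counts, timing, tibble::tibble(wmd = wmd)))
}
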