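# Shared fixtures, built in code at test time.

# small deterministic embedding over a fixed toy vocabulary
toy_embedding <- function(words = letters[1:6], d = 3, seed = 42) {
  set.seed(seed)
  m <- matrix(stats::rnorm(length(words) * d), length(words), d,
              dimnames = list(words, NULL))
  embedding_table(m)
}

# exhaustive integer-transport oracle: enumerates every feasible integer
# plan recursively (tiny instances only) and returns the minimal cost per
# unit of total mass
brute_transport <- function(s, d, C) {
  m <- length(s); n <- length(d)
  best <- Inf
  rec <- function(i, d_rem, acc) {
    if (acc >= best) return()
    if (i > m) { if (all(d_rem == 0)) best <<- acc; return() }
    alloc <- function(j, left, cost_acc) {
      if (acc + cost_acc >= best) return()
      if (j == n) {
        if (left <= d_rem[n]) {
          d_rem[n] <<- d_rem[n] - left
          rec(i + 1, d_rem, acc + cost_acc + left * C[i, n])
          d_rem[n] <<- d_rem[n] + left
        }
        return()
      }
      for (a in 0:min(left, d_rem[j])) {
        d_rem[j] <<- d_rem[j] - a
        alloc(j + 1, left - a, cost_acc + a * C[i, j])
        d_rem[j] <<- d_rem[j] + a
      }
    }
    alloc(1, s[i], 0)
  }
  rec(1, d, 0)
  best / sum(s)
}

# WMD via the oracle, mirroring the bag-of-words reduction
oracle_wmd <- function(doc, ref, emb) {
  tc <- table(doc); rc <- table(ref)
  ei <- emb[names(tc), , drop = FALSE]
  ej <- emb[names(rc), , drop = FALSE]
  C <- sqrt(pmax(outer(rowSums(ei^2), rowSums(ej^2), `+`) - 2 * ei %*% t(ej), 0))
  C[outer(names(tc), names(rc), `==`)] <- 0
  su <- as.numeric(tc) * sum(rc)
  du <- as.numeric(rc) * sum(tc)
  brute_transport(su, du, C)
}

# standard three-segment session: speech / silence / speech
make_session <- function(pause_s = 0.5, speech_s = 1.0, f0 = 120, seed = 7,
                         word_plan = NULL) {
  if (is.null(word_plan))
    word_plan <- data.frame(token = c("ciao", "mondo"),
                            onset_s = c(0.10, 0.45),
                            offset_s = c(0.35, 0.80))
  synthesize_session(session_spec(
    data.frame(kind = c("speech", "silence", "speech"),
               duration_s = c(speech_s, pause_s, speech_s)),
    word_plan, pulse_train_spec(f0, 1), seed = seed))
}

# small effect-map cohort for association/model tests
basic_effect_map <- function() {
  data.frame(feature = c("silence_ratio", "intraword", "jitter_x"),
             target = c("madrs", "madrs", "ymrs"),
             spearman_target = c(0.4, 0.25, -0.3))
}

# write a complete synthetic manifest (audio + transcripts + story +
# embeddings) into dir; returns the manifest path
write_synthetic_manifest <- function(dir, n = 6, seed = 123) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  story_words <- c("la", "macchina", "correva", "veloce", "sulla", "strada",
                   "e", "poi", "si", "ferma")
  writeLines(paste(story_words, collapse = " "), file.path(dir, "story.txt"))
  emb_words <- unique(c(story_words, "casa", "sole"))
  set.seed(seed)
  emb <- cbind(emb_words,
               matrix(sprintf("%.6f", stats::rnorm(length(emb_words) * 4)),
                      length(emb_words), 4))
  writeLines(apply(emb, 1, paste, collapse = " "), file.path(dir, "embeddings.txt"))
  rows <- lapply(seq_len(n), function(i) {
    f0 <- 100 + 15 * i
    nw <- 3 + (i %% 2)
    onsets <- 0.2 + 0.4 * (seq_len(nw) - 1)
    wp <- data.frame(token = rep(story_words, length.out = nw),
                     onset_s = onsets, offset_s = onsets + 0.25)
    sess <- synthesize_session(session_spec(
      data.frame(kind = c("speech", "silence", "speech"),
                 duration_s = c(2.0, 0.4 + 0.1 * i, 1.5)),
      wp, pulse_train_spec(f0, 1, jitter_rel = 0.005 * i,
                           shimmer_rel = 0.004 * i, snr_db = 25),
      seed = seed + i))
    wav <- sprintf("p%02d.wav", i)
    trj <- sprintf("p%02d.json", i)
    write_wav(sess$audio, file.path(dir, wav))
    write_transcript_json(sess$transcript, file.path(dir, trj))
    data.frame(id = sprintf("P%02d", i), wav = wav, transcript = trj,
               sex = c("female", "male")[1 + i %% 2],
               madrs_total = c(4, 13, 19, 25, 8, 31)[1 + (i - 1) %% 6],
               ymrs_total = c(2, 20, 5, 11, 26, 0)[1 + (i - 1) %% 6])
  })
  manifest_path <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest_path, row.names = FALSE)
  manifest_path
}
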