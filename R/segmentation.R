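#' Segment a recording into sounding and silent intervals
#'
#' Frame-wise RMS intensity is computed on sliding windows; a frame is
#' silent if its intensity falls below a threshold relative to the peak
#' intensity (the 99.5th percentile of frame intensities, robust to clicks)
#' or below an absolute floor (so that an all-silence recording is labelled
#' silent). Silent runs shorter than `min_silent_s` are merged into their
#' sounding neighbours, then sounding runs shorter than `min_sounding_s`
#' into theirs. Intervals are half-open `[start, end)` seconds from the
#' recording start and tile its duration exactly.
#'
#' A silent interval is mapped to time as
#' `[window_start(first silent frame), window_start(last silent frame) + window]`:
#' with a deep relative threshold an energy window only reads silent when it
#' lies (almost) fully inside the pause, so each detected edge is within one
#' hop of the true edge.
#'
#' @param audio An [audio_recording()].
#' @param silence_threshold_db Threshold below peak intensity (dB, positive).
#' @param min_silent_s Minimum silent-run duration (s); shorter runs merge.
#' @param min_sounding_s Minimum sounding-run duration (s); shorter runs merge.
#' @param window_s Intensity analysis window (s).
#' @param hop_s Hop between successive windows (s).
#' @param floor_db Absolute silence floor in dBFS (full scale = 1); frames
#'   below it are silent regardless of the relative threshold.
#' @return A `voicing_segmentation`: list with `intervals` (data frame of
#'   `start_s`, `end_s`, `label` in `sounding`/`silent`) and
#'   `total_duration_s`.
#' @export
segment_voicing <- function(audio, silence_threshold_db = 25,
                            min_silent_s = 0.10, min_sounding_s = 0.10,
                            window_s = 0.050, hop_s = 0.010,
                            floor_db = -60) {
  stopifnot(inherits(audio, "audio_recording"),
            silence_threshold_db > 0, min_silent_s > 0, min_sounding_s > 0,
            window_s > 0, hop_s > 0)
  x <- audio$samples
  sr <- audio$sample_rate_hz
  dur <- length(x) / sr
  win <- max(1L, round(window_s * sr))
  hop <- max(1L, round(hop_s * sr))

  if (length(x) < win) {
    db <- 20 * log10(sqrt(mean(x^2)) + 1e-12)
    lab <- if (db < floor_db) "silent" else "sounding"
    return(new_voicing_segmentation(
      data.frame(start_s = 0, end_s = dur, label = lab), dur))
  }

  starts <- seq(1L, length(x) - win + 1L, by = hop)
  csum <- c(0, cumsum(x^2))
  rms <- sqrt((csum[starts + win] - csum[starts]) / win)
  db <- 20 * log10(rms + 1e-12)
  peak <- stats::quantile(db, 0.995, names = FALSE)
  silent <- (db < peak - silence_threshold_db) | (db < floor_db)

  silent <- merge_short_runs(silent, TRUE, min_silent_s, hop_s)
  silent <- merge_short_runs(silent, FALSE, min_sounding_s, hop_s)

  # frame i covers window [(starts[i]-1)/sr, (starts[i]-1)/sr + window_s)
  r <- rle(silent)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  bounds <- numeric(0)
  labels <- character(0)
  t_of <- function(i) (starts[i] - 1L) / sr
  cur <- 0
  for (k in seq_along(r$values)) {
    if (r$values[k]) {              # silent run
      s0 <- if (idx_start[k] == 1L) 0 else t_of(idx_start[k])
      s1 <- if (idx_end[k] == length(silent)) dur else
        min(dur, t_of(idx_end[k]) + win / sr)
      s0 <- max(s0, cur)
      if (s1 > s0) {
        if (s0 > cur) { bounds <- c(bounds, s0); labels <- c(labels, "sounding") }
        bounds <- c(bounds, s1); labels <- c(labels, "silent")
        cur <- s1
      }
    }
  }
  if (cur < dur || length(bounds) == 0) {
    bounds <- c(bounds, dur); labels <- c(labels, "sounding")
  }
  iv <- data.frame(start_s = c(0, bounds[-length(bounds)]), end_s = bounds,
                   label = labels)
  iv <- iv[iv$end_s > iv$start_s, , drop = FALSE]
  rownames(iv) <- NULL
  new_voicing_segmentation(iv, dur)
}

# flip runs of `value` shorter than min_dur_s (measured as run_length * hop)
merge_short_runs <- function(flags, value, min_dur_s, hop_s) {
  r <- rle(flags)
  short <- r$values == value & (r$lengths * hop_s) < min_dur_s
  # never flip a run that is the entire signal
  if (length(r$lengths) > 1) r$values[short] <- !value
  inverse.rle(r)
}

new_voicing_segmentation <- function(intervals, total_duration_s) {
  # coalesce accidental same-label neighbours so labels strictly alternate
  if (nrow(intervals) > 1) {
    keep <- c(TRUE, intervals$label[-1] != intervals$label[-nrow(intervals)])
    grp <- cumsum(keep)
    intervals <- data.frame(
      start_s = tapply(intervals$start_s, grp, min),
      end_s = tapply(intervals$end_s, grp, max),
      label = intervals$label[keep])
    rownames(intervals) <- NULL
  }
  structure(list(intervals = intervals, total_duration_s = total_duration_s),
            class = "voicing_segmentation")
}

#' @export
print.voicing_segmentation <- function(x, ...) {
  cat(sprintf("<voicing_segmentation: %.3f s, %d intervals, phonation %.3f s>\n",
              x$total_duration_s, nrow(x$intervals),
              sum(with(x$intervals, end_s - start_s)[x$intervals$label == "sounding"])))
  invisible(x)
}

#' Conversational timing features from a segmentation
#'
#' Computes speech duration, phonation (sounding) time, silence time, the
#' phonation/duration and silence/phonation ratios, and the speech rate in
#' words per second of speech duration. When phonation is zero the
#' silence/phonation ratio is reported as `NA`, never infinity.
#'
#' @param seg A `voicing_segmentation` from [segment_voicing()].
#' @param n_words Word count of the associated transcript (`>= 0`).
#' @return A one-row tibble: `speech_duration_s`, `phonation_s`,
#'   `silence_s`, `phonation_over_duration`, `silence_over_phonation`,
#'   `speech_rate_wps`.
#' @export
conversational_features <- function(seg, n_words) {
  stopifnot(inherits(seg, "voicing_segmentation"), n_words >= 0)
  len <- seg$intervals$end_s - seg$intervals$start_s
  phon <- sum(len[seg$intervals$label == "sounding"])
  sil <- sum(len[seg$intervals$label == "silent"])
  dur <- seg$total_duration_s
  tibble::tibble(
    speech_duration_s = dur,
    phonation_s = phon,
    silence_s = sil,
    phonation_over_duration = if (dur > 0) phon / dur else NA_real_,
    silence_over_phonation = if (phon > 0) sil / phon else NA_real_,
    speech_rate_wps = if (dur > 0) n_words / dur else NA_real_)
}

#' Write a segmentation to a tab-separated interval file
#' @param seg A `voicing_segmentation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segmentation_tsv <- function(seg, path) {
  utils::write.table(seg$intervals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
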