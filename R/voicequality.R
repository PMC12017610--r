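#' Track fundamental frequency with short-time normalized autocorrelation
#'
#' Per analysis frame, the normalized autocorrelation (NCCF) is evaluated
#' over candidate lags between `1/ceiling_hz` and `1/floor_hz`; local maxima
#' are refined by parabolic interpolation, and a best path through the
#' candidates is selected by dynamic programming with an octave-jump
#' transition cost. Frames whose best voiced candidate falls below the
#' voicing-strength threshold are marked unvoiced (`f0 = 0`).
#'
#' @param audio An [audio_recording()].
#' @param floor_hz,ceiling_hz Pitch search bounds (Hz),
#'   `0 < floor < ceiling < sample_rate/2`.
#' @param hop_s Frame hop (s).
#' @param window_s Analysis window (s); default `3 / floor_hz`.
#' @param voicing_threshold Minimum NCCF strength for a frame to be voiced.
#' @param octave_cost Per-octave bias favouring higher-frequency candidates
#'   (a perfectly periodic signal also correlates at period multiples;
#'   this resolves the subharmonic ties toward the true F0).
#' @param octave_jump_cost Transition cost per octave between consecutive
#'   voiced frames in the path search.
#' @param voiced_unvoiced_cost Transition cost for switching between voiced
#'   and unvoiced states.
#' @return A `pitch_track`: tibble with `frame_time_s` (window centres,
#'   strictly increasing), `f0_hz` (0 when unvoiced), `voiced` (logical)
#'   and `strength` (NCCF of the chosen candidate). Attributes carry the
#'   tracker settings.
#' @export
track_pitch <- function(audio, floor_hz = 75, ceiling_hz = 500,
                        hop_s = 0.010, window_s = NULL,
                        voicing_threshold = 0.45,
                        octave_cost = 0.01,
                        octave_jump_cost = 0.35,
                        voiced_unvoiced_cost = 0.14) {
  stopifnot(inherits(audio, "audio_recording"),
            floor_hz > 0, ceiling_hz > floor_hz,
            ceiling_hz < audio$sample_rate_hz / 2)
  if (is.null(window_s)) window_s <- 3 / floor_hz
  sr <- audio$sample_rate_hz
  x <- audio$samples
  w <- round(window_s * sr)
  hop <- max(1L, round(hop_s * sr))
  lag_min <- max(2L, floor(sr / ceiling_hz))
  lag_max <- min(w - 2L, ceiling(sr / floor_hz))
  if (length(x) < w || lag_max <= lag_min + 2L) {
    return(new_pitch_track(tibble::tibble(frame_time_s = numeric(0),
                                          f0_hz = numeric(0),
                                          voiced = logical(0),
                                          strength = numeric(0)),
                           floor_hz, ceiling_hz))
  }
  starts <- seq(1L, length(x) - w + 1L, by = hop)
  nfft <- stats::nextn(2L * w, c(2, 3, 5))
  n_cand <- 4L

  cand_f <- vector("list", length(starts))
  cand_r <- vector("list", length(starts))
  for (fi in seq_along(starts)) {
    fr <- x[starts[fi]:(starts[fi] + w - 1L)]
    fr <- fr - mean(fr)
    e_total <- sum(fr^2)
    if (e_total < 1e-14) { cand_f[[fi]] <- numeric(0); cand_r[[fi]] <- numeric(0); next }
    sp <- stats::fft(c(fr, numeric(nfft - w)))
    ac <- Re(stats::fft(sp * Conj(sp), inverse = TRUE)) / nfft
    cs <- c(0, cumsum(fr^2))
    lags <- lag_min:lag_max
    e0 <- cs[w - lags + 1L]          # energy of x[1..w-lag]
    e1 <- cs[w + 1L] - cs[lags + 1L] # energy of x[lag+1..w]
    ncc <- ac[lags + 1L] / sqrt(pmax(e0 * e1, 1e-30))
    # local maxima with parabolic refinement
    m <- length(ncc)
    is_pk <- c(FALSE, ncc[2:(m - 1)] >= ncc[1:(m - 2)] &
                 ncc[2:(m - 1)] > ncc[3:m], FALSE)
    pk <- which(is_pk & ncc > 0.15)
    if (length(pk)) {
      ord <- order(ncc[pk], decreasing = TRUE)
      pk <- pk[ord[seq_len(min(n_cand, length(pk)))]]
      y0 <- ncc[pk - 1L]; y1 <- ncc[pk]; y2 <- ncc[pk + 1L]
      denom <- (y0 - 2 * y1 + y2)
      delta <- ifelse(abs(denom) > 1e-12, 0.5 * (y0 - y2) / denom, 0)
      delta <- pmin(pmax(delta, -0.5), 0.5)
      lag_ref <- lags[pk] + delta
      r_ref <- pmin(y1 - 0.25 * (y0 - y2) * delta, 1)
      f <- sr / lag_ref
      keep <- f >= floor_hz * 0.99 & f <= ceiling_hz * 1.01
      cand_f[[fi]] <- pmin(pmax(f[keep], floor_hz), ceiling_hz)
      cand_r[[fi]] <- r_ref[keep]
    } else {
      cand_f[[fi]] <- numeric(0)
      cand_r[[fi]] <- numeric(0)
    }
  }

  path <- viterbi_pitch_path(cand_f, cand_r, voicing_threshold,
                             octave_cost, ceiling_hz,
                             octave_jump_cost, voiced_unvoiced_cost)
  tt <- (starts - 1L) / sr + w / (2 * sr)
  new_pitch_track(tibble::tibble(frame_time_s = tt, f0_hz = path$f0,
                                 voiced = path$voiced, strength = path$r),
                  floor_hz, ceiling_hz)
}

new_pitch_track <- function(frames, floor_hz, ceiling_hz) {
  attr(frames, "floor_hz") <- floor_hz
  attr(frames, "ceiling_hz") <- ceiling_hz
  class(frames) <- c("pitch_track", class(frames))
  frames
}

# dynamic programme over per-frame candidate sets plus an unvoiced state
viterbi_pitch_path <- function(cand_f, cand_r, voicing_threshold,
                               octave_cost, ceiling_hz,
                               octave_jump_cost, voiced_unvoiced_cost) {
  n <- length(cand_f)
  f0 <- numeric(n); voiced <- logical(n); rr <- numeric(n)
  if (n == 0) return(list(f0 = f0, voiced = voiced, r = rr))
  # state 1 = unvoiced; states 2.. = voiced candidates
  score_prev <- NULL; states_prev <- NULL
  back <- vector("list", n)
  for (i in seq_len(n)) {
    fs <- c(0, cand_f[[i]])
    rs <- c(voicing_threshold, cand_r[[i]])
    # unvoiced candidate scores the threshold; voiced ones are biased
    # against subharmonics by the octave cost
    local <- c(rs[1], rs[-1] - octave_cost * log2(ceiling_hz / fs[-1]))
    if (is.null(score_prev)) {
      sc <- local
      bk <- rep(0L, length(fs))
    } else {
      sc <- numeric(length(fs)); bk <- integer(length(fs))
      for (j in seq_along(fs)) {
        trans <- vapply(seq_along(states_prev$f), function(k) {
          fprev <- states_prev$f[k]
          if (fprev == 0 && fs[j] == 0) 0
          else if (fprev == 0 || fs[j] == 0) voiced_unvoiced_cost
          else octave_jump_cost * abs(log2(fs[j] / fprev))
        }, numeric(1))
        tot <- score_prev - trans
        bk[j] <- which.max(tot)
        sc[j] <- tot[bk[j]] + local[j]
      }
    }
    back[[i]] <- bk
    score_prev <- sc
    states_prev <- list(f = fs, r = rs)
    attr(back[[i]], "f") <- fs
    attr(back[[i]], "r") <- rs
  }
  j <- which.max(score_prev)
  for (i in rev(seq_len(n))) {
    fs <- attr(back[[i]], "f"); rs <- attr(back[[i]], "r")
    f0[i] <- fs[j]; rr[i] <- rs[j]; voiced[i] <- fs[j] > 0
    j <- back[[i]][j]
    if (i > 1 && j == 0) j <- 1L
  }
  list(f0 = f0, voiced = voiced, r = rr)
}

#' Extract glottal cycle epochs and per-cycle peak amplitudes
#'
#' Within each voiced run of the pitch track, cycle epochs are located by
#' peak-picking the waveform guided by the local period estimate: starting
#' from the strongest positive peak near the run onset, each next epoch is
#' the (parabolically interpolated) waveform maximum within 0.7-1.35 local
#' periods of the previous one. Cycles whose implied period falls outside
#' `[1/ceiling, 1/floor]` are dropped, counted, and break the run (periods
#' are never bridged across breaks or pauses).
#'
#' @param audio The [audio_recording()] the track was computed from.
#' @param track A `pitch_track` from [track_pitch()].
#' @return A `period_sequence`: tibble with `epoch_s`, `amplitude`
#'   (interpolated positive peak height) and `run` (integer id; period
#'   differences are only meaningful within a run). Attributes:
#'   `n_dropped_cycles`, `insufficient` (fewer than 3 periods overall).
#' @export
extract_periods <- function(audio, track) {
  stopifnot(inherits(audio, "audio_recording"), inherits(track, "pitch_track"))
  x <- audio$samples
  sr <- audio$sample_rate_hz
  floor_hz <- attr(track, "floor_hz")
  ceiling_hz <- attr(track, "ceiling_hz")
  t_min <- 1 / ceiling_hz
  t_max <- 1 / floor_hz

  epochs <- numeric(0); amps <- numeric(0); runs <- integer(0)
  n_drop <- 0L
  run_id <- 0L

  vr <- rle(track$voiced)
  ends <- cumsum(vr$lengths); starts_i <- ends - vr$lengths + 1L
  for (k in seq_along(vr$values)) {
    if (!vr$values[k]) next
    fidx <- starts_i[k]:ends[k]
    ft <- track$frame_time_s[fidx]
    ff <- track$f0_hz[fidx]
    f0_at <- function(t) {
      if (length(ft) == 1) ff else
        stats::approx(ft, ff, xout = t, rule = 2)$y
    }
    run_id <- run_id + 1L
    t_run0 <- max(ft[1] - 1.5 / f0_at(ft[1]), 0)
    t_run1 <- min(ft[length(ft)] + 1.5 / ff[length(ff)],
                  (length(x) - 2) / sr)
    # seed epoch: strongest positive peak in the first 2 periods of the run
    sw0 <- max(2L, floor(t_run0 * sr) + 1L)
    sw1 <- min(length(x) - 1L, ceiling((t_run0 + 2 / f0_at(t_run0)) * sr))
    if (sw1 - sw0 < 3) next
    seg <- x[sw0:sw1]
    pk <- which.max(seg)
    e <- refine_peak(x, sw0 + pk - 1L)
    if (is.null(e)) next
    epochs <- c(epochs, e$t / sr); amps <- c(amps, e$a); runs <- c(runs, run_id)
    repeat {
      t_prev <- epochs[length(epochs)]
      t_loc <- 1 / f0_at(t_prev)
      lo <- floor((t_prev + 0.70 * t_loc) * sr) + 1L
      hi <- ceiling((t_prev + 1.35 * t_loc) * sr) + 1L
      if (hi > min(length(x) - 1L, floor(t_run1 * sr))) break
      seg <- x[lo:hi]
      pk <- which.max(seg)
      e <- refine_peak(x, lo + pk - 1L)
      if (is.null(e)) break
      t_new <- e$t / sr
      period <- t_new - t_prev
      if (period < t_min || period > t_max) {
        n_drop <- n_drop + 1L
        run_id <- run_id + 1L        # break the run, restart from this peak
      }
      epochs <- c(epochs, t_new); amps <- c(amps, e$a); runs <- c(runs, run_id)
    }
  }
  out <- tibble::tibble(epoch_s = epochs, amplitude = amps, run = runs)
  attr(out, "n_dropped_cycles") <- n_drop
  attr(out, "insufficient") <- length(epochs) < 4
  class(out) <- c("period_sequence", class(out))
  out
}

#' Construct a period sequence directly
#'
#' Builds the container returned by [extract_periods()] from explicit cycle
#' epochs and amplitudes, e.g. for perturbation measures on externally
#' detected cycles.
#'
#' @param epoch_s Cycle onset times (s), strictly increasing within runs.
#' @param amplitude Per-cycle peak amplitudes (`>= 0`).
#' @param run Integer run ids (periods are never computed across runs);
#'   default: a single run.
#' @return A `period_sequence`.
#' @export
period_sequence <- function(epoch_s, amplitude, run = rep(1L, length(epoch_s))) {
  stopifnot(length(epoch_s) == length(amplitude),
            length(run) == length(epoch_s), all(amplitude >= 0))
  out <- tibble::tibble(epoch_s = epoch_s, amplitude = amplitude,
                        run = as.integer(run))
  attr(out, "n_dropped_cycles") <- 0L
  attr(out, "insufficient") <- length(epoch_s) < 4
  class(out) <- c("period_sequence", class(out))
  out
}

# parabolic sub-sample refinement of a local maximum at sample index i (1-based)
# returns list(t = 0-based fractional sample position, a = vertex height)
refine_peak <- function(x, i) {
  if (i < 2 || i > length(x) - 1) return(NULL)
  y0 <- x[i - 1]; y1 <- x[i]; y2 <- x[i + 1]
  denom <- y0 - 2 * y1 + y2
  delta <- if (abs(denom) > 1e-15) 0.5 * (y0 - y2) / denom else 0
  delta <- min(max(delta, -0.5), 0.5)
  list(t = (i - 1) + delta, a = max(y1 - 0.25 * (y0 - y2) * delta, 0))
}

# periods grouped by voiced run: list of numeric vectors (>= 2 epochs each)
periods_by_run <- function(p) {
  sp <- split(p$epoch_s, p$run)
  lapply(Filter(function(v) length(v) >= 2, sp), diff)
}

amplitudes_by_run <- function(p) {
  Filter(function(v) length(v) >= 1, split(p$amplitude, p$run))
}

# mean |v_i - mean(v in centred window of size k)| pooled across runs
apq_pooled <- function(runs, k) {
  half <- (k - 1L) %/% 2L
  devs <- unlist(lapply(runs, function(v) {
    n <- length(v)
    if (n < k) return(numeric(0))
    vapply((1L + half):(n - half), function(i)
      abs(v[i] - mean(v[(i - half):(i + half)])), numeric(1))
  }))
  if (length(devs) == 0) return(NA_real_)
  mean(devs)
}

#' Jitter (period-perturbation) measures
#'
#' Praat-compatible jitter family computed from a [extract_periods()]
#' sequence, within voiced runs only (never bridging pauses or run breaks):
#' `local` = mean absolute consecutive period difference over the mean
#' period; `local_abs` = the same difference in seconds; `rap` and `ppq5` =
#' mean absolute deviation of each period from the running 3- and 5-point
#' average, over the mean period; `ddp = 3 * rap`.
#'
#' @param p A `period_sequence`.
#' @return One-row tibble: `jitter_local`, `jitter_local_abs_s`,
#'   `jitter_rap`, `jitter_ppq5`, `jitter_ddp`. Fields are `NA` when too few
#'   periods are available (fewer than 3 for local/rap, 5 for ppq5), with
#'   the reason in attribute `reason`.
#' @export
jitter_measures <- function(p) {
  runs <- periods_by_run(p)
  allT <- unlist(runs)
  out <- tibble::tibble(jitter_local = NA_real_, jitter_local_abs_s = NA_real_,
                        jitter_rap = NA_real_, jitter_ppq5 = NA_real_,
                        jitter_ddp = NA_real_)
  if (length(allT) < 3) {
    attr(out, "reason") <- "fewer than 3 periods"
    return(out)
  }
  mean_t <- mean(allT)
  d <- unlist(lapply(Filter(function(v) length(v) >= 2, runs),
                     function(v) abs(diff(v))))
  out$jitter_local_abs_s <- mean(d)
  out$jitter_local <- mean(d) / mean_t
  rap <- apq_pooled(runs, 3L) / mean_t
  out$jitter_rap <- rap
  out$jitter_ddp <- 3 * rap
  ppq5 <- apq_pooled(runs, 5L)
  out$jitter_ppq5 <- if (is.na(ppq5)) NA_real_ else ppq5 / mean_t
  out
}

#' Shimmer (amplitude-perturbation) measures
#'
#' Praat-compatible shimmer family from per-cycle peak amplitudes, within
#' voiced runs: `local` = mean absolute consecutive amplitude difference
#' over the mean amplitude; `local_db` = mean absolute
#' `20*log10(A_{i+1}/A_i)` (cycles with a zero amplitude are excluded from
#' the dB form and counted in attribute `n_zero_amplitude`); `apq3/5/11` =
#' mean absolute deviation from the running N-point average over the mean
#' amplitude; `dda = 3 * apq3`.
#'
#' @param p A `period_sequence`.
#' @return One-row tibble: `shimmer_local`, `shimmer_local_db`,
#'   `shimmer_apq3`, `shimmer_apq5`, `shimmer_apq11`, `shimmer_dda`.
#' @export
shimmer_measures <- function(p) {
  runs <- amplitudes_by_run(p)
  allA <- unlist(runs)
  out <- tibble::tibble(shimmer_local = NA_real_, shimmer_local_db = NA_real_,
                        shimmer_apq3 = NA_real_, shimmer_apq5 = NA_real_,
                        shimmer_apq11 = NA_real_, shimmer_dda = NA_real_)
  if (length(allA) < 3) {
    attr(out, "reason") <- "fewer than 3 cycles"
    return(out)
  }
  mean_a <- mean(allA)
  pair_runs <- Filter(function(v) length(v) >= 2, runs)
  d <- unlist(lapply(pair_runs, function(v) abs(diff(v))))
  out$shimmer_local <- mean(d) / mean_a
  n_zero <- 0L
  db <- unlist(lapply(pair_runs, function(v) {
    a0 <- v[-length(v)]; a1 <- v[-1]
    ok <- a0 > 0 & a1 > 0
    n_zero <<- n_zero + sum(!ok)
    abs(20 * log10(a1[ok] / a0[ok]))
  }))
  out$shimmer_local_db <- if (length(db)) mean(db) else NA_real_
  apq3 <- apq_pooled(runs, 3L) / mean_a
  out$shimmer_apq3 <- apq3
  out$shimmer_dda <- 3 * apq3
  a5 <- apq_pooled(runs, 5L)
  out$shimmer_apq5 <- if (is.na(a5)) NA_real_ else a5 / mean_a
  a11 <- apq_pooled(runs, 11L)
  out$shimmer_apq11 <- if (is.na(a11)) NA_real_ else a11 / mean_a
  attr(out, "n_zero_amplitude") <- n_zero
  out
}

#' Mean harmonics-to-noise ratio
#'
#' Per voiced frame, the normalized autocorrelation `r` at the frame's F0
#' lag (parabolically refined local maximum nearest that lag) is converted
#' to `10*log10(r / (1 - r))` dB, with `r` clipped to `[1e-6, 1 - 1e-6]`;
#' the result is the mean over voiced frames.
#'
#' @param audio The [audio_recording()].
#' @param track A `pitch_track` from [track_pitch()] on the same audio.
#' @return Mean HNR in dB, or `NA` if no voiced frame exists.
#' @export
harmonics_to_noise <- function(audio, track) {
  stopifnot(inherits(audio, "audio_recording"), inherits(track, "pitch_track"))
  voiced <- which(track$voiced)
  if (length(voiced) == 0) return(NA_real_)
  sr <- audio$sample_rate_hz
  x <- audio$samples
  floor_hz <- attr(track, "floor_hz")
  w <- round(3 / floor_hz * sr)
  eps <- 1e-6
  hnr <- vapply(voiced, function(fi) {
    tc <- track$frame_time_s[fi]
    a <- max(1L, round(tc * sr - w / 2))
    b <- min(length(x), a + w - 1L)
    fr <- x[a:b]; fr <- fr - mean(fr)
    wl <- length(fr)
    if (sum(fr^2) < 1e-14) return(NA_real_)
    nfft <- stats::nextn(2L * wl, c(2, 3, 5))
    sp <- stats::fft(c(fr, numeric(nfft - wl)))
    ac <- Re(stats::fft(sp * Conj(sp), inverse = TRUE)) / nfft
    cs <- c(0, cumsum(fr^2))
    lag0 <- round(sr / track$f0_hz[fi])
    lo <- max(2L, lag0 - 3L); hi <- min(wl - 2L, lag0 + 3L)
    if (hi <= lo) return(NA_real_)
    lags <- lo:hi
    e0 <- cs[wl - lags + 1L]
    e1 <- cs[wl + 1L] - cs[lags + 1L]
    ncc <- ac[lags + 1L] / sqrt(pmax(e0 * e1, 1e-30))
    j <- which.max(ncc)
    r <- if (j > 1 && j < length(ncc)) {
      y0 <- ncc[j - 1]; y1 <- ncc[j]; y2 <- ncc[j + 1]
      denom <- y0 - 2 * y1 + y2
      delta <- if (abs(denom) > 1e-15) min(max(0.5 * (y0 - y2) / denom, -0.5), 0.5) else 0
      y1 - 0.25 * (y0 - y2) * delta
    } else ncc[j]
    r <- min(max(r, eps), 1 - eps)
    10 * log10(r / (1 - r))
  }, numeric(1))
  mean(hnr, na.rm = TRUE)
}

#' F0 statistics over voiced frames
#'
#' Mean and population SD (divide by n) of the F0 values of voiced frames.
#'
#' @param track A `pitch_track`.
#' @return One-row tibble `f0_mean_hz`, `f0_sd_hz`; both `NA` when no frame
#'   is voiced.
#' @export
f0_statistics <- function(track) {
  f <- track$f0_hz[track$voiced]
  if (length(f) == 0)
    return(tibble::tibble(f0_mean_hz = NA_real_, f0_sd_hz = NA_real_))
  tibble::tibble(f0_mean_hz = mean(f),
                 f0_sd_hz = sqrt(mean((f - mean(f))^2)))
}

#' Full acoustic voice-quality panel for one recording
#'
#' Convenience wrapper: pitch track, period extraction, jitter and shimmer
#' families, mean HNR and F0 statistics in one row.
#'
#' @param audio An [audio_recording()].
#' @param floor_hz,ceiling_hz Pitch bounds passed to [track_pitch()].
#' @param ... Further arguments to [track_pitch()].
#' @return One-row tibble with all `AcousticFeatureSet` columns; attribute
#'   `qc` holds voicing fraction and dropped-cycle counts.
#' @export
acoustic_features <- function(audio, floor_hz = 75, ceiling_hz = 500, ...) {
  track <- track_pitch(audio, floor_hz = floor_hz, ceiling_hz = ceiling_hz, ...)
  p <- extract_periods(audio, track)
  out <- cbind(f0_statistics(track),
               jitter_measures(p),
               shimmer_measures(p),
               tibble::tibble(hnr_mean_db = harmonics_to_noise(audio, track)))
  out <- tibble::as_tibble(out)
  attr(out, "qc") <- list(
    voicing_fraction = if (nrow(track)) mean(track$voiced) else 0,
    n_dropped_cycles = attr(p, "n_dropped_cycles"),
    n_cycles = nrow(p))
  out
}
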