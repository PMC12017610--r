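#' Specification of a synthetic glottal pulse train
#'
#' Defines a voiced-speech surrogate: a train of excitation pulses at a
#' target fundamental frequency, with controlled cycle-to-cycle period
#' perturbation (jitter), pulse-amplitude perturbation (shimmer), and an
#' additive white-noise level. Every downstream voice-quality estimator can
#' be validated against the exact perturbations drawn here.
#'
#' @param f0_hz Target fundamental frequency (Hz), `> 0` and `< sample_rate_hz/4`.
#' @param duration_s Signal duration (seconds), `> 0`.
#' @param jitter_rel Relative SD of the multiplicative Gaussian period
#'   perturbation (dimensionless, `>= 0`).
#' @param shimmer_rel Relative SD of the multiplicative Gaussian pulse
#'   amplitude perturbation (dimensionless, `>= 0`).
#' @param snr_db Additive white-noise signal-to-noise ratio in dB;
#'   `Inf` means no noise.
#' @param sample_rate_hz Sampling rate (Hz), `>= 8000`.
#' @param seed Integer seed; all draws are reproducible from it.
#' @return A `pulse_train_spec` list.
#' @export
pulse_train_spec <- function(f0_hz, duration_s, jitter_rel = 0, shimmer_rel = 0,
                             snr_db = Inf, sample_rate_hz = 16000L, seed = 1L) {
  stopifnot(f0_hz > 0, duration_s > 0, jitter_rel >= 0, shimmer_rel >= 0,
            sample_rate_hz >= 8000, f0_hz < sample_rate_hz / 4,
            is.finite(seed))
  structure(list(f0_hz = f0_hz, duration_s = duration_s,
                 jitter_rel = jitter_rel, shimmer_rel = shimmer_rel,
                 snr_db = snr_db, sample_rate_hz = as.integer(sample_rate_hz),
                 seed = as.integer(seed)),
            class = "pulse_train_spec")
}

#' Synthesize a glottal pulse train with known ground truth
#'
#' Draws per-cycle periods `T_i = (1/f0) * (1 + jitter_rel * z_i)` and pulse
#' amplitudes `A_i = A0 * (1 + shimmer_rel * w_i)` with `z, w` iid standard
#' normal, then renders each pulse as an exponentially damped sinusoid
#' (carrier at `2 * f0`, decay time constant `1/(5 f0)`) starting at its
#' epoch, and finally adds white Gaussian noise scaled so the expected SNR
#' equals `snr_db`. A period draw that would be non-positive is rejected and
#' redrawn; the count of redraws is reported.
#'
#' @param spec A [pulse_train_spec()].
#' @return A list with elements:
#'   \describe{
#'     \item{audio}{an [audio_recording()] (signal plus noise)}
#'     \item{ground_truth}{list with `epochs_s` (pulse onset times),
#'       `periods_s` (the drawn periods, `epochs_s` differences),
#'       `amplitudes` (the drawn `A_i`), `signal` and `noise` (the two
#'       additive waveform components), and `n_period_redraws`.}
#'   }
#' @export
synthesize_pulse_train <- function(spec) {
  stopifnot(inherits(spec, "pulse_train_spec"))
  sr <- spec$sample_rate_hz
  t0 <- 1 / spec$f0_hz
  set.seed(spec$seed)

  epochs <- numeric(0)
  periods <- numeric(0)
  e <- 0
  n_redraw <- 0L
  while (e < spec$duration_s) {
    epochs <- c(epochs, e)
    repeat {
      ti <- t0 * (1 + spec$jitter_rel * stats::rnorm(1))
      if (ti > 0) break
      n_redraw <- n_redraw + 1L
    }
    periods <- c(periods, ti)
    e <- e + ti
  }
  n_pulse <- length(epochs)
  a0 <- 0.4
  amplitudes <- a0 * (1 + spec$shimmer_rel * stats::rnorm(n_pulse))

  n <- round(spec$duration_s * sr)
  signal <- numeric(n)
  fc <- 2 * spec$f0_hz
  tau <- 1 / (5 * spec$f0_hz)
  kern_len_s <- 9.5 * tau                  # decayed below 1e-4 of peak
  for (i in seq_len(n_pulse)) {
    i0 <- ceiling(epochs[i] * sr) + 1L     # first sample at/after epoch
    i1 <- min(n, floor((epochs[i] + kern_len_s) * sr) + 1L)
    if (i0 > n) next
    trel <- ((i0:i1) - 1) / sr - epochs[i]
    signal[i0:i1] <- signal[i0:i1] +
      amplitudes[i] * exp(-trel / tau) * sin(2 * pi * fc * trel)
  }

  if (is.finite(spec$snr_db)) {
    p_sig <- mean(signal^2)
    noise <- stats::rnorm(n, sd = sqrt(p_sig * 10^(-spec$snr_db / 10)))
  } else {
    noise <- numeric(n)
  }
  # drop the trailing period draw that overran the duration
  periods <- periods[seq_len(max(0L, n_pulse - 1L))]
  list(audio = audio_recording(signal + noise, sr),
       ground_truth = list(epochs_s = epochs,
                           periods_s = periods,
                           amplitudes = amplitudes,
                           signal = signal, noise = noise,
                           n_period_redraws = n_redraw))
}

#' Specification of a synthetic recording session
#'
#' An ordered plan of speech and silence segments with a word plan whose
#' intervals must fall inside speech segments; the speech portions are
#' rendered from a [pulse_train_spec()].
#'
#' @param segments Data frame with columns `kind` (`"speech"`/`"silence"`)
#'   and `duration_s` (`> 0`).
#' @param word_plan Data frame with columns `token`, `onset_s`, `offset_s`
#'   (may have zero rows). Intervals must be non-overlapping, strictly
#'   increasing, and contained in speech segments.
#' @param voice A [pulse_train_spec()] used for the speech portions.
#' @param seed Integer seed.
#' @return A `session_spec` list.
#' @export
session_spec <- function(segments, word_plan, voice, seed = 1L) {
  segments <- as.data.frame(segments)
  word_plan <- as.data.frame(word_plan)
  stopifnot(all(c("kind", "duration_s") %in% names(segments)),
            nrow(segments) >= 1,
            all(segments$kind %in% c("speech", "silence")),
            all(segments$duration_s > 0),
            inherits(voice, "pulse_train_spec"))
  if (nrow(word_plan) > 0) {
    stopifnot(all(c("token", "onset_s", "offset_s") %in% names(word_plan)))
    if (any(word_plan$offset_s <= word_plan$onset_s))
      stop("word intervals must have onset < offset")
    if (nrow(word_plan) > 1) {
      prev_off <- word_plan$offset_s[-nrow(word_plan)]
      next_on <- word_plan$onset_s[-1]
      if (any(next_on < prev_off))
        stop("word intervals must be non-overlapping and increasing")
    }
    seg_end <- cumsum(segments$duration_s)
    seg_start <- seg_end - segments$duration_s
    speech <- segments$kind == "speech"
    for (k in seq_len(nrow(word_plan))) {
      inside <- any(speech &
                      word_plan$onset_s[k] >= seg_start - 1e-9 &
                      word_plan$offset_s[k] <= seg_end + 1e-9)
      if (!inside)
        stop(sprintf("word '%s' [%.3f, %.3f] s lies outside every speech segment",
                     word_plan$token[k], word_plan$onset_s[k], word_plan$offset_s[k]))
    }
  }
  structure(list(segments = segments, word_plan = word_plan,
                 voice = voice, seed = as.integer(seed)),
            class = "session_spec")
}

#' Synthesize a session recording with planned pause structure
#'
#' Renders each speech segment as a pulse train (from the session's voice
#' spec, reseeded per segment) and each silence segment as a near-zero noise
#' floor at least 40 dB below the speech RMS. Returns the audio, the planned
#' transcript verbatim, and the exact segment boundaries.
#'
#' @param spec A [session_spec()].
#' @return List with `audio` ([audio_recording()]), `transcript` (a
#'   [timed_transcript()]), and `ground_truth` (data frame of segment
#'   `start_s`, `end_s`, `kind`).
#' @export
synthesize_session <- function(spec) {
  stopifnot(inherits(spec, "session_spec"))
  sr <- spec$voice$sample_rate_hz
  segs <- spec$segments
  pieces <- vector("list", nrow(segs))
  for (i in seq_len(nrow(segs))) {
    if (segs$kind[i] == "speech") {
      vs <- spec$voice
      vs$duration_s <- segs$duration_s[i]
      vs$seed <- spec$seed + i
      pieces[[i]] <- synthesize_pulse_train(vs)$audio$samples
    } else {
      pieces[[i]] <- NULL  # fill after speech RMS is known
    }
  }
  speech_rms <- {
    sp <- unlist(pieces[segs$kind == "speech"])
    if (length(sp)) sqrt(mean(sp^2)) else 0.1
  }
  set.seed(spec$seed + 100003L)
  for (i in seq_len(nrow(segs))) {
    if (segs$kind[i] == "silence") {
      nsil <- round(segs$duration_s[i] * sr)
      pieces[[i]] <- stats::rnorm(nsil, sd = speech_rms * 1e-3)  # -60 dB floor
    }
  }
  samples <- unlist(pieces)
  ends <- cumsum(segs$duration_s)
  gt <- data.frame(start_s = ends - segs$duration_s, end_s = ends,
                   kind = segs$kind)
  transcript <- timed_transcript(spec$word_plan, task_start_s = 0)
  list(audio = audio_recording(samples, sr), transcript = transcript,
       ground_truth = gt)
}

#' Specification of a synthetic participant cohort
#'
#' Describes a cohort whose features carry configured monotone associations
#' with the MADRS or YMRS total, via a Gaussian-copula construction, with
#' optional sex-dependent effect modification.
#'
#' @param n Number of participants (`>= 4`).
#' @param effect_map Data frame with columns `feature` (name), `target`
#'   (`"madrs"` or `"ymrs"`) and `spearman_target` (intended population
#'   Spearman rank correlation, `|rho| < 1`).
#' @param sex_modifier Optional named numeric vector; for each named
#'   feature, the latent correlation is multiplied by this factor in
#'   females (males keep the unmodified effect).
#' @param noise_sd Residual Gaussian SD added on the feature scale after the
#'   copula construction (default 0, so sample correlations converge to
#'   their targets).
#' @param score_distribution List with `madrs` and `ymrs` sublists giving
#'   `mu` and `size` of the negative-binomial marginal used for the totals
#'   (right-skewed, then clamped to 0-60). Defaults approximate a mood-
#'   disorder cohort with moderate depressive and low manic symptom load.
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n, effect_map, sex_modifier = NULL, noise_sd = 0,
                        score_distribution = NULL, seed = 1L) {
  effect_map <- as.data.frame(effect_map)
  stopifnot(n >= 4,
            all(c("feature", "target", "spearman_target") %in% names(effect_map)),
            all(effect_map$target %in% c("madrs", "ymrs")),
            all(abs(effect_map$spearman_target) < 1),
            !anyDuplicated(effect_map$feature),
            noise_sd >= 0)
  if (is.null(score_distribution))
    score_distribution <- list(madrs = list(mu = 18, size = 1.1),
                               ymrs = list(mu = 12, size = 0.5))
  structure(list(n = as.integer(n), effect_map = effect_map,
                 sex_modifier = sex_modifier, noise_sd = noise_sd,
                 score_distribution = score_distribution,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Spearman -> Pearson correlation of the underlying bivariate normal copula
spearman_to_latent <- function(rho_s) 2 * sin(pi * rho_s / 6)

#' Generate a synthetic participant cohort
#'
#' Per target, a latent standard normal drives the (discrete, skewed) symptom
#' total through its negative-binomial quantile function; each configured
#' feature is a unit-variance normal correlated with that latent at the level
#' that yields the requested population Spearman correlation
#' (`r = 2 sin(pi rho_s / 6)`). Sex is assigned 50/50 and, for features named
#' in `sex_modifier`, the latent correlation is multiplied by the modifier in
#' females.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with columns `id`, `sex`, `madrs_total`, `ymrs_total`
#'   and one column per configured feature.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  em <- spec$effect_map
  r_base <- spearman_to_latent(em$spearman_target)
  r_female <- r_base
  if (!is.null(spec$sex_modifier)) {
    idx <- match(names(spec$sex_modifier), em$feature)
    if (anyNA(idx)) stop("sex_modifier names not in effect_map: ",
                         paste(names(spec$sex_modifier)[is.na(idx)], collapse = ", "))
    r_female[idx] <- r_base[idx] * spec$sex_modifier
  }
  bad <- abs(r_base) >= 1 | abs(r_female) >= 1
  if (any(bad))
    stop("infeasible latent correlation (|r| >= 1) for feature(s): ",
         paste(em$feature[bad], collapse = ", "))

  set.seed(spec$seed)
  n <- spec$n
  sex <- sample(rep(c("female", "male"), length.out = n))
  z_madrs <- stats::rnorm(n)
  z_ymrs <- stats::rnorm(n)
  sd_par <- spec$score_distribution
  madrs <- pmin(60L, stats::qnbinom(stats::pnorm(z_madrs),
                                    mu = sd_par$madrs$mu, size = sd_par$madrs$size))
  ymrs <- pmin(60L, stats::qnbinom(stats::pnorm(z_ymrs),
                                   mu = sd_par$ymrs$mu, size = sd_par$ymrs$size))

  out <- tibble::tibble(id = sprintf("P%04d", seq_len(n)), sex = sex,
                        madrs_total = as.integer(madrs),
                        ymrs_total = as.integer(ymrs))
  is_f <- sex == "female"
  for (k in seq_len(nrow(em))) {
    z_t <- if (em$target[k] == "madrs") z_madrs else z_ymrs
    r <- ifelse(is_f, r_female[k], r_base[k])
    eps <- stats::rnorm(n)
    val <- r * z_t + sqrt(1 - r^2) * eps
    if (spec$noise_sd > 0) val <- val + stats::rnorm(n, sd = spec$noise_sd)
    out[[em$feature[k]]] <- val
  }
  out
}

#' Write a cohort table to CSV
#' @param cohort Tibble from [generate_cohort()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
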