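#' Read a participant manifest
#'
#' CSV with columns `id`, `wav`, `transcript`, `sex`, `madrs_total`,
#' `ymrs_total`, plus optional per-item score columns. Paths are resolved
#' relative to the manifest's directory unless absolute.
#'
#' @param path Manifest CSV path.
#' @return Tibble with attribute `base_dir`.
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "wav", "transcript", "sex", "madrs_total", "ymrs_total")
  missing_cols <- setdiff(need, names(m))
  if (length(missing_cols))
    stop("manifest lacks column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(m) == 0) stop("empty manifest: ", path)
  if (anyDuplicated(m$id))
    stop("duplicate participant ids in manifest")
  out <- tibble::as_tibble(m)
  attr(out, "base_dir") <- dirname(normalizePath(path))
  out
}

resolve_path <- function(p, base_dir) {
  ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base_dir, p))
}

#' Validate manifest rows
#'
#' Report-only checks per participant: files readable, scores within 0-60,
#' sex level recognised, transcript schema valid (sorted, non-overlapping
#' word intervals), audio readable and not clipped (less than 1% of
#' samples at full scale).
#'
#' @param manifest Tibble from [read_manifest()] (or a data frame plus
#'   `base_dir`).
#' @param base_dir Directory for relative paths (default: the manifest
#'   attribute).
#' @return Tibble `id`, `pass`, `reasons` (semicolon-joined; empty when
#'   passing).
#' @export
validate_inputs <- function(manifest, base_dir = attr(manifest, "base_dir")) {
  if (is.null(base_dir)) base_dir <- "."
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    r <- manifest[i, ]
    reasons <- character(0)
    if (!r$sex %in% c("female", "male"))
      reasons <- c(reasons, sprintf("unrecognised sex '%s'", r$sex))
    for (sc in c("madrs_total", "ymrs_total")) {
      v <- r[[sc]]
      if (is.na(v) || v < 0 || v > 60)
        reasons <- c(reasons, sprintf("%s out of range [0, 60]: %s", sc, v))
    }
    wav_path <- resolve_path(r$wav, base_dir)
    if (!file.exists(wav_path)) {
      reasons <- c(reasons, "wav file missing")
    } else {
      audio <- tryCatch(read_wav(wav_path), error = function(e) NULL)
      if (is.null(audio)) reasons <- c(reasons, "wav unreadable")
      else if (mean(abs(audio$samples) >= 0.999) > 0.01)
        reasons <- c(reasons, "audio clipped")
    }
    tr_path <- resolve_path(r$transcript, base_dir)
    if (!file.exists(tr_path)) {
      reasons <- c(reasons, "transcript file missing")
    } else {
      tr <- tryCatch(read_transcript_json(tr_path), error = function(e) e)
      if (inherits(tr, "error"))
        reasons <- c(reasons, paste("transcript invalid:",
                                    conditionMessage(tr)))
    }
    tibble::tibble(id = r$id, pass = length(reasons) == 0,
                   reasons = paste(reasons, collapse = "; "))
  })
  do.call(rbind, rows)
}

#' Default pipeline configuration
#'
#' @param manifest,story,embeddings,out_dir Paths (embeddings may be `NULL`
#'   to skip the word mover's distance).
#' @param seed Integer master seed.
#' @param segmentation,pitch Parameter lists forwarded to
#'   [segment_voicing()] and [track_pitch()].
#' @param intraword Intraword-time convention, see [timing_scores()].
#' @param subgroups,severity_tests,adjust_p,run_models Analysis toggles.
#' @return A `run_config` list.
#' @export
run_config <- function(manifest, story, embeddings = NULL, out_dir,
                       seed = 1L,
                       segmentation = list(), pitch = list(),
                       intraword = "onset",
                       subgroups = TRUE, severity_tests = TRUE,
                       adjust_p = FALSE, run_models = TRUE) {
  structure(list(manifest = manifest, story = story, embeddings = embeddings,
                 out_dir = out_dir, seed = as.integer(seed),
                 segmentation = segmentation, pitch = pitch,
                 intraword = intraword, subgroups = subgroups,
                 severity_tests = severity_tests, adjust_p = adjust_p,
                 run_models = run_models),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' Extract the full feature panel for one participant
#'
#' @param wav_path,transcript_path Input files.
#' @param story A [reference_story()].
#' @param embeddings An `embedding_table` or `NULL`.
#' @param segmentation,pitch Parameter lists.
#' @param intraword Convention for [timing_scores()].
#' @return One-row tibble of conversational + language + acoustic features.
#' @export
extract_participant_features <- function(wav_path, transcript_path, story,
                                         embeddings = NULL,
                                         segmentation = list(), pitch = list(),
                                         intraword = "onset") {
  audio <- read_wav(wav_path)
  transcript <- read_transcript_json(transcript_path)
  seg <- do.call(segment_voicing, c(list(audio), segmentation))
  conv <- conversational_features(seg, nrow(transcript$words))
  lang <- language_features(transcript, story, embeddings,
                            intraword = intraword)
  ac <- do.call(acoustic_features, c(list(audio), pitch))
  tibble::as_tibble(cbind(conv, lang, ac))
}

#' Feature column groups
#'
#' The conversational + NLP panel and the acoustic panel, as used for the
#' model feature sets (`combined` is their union).
#'
#' @return Named list of character vectors.
#' @export
feature_columns <- function() {
  list(
    nlp_conversational = c("speech_duration_s", "phonation_s", "silence_s",
                           "phonation_over_duration", "silence_over_phonation",
                           "speech_rate_wps", "n_words", "n_matched",
                           "latency_s", "mean_intraword_s", "wmd"),
    acoustic = c("f0_mean_hz", "f0_sd_hz", "jitter_local",
                 "jitter_local_abs_s", "jitter_rap", "jitter_ppq5",
                 "jitter_ddp", "shimmer_local", "shimmer_local_db",
                 "shimmer_apq3", "shimmer_apq5", "shimmer_apq11",
                 "shimmer_dda", "hnr_mean_db"))
}

write_csv_hashed <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Extracts the feature panel for every manifest row (per-participant
#' failures are isolated: logged, row flagged, run continues), then runs the
#' correlation analyses, severity-group tests, and (when enough complete
#' rows exist) the nested-CV random-forest evaluations, writing all outputs
#' into the run directory. Deterministic given the config seed; every
#' output carries the hash of the resolved configuration.
#'
#' @param config A `run_config` (or path to a YAML config).
#' @return Invisibly, a list with the run directory, the feature table, the
#'   QC report and (if run) the model evaluations. The QC report notes
#'   partial success when any participant failed.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- load_run_config(config)
  stopifnot(inherits(config, "run_config"))
  manifest <- read_manifest(config$manifest)
  base_dir <- attr(manifest, "base_dir")
  story <- read_story(config$story)
  embeddings <- if (!is.null(config$embeddings))
    read_embeddings(config$embeddings) else NULL
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  cfg_plain <- unclass(config)
  cfg_path <- file.path(config$out_dir, "config_resolved.json")
  jsonlite::write_json(cfg_plain, cfg_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  # hash excludes the output location so identical analyses into different
  # clean directories produce byte-identical content
  cfg_hashable <- cfg_plain
  cfg_hashable$out_dir <- NULL
  hash_tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg_hashable, hash_tmp, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  hash <- unname(tools::md5sum(hash_tmp))
  unlink(hash_tmp)

  feat_cols <- unlist(feature_columns(), use.names = FALSE)
  rows <- vector("list", nrow(manifest))
  failures <- list()
  for (i in seq_len(nrow(manifest))) {
    r <- manifest[i, ]
    feats <- tryCatch(
      extract_participant_features(
        resolve_path(r$wav, base_dir), resolve_path(r$transcript, base_dir),
        story, embeddings, config$segmentation, config$pitch,
        config$intraword),
      error = function(e) e)
    if (inherits(feats, "error")) {
      failures[[length(failures) + 1L]] <-
        list(id = r$id, error = conditionMessage(feats))
      feats <- tibble::as_tibble(
        stats::setNames(as.list(rep(NA_real_, length(feat_cols))), feat_cols))
    }
    rows[[i]] <- cbind(r[, c("id", "sex", "madrs_total", "ymrs_total")], feats)
  }
  features <- tibble::as_tibble(do.call(rbind, rows))
  write_csv_hashed(features, file.path(config$out_dir, "features.csv"), hash)

  targets <- c("madrs_total", "ymrs_total")
  cm <- if (config$subgroups)
    suppressWarnings(subgroup_analysis(features, feat_cols, targets)) else {
      x <- correlation_matrix(features, feat_cols, targets)
      x$stratum <- "overall"; x
    }
  if (config$adjust_p) cm <- adjust_correlations(cm)
  write_csv_hashed(as.data.frame(cm),
                   file.path(config$out_dir, "correlations_long.csv"), hash)

  if (config$severity_tests) {
    sev <- dichotomize_severity(features$madrs_total, features$ymrs_total)
    tests <- do.call(rbind, lapply(feat_cols, function(fc) {
      d <- group_difference(features, fc, sev$depr_severe)
      m <- group_difference(features, fc, sev$manic_severe)
      d$feature <- fc; d$grouping <- "depr_severe"
      m$feature <- fc; m$grouping <- "manic_severe"
      rbind(d, m)
    }))
    write_csv_hashed(tests, file.path(config$out_dir, "severity_tests.csv"),
                     hash)
  }

  evaluations <- NULL
  models_note <- "models not run"
  if (isTRUE(config$run_models)) {
    groups <- feature_columns()
    specs <- list(
      feature_set_spec("nlp_conversational", groups$nlp_conversational),
      feature_set_spec("acoustic", groups$acoustic),
      feature_set_spec("combined", unlist(groups, use.names = FALSE)))
    specs <- c(specs, lapply(specs, function(s) {
      s$adjust_sex <- TRUE; s
    }))
    evaluations <- list()
    for (sp in specs) for (tg in targets) {
      ev <- tryCatch(nested_cv_evaluate(features, sp, tg, seed = config$seed),
                     error = function(e) e)
      if (inherits(ev, "error")) {
        models_note <- paste0("model skipped (", sp$name, " ~ ", tg, "): ",
                              conditionMessage(ev))
      } else {
        evaluations[[length(evaluations) + 1L]] <- ev
      }
    }
    if (length(evaluations)) {
      models_note <- sprintf("%d evaluations run", length(evaluations))
      write_csv_hashed(report_table(evaluations),
                       file.path(config$out_dir, "model_report.csv"), hash)
      per_fold <- do.call(rbind, lapply(evaluations, function(e) {
        pf <- e$per_fold
        pf$target <- e$target; pf$feature_set <- e$spec$name
        pf$adjust_sex <- e$spec$adjust_sex
        pf
      }))
      write_csv_hashed(per_fold,
                       file.path(config$out_dir, "model_folds.csv"), hash)
    }
  }

  qc <- list(config_hash = hash,
             n_participants = nrow(manifest),
             n_failed = length(failures),
             failures = failures,
             models = models_note,
             partial_success = length(failures) > 0)
  jsonlite::write_json(qc, file.path(config$out_dir, "qc.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(out_dir = config$out_dir, features = features, qc = qc,
                 evaluations = evaluations))
}
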