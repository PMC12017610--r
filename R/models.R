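#' Regression performance metrics
#'
#' `mse` is the mean squared residual, `mae` the mean absolute residual,
#' and `r2 = 1 - SSres/SStot` with `SStot` taken about the mean of
#' `y_true`. On held-out data `r2` can be negative; when `y_true` has zero
#' variance `r2` is undefined and reported `NA`.
#'
#' @param y_true,y_pred Numeric vectors of equal nonzero length.
#' @return One-row tibble `r2`, `mse`, `mae`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) > 0,
            all(is.finite(y_true)), all(is.finite(y_pred)))
  res <- y_true - y_pred
  mse <- mean(res^2)
  mae <- mean(abs(res))
  sstot <- sum((y_true - mean(y_true))^2)
  r2 <- if (sstot == 0) NA_real_ else 1 - sum(res^2) / sstot
  tibble::tibble(r2 = r2, mse = mse, mae = mae)
}

#' Feature-set specification for the severity models
#'
#' @param name One of `"nlp_conversational"`, `"acoustic"`, `"combined"`,
#'   or any label for a custom set.
#' @param columns Nonempty character vector of feature column names.
#' @param adjust_sex If `TRUE`, a 0/1 sex indicator (female = 0, male = 1)
#'   is appended to the predictor matrix.
#' @return A `feature_set_spec`.
#' @export
feature_set_spec <- function(name, columns, adjust_sex = FALSE) {
  stopifnot(is.character(columns), length(columns) >= 1)
  structure(list(name = name, columns = columns, adjust_sex = adjust_sex),
            class = "feature_set_spec")
}

#' Default hyperparameter grid for the random-forest inner search
#'
#' Trees in {200, 500}, maximum depth in {unbounded, 5}, minimum node size
#' in {1, 3}.
#'
#' @return Data frame with columns `num_trees`, `max_depth` (0 =
#'   unbounded), `min_node_size`.
#' @export
default_rf_grid <- function() {
  expand.grid(num_trees = c(200L, 500L), max_depth = c(0L, 5L),
              min_node_size = c(1L, 3L))
}

# assemble the predictor matrix for a spec; drops incomplete rows
build_design <- function(table, spec, target) {
  cols <- spec$columns
  stopifnot(all(cols %in% names(table)), target %in% names(table))
  X <- as.data.frame(table[, cols, drop = FALSE])
  if (spec$adjust_sex) {
    stopifnot("sex" %in% names(table))
    X$sex <- as.integer(table$sex == "male")
  }
  y <- table[[target]]
  ok <- stats::complete.cases(X) & is.finite(y)
  list(X = X[ok, , drop = FALSE], y = y[ok], n_dropped = sum(!ok))
}

fit_rf <- function(X, y, hp, seed) {
  ranger::ranger(y = y, x = X,
                 num.trees = hp$num_trees,
                 max.depth = hp$max_depth,
                 min.node.size = hp$min_node_size,
                 seed = seed, num.threads = 1)
}

predict_rf <- function(model, X) {
  stats::predict(model, data = X, num.threads = 1, seed = 1L)$predictions
}

# seeded fold assignment, stratified by target quartile
stratified_folds <- function(y, k, seed, stratify = TRUE) {
  n <- length(y)
  set.seed(seed)
  fold <- integer(n)
  if (stratify) {
    q <- stats::quantile(y, probs = c(0.25, 0.5, 0.75), type = 7)
    stratum <- findInterval(y, unique(q))
  } else {
    stratum <- rep(0L, n)
  }
  for (s in unique(stratum)) {
    idx <- sample(which(stratum == s))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  # deal folds round-robin from a shuffled global order so sizes balance
  fold
}

#' Nested cross-validated random-forest evaluation
#'
#' Outer `outer_k`-fold split (seeded; by default stratified by target
#' quartile so small samples keep comparable fold spreads); on each outer
#' training set an inner `inner_k`-fold grid search over the forest
#' hyperparameters selects the minimum-MSE configuration, which is refit on
#' the full outer training set and evaluated on the held-out fold. Features
#' enter the forest unscaled. Rows with missing predictors or target are
#' dropped listwise (count reported).
#'
#' @param table Participant table (one row each).
#' @param spec A [feature_set_spec()].
#' @param target Target column name (e.g. `"madrs_total"`).
#' @param seed Integer seed; the whole evaluation is deterministic in it.
#' @param outer_k,inner_k Fold counts (defaults 5 and 3).
#' @param grid Hyperparameter data frame (default [default_rf_grid()]).
#' @param stratify Stratify outer folds by target quartile (default TRUE).
#' @return A `model_evaluation`: list with `per_fold` (tibble `fold`, `r2`,
#'   `mse`, `mae`, `n_test`, plus the selected hyperparameters),
#'   `averages` (`r2_avg`, `mse_avg`, `mae_avg`; an average is `NA` when
#'   any fold value is missing), `target`, `spec`, `seed`, `n_dropped`.
#' @export
nested_cv_evaluate <- function(table, spec, target, seed,
                               outer_k = 5L, inner_k = 3L,
                               grid = default_rf_grid(), stratify = TRUE) {
  stopifnot(inherits(spec, "feature_set_spec"))
  d <- build_design(table, spec, target)
  if (nrow(d$X) < 10) stop("fewer than 10 complete rows for ", spec$name)
  X <- d$X; y <- d$y
  fold <- stratified_folds(y, outer_k, seed = seed, stratify = stratify)
  if (any(tabulate(fold, outer_k) < 2))
    stop("outer fold with fewer than 2 test rows; reduce outer_k")

  per_fold <- vector("list", outer_k)
  for (f in seq_len(outer_k)) {
    tr <- fold != f
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
    Xte <- X[!tr, , drop = FALSE]; yte <- y[!tr]
    inner_fold <- stratified_folds(ytr, inner_k, seed = seed * 131L + f,
                                   stratify = stratify)
    cv_mse <- vapply(seq_len(nrow(grid)), function(g) {
      mean(vapply(seq_len(inner_k), function(i) {
        it <- inner_fold != i
        m <- fit_rf(Xtr[it, , drop = FALSE], ytr[it], grid[g, ],
                    seed = seed * 7919L + f * 101L + i)
        mean((ytr[!it] - predict_rf(m, Xtr[!it, , drop = FALSE]))^2)
      }, numeric(1)))
    }, numeric(1))
    best <- grid[which.min(cv_mse), ]
    model <- fit_rf(Xtr, ytr, best, seed = seed * 524287L + f)
    met <- regression_metrics(yte, predict_rf(model, Xte))
    per_fold[[f]] <- cbind(tibble::tibble(fold = f, n_test = length(yte)),
                           met, tibble::as_tibble(best))
  }
  per_fold <- tibble::as_tibble(do.call(rbind, per_fold))
  avg <- function(v) if (anyNA(v)) NA_real_ else mean(v)
  structure(list(per_fold = per_fold,
                 averages = tibble::tibble(r2_avg = avg(per_fold$r2),
                                           mse_avg = avg(per_fold$mse),
                                           mae_avg = avg(per_fold$mae)),
                 target = target, spec = spec, seed = seed,
                 n_dropped = d$n_dropped),
            class = "model_evaluation")
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat(sprintf("<model_evaluation: %s ~ %s%s, seed %d>\n", x$target,
              x$spec$name, if (x$spec$adjust_sex) " + sex" else "", x$seed))
  print(x$averages)
  invisible(x)
}

#' Fit a single random forest on a feature set
#'
#' Plain (non-nested) fit, used for whole-sample attribution analyses.
#'
#' @inheritParams nested_cv_evaluate
#' @param hyperparams One row of a hyperparameter grid (default: 500
#'   unbounded trees, min node size 1).
#' @return A `fitted_forest`: list with `model` (ranger object), `columns`,
#'   `X`, `y`, `target`, `seed`.
#' @export
fit_forest <- function(table, spec, target, seed,
                       hyperparams = data.frame(num_trees = 500L,
                                                max_depth = 0L,
                                                min_node_size = 1L)) {
  d <- build_design(table, spec, target)
  model <- fit_rf(d$X, d$y, hyperparams, seed = seed)
  structure(list(model = model, columns = names(d$X), X = d$X, y = d$y,
                 target = target, seed = seed),
            class = "fitted_forest")
}

#' Performance report shaped like a metric-by-fold table
#'
#' Arranges a list of [nested_cv_evaluate()] results into the canonical
#' report layout: within each feature-set block, rows are `R2 average`,
#' `Fold 1..k`, `MSE average`, `Fold 1..k`, `MAE average`, `Fold 1..k`;
#' columns are one per target-by-adjustment combination. Missing averages
#' stay `NA` (rendered as em dashes downstream), never silently dropped.
#'
#' @param evaluations List of `model_evaluation` objects (at least one).
#' @return A tibble with columns `feature_set`, `row`, and one column per
#'   `target`/`adjustment` combination (named `<target>_<unadjusted|adjusted>`).
#' @export
report_table <- function(evaluations) {
  stopifnot(length(evaluations) >= 1)
  col_of <- function(ev) paste0(ev$target, "_",
                                if (ev$spec$adjust_sex) "adjusted" else "unadjusted")
  sets <- unique(vapply(evaluations, function(e) e$spec$name, character(1)))
  cols <- unique(vapply(evaluations, col_of, character(1)))
  k <- max(vapply(evaluations, function(e) nrow(e$per_fold), integer(1)))
  row_names <- function(metric_label)
    c(paste(metric_label, "average"), paste("Fold", seq_len(k)))
  rows <- c(row_names("R2"), row_names("MSE"), row_names("MAE"))
  out <- expand.grid(row = rows, feature_set = sets,
                     stringsAsFactors = FALSE)[, c("feature_set", "row")]
  for (cn in cols) out[[cn]] <- NA_real_
  for (ev in evaluations) {
    cn <- col_of(ev)
    blk <- out$feature_set == ev$spec$name
    vals <- c(ev$averages$r2_avg, ev$per_fold$r2,
              ev$averages$mse_avg, ev$per_fold$mse,
              ev$averages$mae_avg, ev$per_fold$mae)
    out[[cn]][blk] <- vals
  }
  tibble::as_tibble(out)
}
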