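#' Shapley feature attributions by permutation sampling
#'
#' Interventional Shapley values for a fitted forest, estimated by sampling
#' feature permutations against a background sample: for each permutation
#' and background row, features are switched from the background value to
#' the explained row's value in permutation order, and each feature is
#' credited with the change in prediction at its switch. Averaging over
#' permutations and background rows gives the attribution. By the
#' telescoping construction, for every explained row the attributions sum
#' exactly to `prediction - base_value`, where `base_value` is the mean
#' prediction over the background sample; the sampling error affects only
#' how the total is shared among features (standard error decreasing with
#' `n_perm * n_background`).
#'
#' @param fit A `fitted_forest` from [fit_forest()].
#' @param X Data frame of rows to explain; must carry exactly the model's
#'   feature columns.
#' @param background Data frame of background rows (default: the training
#'   matrix stored in `fit`).
#' @param n_perm Number of sampled permutations (default 8).
#' @param n_background Number of background rows sampled (default 20).
#' @param seed Integer seed for the permutation and background draws.
#' @return An `attribution_matrix`: list with `contributions` (matrix,
#'   rows = explained rows, columns = features), `base_value`, and
#'   `predictions` (model predictions for `X`).
#' @export
shapley_attribution <- function(fit, X, background = fit$X,
                                n_perm = 8L, n_background = 20L, seed = 1L) {
  stopifnot(inherits(fit, "fitted_forest"))
  X <- as.data.frame(X)
  if (!identical(sort(names(X)), sort(fit$columns)))
    stop("columns of X do not match the fitted model: expected ",
         paste(fit$columns, collapse = ", "))
  X <- X[, fit$columns, drop = FALSE]
  background <- as.data.frame(background)[, fit$columns, drop = FALSE]
  p <- length(fit$columns)
  n <- nrow(X)

  set.seed(seed)
  bg_idx <- if (nrow(background) <= n_background) seq_len(nrow(background))
            else sample(nrow(background), n_background)
  bg <- background[bg_idx, , drop = FALSE]
  B <- nrow(bg)
  perms <- lapply(seq_len(n_perm), function(i) sample.int(p))

  # stack every hybrid row: for each (explained row, permutation, step k =
  # 0..p, background row) the row equals bg with features perm[1..k]
  # replaced by the explained row's values
  blocks <- vector("list", n_perm * (p + 1L))
  bi <- 0L
  for (pi in seq_len(n_perm)) {
    perm <- perms[[pi]]
    for (k in 0:p) {
      repl <- perm[seq_len(k)]
      # rows: explained index varies fastest within each background row
      h <- bg[rep(seq_len(B), each = n), , drop = FALSE]
      if (k > 0) h[, repl] <- X[rep(seq_len(n), times = B), repl, drop = FALSE]
      bi <- bi + 1L
      blocks[[bi]] <- h
    }
  }
  all_rows <- do.call(rbind, blocks)
  preds <- predict_rf(fit$model, all_rows)
  block_len <- n * B
  # preds layout: block index (perm, k) major, then background, then row
  phi <- matrix(0, n, p, dimnames = list(NULL, fit$columns))
  bi <- 0L
  for (pi in seq_len(n_perm)) {
    perm <- perms[[pi]]
    prev <- NULL
    for (k in 0:p) {
      bi <- bi + 1L
      cur <- matrix(preds[((bi - 1L) * block_len + 1L):(bi * block_len)],
                    nrow = n)            # n x B
      if (k > 0) {
        j <- perm[k]
        phi[, j] <- phi[, j] + rowSums(cur - prev)
      }
      prev <- cur
    }
  }
  phi <- phi / (n_perm * B)
  base_value <- mean(predict_rf(fit$model, bg))
  structure(list(contributions = phi, base_value = base_value,
                 predictions = predict_rf(fit$model, X)),
            class = "attribution_matrix")
}

#' Mean absolute Shapley attribution per feature
#' @param attr An `attribution_matrix`.
#' @return Named numeric vector, sorted decreasing.
#' @export
attribution_importance <- function(attr) {
  sort(colMeans(abs(attr$contributions)), decreasing = TRUE)
}

#' Beeswarm-style attribution summary plot
#'
#' Scatter of per-sample Shapley contributions by feature, ordered by mean
#' absolute contribution.
#'
#' @param attr An `attribution_matrix`.
#' @return A ggplot object.
#' @export
plot_attributions <- function(attr) {
  imp <- attribution_importance(attr)
  df <- data.frame(
    feature = factor(rep(colnames(attr$contributions),
                         each = nrow(attr$contributions)),
                     levels = rev(names(imp))),
    value = as.numeric(attr$contributions))
  ggplot2::ggplot(df, ggplot2::aes(x = value, y = feature)) +
    ggplot2::geom_jitter(height = 0.2, size = 0.6, alpha = 0.5) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Shapley contribution", y = NULL) +
    ggplot2::theme_minimal()
}
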