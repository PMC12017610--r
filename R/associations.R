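#' Feature-by-target correlation matrix
#'
#' Pairwise-complete Spearman (average ranks for ties) or Pearson
#' correlations between feature columns and symptom-target columns, with
#' two-sided p-values. Cells with fewer than `min_n` complete pairs, or a
#' zero-variance side, are reported missing with a reason.
#'
#' @param table Data frame with one row per participant.
#' @param features Character vector of feature column names.
#' @param targets Character vector of target column names (e.g.
#'   `"madrs_total"`, `"ymrs_total"`).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param min_n Minimum complete pairs per cell (default 4).
#' @return A tibble of class `correlation_matrix` with columns `feature`,
#'   `target`, `rho`, `n_effective`, `p_value`, `reason` (NA when
#'   computed), and attribute `method`.
#' @export
correlation_matrix <- function(table, features, targets,
                               method = c("spearman", "pearson"),
                               min_n = 4) {
  method <- match.arg(method)
  stopifnot(all(features %in% names(table)), all(targets %in% names(table)))
  grid <- expand.grid(feature = features, target = targets,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(k) {
    x <- table[[grid$feature[k]]]
    y <- table[[grid$target[k]]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (n < min_n)
      return(list(rho = NA_real_, n = n, p = NA_real_,
                  reason = sprintf("fewer than %d complete pairs", min_n)))
    x <- x[ok]; y <- y[ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      return(list(rho = NA_real_, n = n, p = NA_real_,
                  reason = "zero variance"))
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = method, exact = FALSE))
    list(rho = unname(ct$estimate), n = n, p = ct$p.value, reason = NA_character_)
  })
  out <- tibble::tibble(
    feature = grid$feature, target = grid$target,
    rho = vapply(res, `[[`, numeric(1), "rho"),
    n_effective = vapply(res, `[[`, numeric(1), "n"),
    p_value = vapply(res, `[[`, numeric(1), "p"),
    reason = vapply(res, `[[`, character(1), "reason"))
  attr(out, "method") <- method
  class(out) <- c("correlation_matrix", class(out))
  out
}

#' Reshape a correlation matrix to wide form
#' @param cm A `correlation_matrix`.
#' @return Matrix of rho values, features as rows, targets as columns.
#' @export
correlation_rho_matrix <- function(cm) {
  feats <- unique(cm$feature); targs <- unique(cm$target)
  m <- matrix(NA_real_, length(feats), length(targs),
              dimnames = list(feats, targs))
  m[cbind(match(cm$feature, feats), match(cm$target, targs))] <- cm$rho
  m
}

#' Dichotomize symptom severity at the clinical cutoffs
#'
#' Severe depressive symptoms: MADRS total `>= 19`; severe manic symptoms:
#' YMRS total `>= 20` (both cutoffs inclusive). Missing totals give `NA`.
#'
#' @param madrs_total,ymrs_total Integer vectors in 0-60 (NA allowed).
#' @return Tibble with logical columns `depr_severe`, `manic_severe`.
#' @export
dichotomize_severity <- function(madrs_total, ymrs_total) {
  chk <- function(v, nm) {
    if (any(v < 0 | v > 60, na.rm = TRUE))
      stop(nm, " totals must lie in [0, 60]")
    v
  }
  tibble::tibble(depr_severe = chk(madrs_total, "MADRS") >= 19,
                 manic_severe = chk(ymrs_total, "YMRS") >= 20)
}

#' Rank-sum test of a feature between severity groups
#'
#' Two-sided Mann-Whitney test of `feature` between the two levels of a
#' logical grouping (e.g. severe vs non-severe). The reported `U` counts
#' pairs in which the `TRUE`-group value exceeds the `FALSE`-group value.
#' Exact p-values are used when both groups have at most 20 observations
#' and the feature has no ties; otherwise the normal approximation with
#' tie correction.
#'
#' @param table Data frame.
#' @param feature Feature column name.
#' @param grouping Logical vector (or column name) defining the two groups.
#' @return One-row tibble: `U`, `p_value`, `median_true`, `median_false`,
#'   `n_true`, `n_false`, `reason` (NA unless degenerate).
#' @export
group_difference <- function(table, feature, grouping) {
  if (is.character(grouping) && length(grouping) == 1)
    grouping <- table[[grouping]]
  x <- table[[feature]]
  ok <- is.finite(x) & !is.na(grouping)
  x <- x[ok]; g <- grouping[ok]
  x1 <- x[g]; x0 <- x[!g]
  miss <- function(reason)
    tibble::tibble(U = NA_real_, p_value = NA_real_,
                   median_true = NA_real_, median_false = NA_real_,
                   n_true = length(x1), n_false = length(x0), reason = reason)
  if (length(x1) < 2 || length(x0) < 2) return(miss("a group has fewer than 2 values"))
  if (stats::sd(x) == 0) return(miss("constant feature in both groups"))
  exact <- length(x1) <= 20 && length(x0) <= 20 && !anyDuplicated(x)
  wt <- suppressWarnings(
    stats::wilcox.test(x1, x0, exact = exact, correct = !exact))
  tibble::tibble(U = unname(wt$statistic), p_value = wt$p.value,
                 median_true = stats::median(x1),
                 median_false = stats::median(x0),
                 n_true = length(x1), n_false = length(x0),
                 reason = NA_character_)
}

#' Sex-stratified correlation analysis
#'
#' Recomputes the feature-by-target correlation matrix overall and within
#' each sex stratum (mirroring overall/male/female heat-plot panels).
#' Strata with fewer than `min_stratum_n` rows are omitted with a warning.
#'
#' @inheritParams correlation_matrix
#' @param by Stratification column name (default `"sex"`).
#' @param min_stratum_n Minimum rows per stratum (default 4).
#' @return Tibble of class `correlation_matrix` with an extra `stratum`
#'   column (`"overall"` plus one level per retained stratum).
#' @export
subgroup_analysis <- function(table, features, targets,
                              method = c("spearman", "pearson"),
                              by = "sex", min_stratum_n = 4) {
  method <- match.arg(method)
  overall <- correlation_matrix(table, features, targets, method)
  overall$stratum <- "overall"
  pieces <- list(overall)
  for (lev in sort(unique(table[[by]]))) {
    sub <- table[table[[by]] == lev, , drop = FALSE]
    if (nrow(sub) < min_stratum_n) {
      warning(sprintf("stratum '%s' omitted: only %d rows", lev, nrow(sub)))
      next
    }
    cm <- correlation_matrix(sub, features, targets, method)
    cm$stratum <- as.character(lev)
    pieces[[length(pieces) + 1L]] <- cm
  }
  out <- do.call(rbind, pieces)
  attr(out, "method") <- method
  class(out) <- c("correlation_matrix", class(out))
  out
}

#' Adjust correlation p-values for multiple testing
#'
#' Off by default in the analysis pipeline; applies Benjamini-Hochberg (or
#' any [stats::p.adjust()] method) across the cells of a correlation
#' matrix, adding a `p_adjusted` column.
#'
#' @param cm A `correlation_matrix`.
#' @param method Adjustment method (default `"BH"`).
#' @return The matrix with a `p_adjusted` column.
#' @export
adjust_correlations <- function(cm, method = "BH") {
  cm$p_adjusted <- stats::p.adjust(cm$p_value, method = method)
  cm
}

#' Correlation heat plot
#'
#' Diverging-scale heat plot of the rho values with the colour scale fixed
#' at \[-1, 1\]; one facet per stratum when present.
#'
#' @param cm A `correlation_matrix`.
#' @return A ggplot object.
#' @export
plot_correlation_heatmap <- function(cm) {
  df <- as.data.frame(cm)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = target, y = feature,
                                        fill = rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0,
                                  limits = c(-1, 1), name = "rho") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  if ("stratum" %in% names(df))
    p <- p + ggplot2::facet_wrap(~stratum)
  p
}
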