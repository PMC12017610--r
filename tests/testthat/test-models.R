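test_that("regression metrics match hand evaluation and degenerate contracts", {
  m <- regression_metrics(c(1, 2, 3), c(2, 2, 2))
  expect_equal(m$mse, 2 / 3)
  expect_equal(m$mae, 2 / 3)
  expect_equal(m$r2, 0)
  perfect <- regression_metrics(c(1, 5, 9), c(1, 5, 9))
  expect_equal(unlist(perfect), c(r2 = 1, mse = 0, mae = 0))
  flat <- regression_metrics(c(0, 0), c(1, 1))
  expect_equal(flat$mse, 1)
  expect_equal(flat$mae, 1)
  expect_true(is.na(flat$r2))
})

test_that("nested CV is deterministic, partitions rows, and satisfies Jensen", {
  em <- data.frame(feature = paste0("x", 1:3), target = "madrs",
                   spearman_target = c(0.6, 0.2, 0))
  tab <- generate_cohort(cohort_spec(80, em, seed = 7))
  sp <- feature_set_spec("panel", paste0("x", 1:3))
  grid <- data.frame(num_trees = 100L, max_depth = 0L, min_node_size = c(1L, 5L))
  ev1 <- nested_cv_evaluate(tab, sp, "madrs_total", seed = 5, grid = grid)
  ev2 <- nested_cv_evaluate(tab, sp, "madrs_total", seed = 5, grid = grid)
  expect_identical(ev1$per_fold, ev2$per_fold)
  expect_equal(sum(ev1$per_fold$n_test), nrow(tab))
  expect_true(all(ev1$per_fold$mae^2 <= ev1$per_fold$mse + 1e-12))
  expect_equal(ev1$averages$r2_avg, mean(ev1$per_fold$r2))
  expect_equal(ev1$averages$mse_avg, mean(ev1$per_fold$mse))
})

test_that("sex adjustment appends exactly one 0/1 predictor", {
  em <- data.frame(feature = "x1", target = "madrs", spearman_target = 0.5)
  tab <- generate_cohort(cohort_spec(40, em, seed = 9))
  d <- speechmarkers:::build_design(
    tab, feature_set_spec("a", "x1", adjust_sex = TRUE), "madrs_total")
  expect_equal(names(d$X), c("x1", "sex"))
  expect_true(all(d$X$sex %in% 0:1))
  expect_equal(d$X$sex, as.integer(tab$sex == "male"))
})

test_that("rows with missing features are dropped listwise and counted", {
  em <- data.frame(feature = c("x1", "x2"), target = "madrs",
                   spearman_target = c(0.5, 0.2))
  tab <- generate_cohort(cohort_spec(40, em, seed = 11))
  tab$x1[c(3, 9)] <- NA
  d <- speechmarkers:::build_design(tab, feature_set_spec("a", c("x1", "x2")),
                                    "madrs_total")
  expect_equal(d$n_dropped, 2)
  expect_equal(nrow(d$X), 38)
})

test_that("undersized tables abort with a sizing error", {
  em <- data.frame(feature = "x1", target = "madrs", spearman_target = 0.5)
  tab <- generate_cohort(cohort_spec(8, em, seed = 13))
  expect_error(nested_cv_evaluate(tab, feature_set_spec("a", "x1"),
                                  "madrs_total", seed = 1),
               "10 complete rows")
})

test_that("Shapley attributions are locally additive and symmetric", {
  em <- data.frame(feature = c("x1", "x2"), target = "madrs",
                   spearman_target = c(0.6, 0.1))
  tab <- generate_cohort(cohort_spec(60, em, seed = 15))
  tab$x2 <- tab$x1                       # duplicated feature
  fit <- fit_forest(tab, feature_set_spec("dup", c("x1", "x2")),
                    "madrs_total", seed = 3)
  at <- shapley_attribution(fit, fit$X[1:25, ], n_perm = 24, seed = 8)
  total <- rowSums(at$contributions) + at$base_value
  expect_equal(total, at$predictions, tolerance = 1e-6)
  imp <- colMeans(abs(at$contributions))
  expect_lt(abs(imp["x1"] - imp["x2"]) / mean(imp), 0.25)
})

test_that("a single-feature model attributes the whole deviation to it", {
  em <- data.frame(feature = "x1", target = "madrs", spearman_target = 0.6)
  tab <- generate_cohort(cohort_spec(50, em, seed = 21))
  fit <- fit_forest(tab, feature_set_spec("solo", "x1"), "madrs_total", seed = 2)
  at <- shapley_attribution(fit, fit$X[1:10, , drop = FALSE], n_perm = 2,
                            seed = 4)
  expect_equal(as.numeric(at$contributions[, "x1"]),
               at$predictions - at$base_value, tolerance = 1e-9)
})

test_that("a column mismatch raises a schema error", {
  em <- data.frame(feature = "x1", target = "madrs", spearman_target = 0.5)
  tab <- generate_cohort(cohort_spec(30, em, seed = 23))
  fit <- fit_forest(tab, feature_set_spec("a", "x1"), "madrs_total", seed = 1)
  bad <- data.frame(wrong = 1:3)
  expect_error(shapley_attribution(fit, bad), "columns")
})

test_that("the report table mirrors the metric-by-fold layout", {
  em <- data.frame(feature = "x1", target = "madrs", spearman_target = 0.6)
  tab <- generate_cohort(cohort_spec(60, em, seed = 25))
  grid <- data.frame(num_trees = 100L, max_depth = 0L, min_node_size = 1L)
  sp <- feature_set_spec("nlp_conversational", "x1")
  spa <- feature_set_spec("nlp_conversational", "x1", adjust_sex = TRUE)
  evs <- list(nested_cv_evaluate(tab, sp, "madrs_total", 1, grid = grid),
              nested_cv_evaluate(tab, spa, "madrs_total", 1, grid = grid))
  rt <- report_table(evs)
  expect_equal(nrow(rt), 18)              # 3 metrics x (average + 5 folds)
  expect_true(all(c("madrs_total_unadjusted", "madrs_total_adjusted") %in%
                    names(rt)))
  expect_equal(rt$madrs_total_unadjusted[rt$row == "R2 average"],
               evs[[1]]$averages$r2_avg)
  expect_equal(rt$madrs_total_unadjusted[rt$row == "Fold 3"][1],
               evs[[1]]$per_fold$r2[3])
  # an average over folds with a missing value stays missing in the table
  ev_na <- evs[[1]]
  ev_na$per_fold$r2[2] <- NA_real_
  ev_na$averages$r2_avg <- NA_real_
  rt2 <- report_table(list(ev_na))
  expect_true(is.na(rt2$madrs_total_unadjusted[rt2$row == "R2 average"]))
})

test_that("fold averages computed with any missing fold value are flagged NA", {
  em <- data.frame(feature = "x1", target = "madrs", spearman_target = 0.4)
  tab <- generate_cohort(cohort_spec(60, em, seed = 27))
  grid <- data.frame(num_trees = 50L, max_depth = 0L, min_node_size = 1L)
  ev <- nested_cv_evaluate(tab, feature_set_spec("a", "x1"), "madrs_total",
                           seed = 2, grid = grid)
  expect_false(anyNA(ev$per_fold$r2))
  expect_equal(ev$averages$mae_avg, mean(ev$per_fold$mae))
})
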