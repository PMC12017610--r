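test_that("Spearman correlation handles monotone, reversed and tied data", {
  tab <- tibble::tibble(x = c(1, 2, 3), up = c(1, 4, 9), down = c(3, 2, 1))
  cm <- correlation_matrix(tab, c("up", "down"), "x", min_n = 3)
  expect_equal(cm$rho[cm$feature == "up"], 1)
  expect_equal(cm$rho[cm$feature == "down"], -1)
  # ties: rank-then-Pearson with average ranks oracle
  tab2 <- tibble::tibble(x = c(1, 2, 2, 3), y = c(1, 3, 2, 4))
  cm2 <- correlation_matrix(tab2, "y", "x")
  oracle <- stats::cor(rank(tab2$x), rank(tab2$y), method = "pearson")
  expect_equal(cm2$rho, oracle, tolerance = 1e-12)
})

test_that("insufficient or degenerate cells are missing with reasons", {
  tab <- tibble::tibble(x = c(1, 2, 3, 4), flat = rep(5, 4),
                        holey = c(1, NA, NA, NA))
  cm <- correlation_matrix(tab, c("flat", "holey"), "x")
  expect_true(all(is.na(cm$rho)))
  expect_match(cm$reason[cm$feature == "flat"], "zero variance")
  expect_match(cm$reason[cm$feature == "holey"], "complete pairs")
})

test_that("severity cutoffs are inclusive at 19 (MADRS) and 20 (YMRS)", {
  d <- dichotomize_severity(c(19, 18, 13, NA), c(20, 19, 5, 7))
  expect_equal(d$depr_severe, c(TRUE, FALSE, FALSE, NA))
  expect_equal(d$manic_severe, c(TRUE, FALSE, FALSE, FALSE))
  expect_error(dichotomize_severity(61, 5), "0, 60")
})

test_that("group difference test matches exact enumeration on separated groups", {
  tab <- tibble::tibble(v = c(1, 2, 3, 10, 11, 12),
                        g = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  gd <- group_difference(tab, "v", "g")
  expect_equal(gd$U, 9)          # every severe value exceeds every other
  expect_lte(gd$p_value, 0.1)    # 2/20 arrangements are this extreme
  expect_equal(gd$median_true, 11)
  same <- tibble::tibble(v = rep(c(1, 2, 3, 4), 2),
                         g = rep(c(TRUE, FALSE), each = 4))
  expect_gt(group_difference(same, "v", "g")$p_value, 0.9)
  const <- tibble::tibble(v = rep(1, 8), g = rep(c(TRUE, FALSE), 4))
  expect_true(is.na(group_difference(const, "v", "g")$U))
  expect_match(group_difference(const, "v", "g")$reason, "constant")
})

test_that("subgroup analysis reproduces the overall matrix on duplicated strata", {
  em <- basic_effect_map()
  co <- generate_cohort(cohort_spec(120, em, seed = 3))
  co$sex <- rep(c("female", "male"), each = 60)
  half <- co[1:60, ]
  both <- rbind(half, transform(half, sex = "male"))
  sa <- subgroup_analysis(both, em$feature, c("madrs_total", "ymrs_total"))
  f <- sa[sa$stratum == "female", c("feature", "target", "rho")]
  m <- sa[sa$stratum == "male", c("feature", "target", "rho")]
  expect_equal(f$rho, m$rho)
})

test_that("sex effect modification shows up as larger female correlations", {
  em <- data.frame(feature = "f1", target = "madrs", spearman_target = 0.3)
  co <- generate_cohort(cohort_spec(1000, em, sex_modifier = c(f1 = 2.0),
                                    seed = 19))
  sa <- subgroup_analysis(co, "f1", "madrs_total")
  rf <- abs(sa$rho[sa$stratum == "female"])
  rm_ <- abs(sa$rho[sa$stratum == "male"])
  expect_gt(rf, rm_)
})

test_that("undersized strata are omitted with a warning", {
  em <- basic_effect_map()
  co <- generate_cohort(cohort_spec(20, em, seed = 23))
  co$sex <- c(rep("female", 18), "male", "male")
  expect_warning(sa <- subgroup_analysis(co, em$feature, "madrs_total"),
                 "male")
  expect_false("male" %in% sa$stratum)
  expect_true(all(c("overall", "female") %in% sa$stratum))
})

test_that("correlations are invariant to row order and monotone transforms", {
  em <- basic_effect_map()
  co <- generate_cohort(cohort_spec(150, em, seed = 29))
  cm1 <- correlation_matrix(co, em$feature, "madrs_total")
  set.seed(1)
  cm2 <- correlation_matrix(co[sample(nrow(co)), ], em$feature, "madrs_total")
  expect_equal(cm1$rho, cm2$rho)
  co$silence_ratio <- exp(co$silence_ratio)   # strictly monotone transform
  cm3 <- correlation_matrix(co, "silence_ratio", "madrs_total")
  expect_equal(cm3$rho, cm1$rho[cm1$feature == "silence_ratio"])
})

test_that("BH adjustment adds a column without touching raw p-values", {
  em <- basic_effect_map()
  co <- generate_cohort(cohort_spec(60, em, seed = 41))
  cm <- correlation_matrix(co, em$feature, c("madrs_total", "ymrs_total"))
  adj <- adjust_correlations(cm)
  expect_equal(adj$p_value, cm$p_value)
  expect_equal(adj$p_adjusted, stats::p.adjust(cm$p_value, "BH"))
})

test_that("heat plot builder returns a ggplot with the fixed [-1, 1] scale", {
  em <- basic_effect_map()
  co <- generate_cohort(cohort_spec(50, em, seed = 43))
  cm <- correlation_matrix(co, em$feature, "madrs_total")
  p <- plot_correlation_heatmap(cm)
  expect_s3_class(p, "ggplot")
  expect_equal(p$scales$scales[[1]]$limits, c(-1, 1))
})
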