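test_that("control normalization produces unit controls and exact ratios", {
  tab <- data.frame(id = c("a1", "a2", "b1", "b2"),
                    control_ref = c("a1", "a1", "b1", "b1"),
                    label = c("healthy", "tumor", "healthy", "tumor"),
                    f1 = c(2, 4, 5, 10), f2 = c(1, 3, 2, 2))
  out <- normalize_to_control(tab, c("f1", "f2"))
  expect_equal(out$f1, c(1, 2, 1, 2))
  expect_equal(out$f2, c(1, 3, 1, 1))
  # global rescale before normalization is a no-op
  tab2 <- tab; tab2$f1 <- tab$f1 * 13
  expect_equal(normalize_to_control(tab2, "f1")$f1, out$f1)
  # zero control flags the column for that subject
  tab3 <- tab; tab3$f1[1] <- 0
  out3 <- normalize_to_control(tab3, "f1")
  expect_true(all(is.na(out3$f1[1:2])))
  expect_true(length(attr(out3, "flagged")) > 0)
})

test_that("feature ranking finds perfect monotone association first", {
  tab <- synthetic_cohort_table(n_per_arm = 15, shift = c(f1 = 0.5, f2 = 0),
                                seed = 3)
  # f3 separates the arms perfectly
  tab$f3 <- ifelse(tab$label == "tumor", 10, 0) + rnorm(nrow(tab), sd = 0.1)
  rk <- rank_features(tab, c("f1", "f2", "f3"))
  expect_equal(rk$feature[1], "f3")
  expect_equal(abs(rk$rho[1]), max(abs(rk$rho), na.rm = TRUE))
  expect_true(rk$significant[1])
  # constant feature is flagged and ranked last
  tab$f4 <- 1
  rk4 <- rank_features(tab, c("f1", "f4"))
  expect_true(rk4$flagged[rk4$feature == "f4"])
  expect_equal(rk4$feature[nrow(rk4)], "f4")
})

test_that("Spearman rho matches a brute-force rank-then-Pearson oracle", {
  set.seed(9)
  for (i in 1:5) {
    tab <- synthetic_cohort_table(n_per_arm = 8,
                                  shift = c(f1 = runif(1, 0, 2)), seed = i)
    rk <- rank_features(tab, "f1")
    oracle <- cor(rank(tab$f1), rank(as.integer(tab$label == "tumor")))
    expect_equal(rk$rho[1], oracle, tolerance = 1e-12)
  }
})

test_that("label-independent features are significant at about the alpha rate", {
  set.seed(1234)
  hits <- 0L; n_rep <- 300L
  lab <- rep(c("healthy", "tumor"), each = 50)
  for (i in seq_len(n_rep)) {
    tab <- data.frame(label = lab, f1 = rnorm(100))
    hits <- hits + rank_features(tab, "f1")$significant[1]
  }
  rate <- hits / n_rep
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("correlation matrix is symmetric with unit diagonal and flags duplicates", {
  tab <- synthetic_cohort_table(n_per_arm = 20, shift = c(f1 = 1, f2 = 0),
                                seed = 5)
  tab$f3 <- tab$f1
  m <- correlation_matrix(tab, c("f1", "f2", "f3"))
  expect_equal(m, t(m), tolerance = 1e-15)
  expect_equal(unname(diag(m)), rep(1, 3))
  expect_equal(m["f1", "f3"], 1, tolerance = 1e-12)
  expect_false(all(c("f1", "f3") %in% attr(m, "independent")))
  expect_true("f2" %in% attr(m, "independent"))
})

test_that("QDA separates far classes perfectly and is calibrated under the null", {
  tab <- synthetic_cohort_table(n_per_arm = 25, shift = c(f1 = 20), seed = 2)
  res <- qda_cv(tab, "f1", seed = 1)
  expect_equal(res$auc, 1.0)
  # permuted labels: AUC near chance when averaged over seeds
  aucs <- sapply(1:6, function(s) {
    set.seed(100 + s)
    tabp <- tab
    tabp$label <- sample(tab$label)
    qda_cv(tabp, "f1", seed = s)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.12)
})

test_that("stratified folds preserve the class ratio within one sample", {
  tab <- synthetic_cohort_table(n_per_arm = 23, shift = c(f1 = 1), seed = 7)
  res <- qda_cv(tab, "f1", k = 5, seed = 3)
  tab_kept <- table(res$fold, res$label)
  for (f in rownames(tab_kept))
    expect_lte(abs(tab_kept[f, 1] - tab_kept[f, 2]), 1)
})

test_that("out-of-fold scores match the closed-form Gaussian discriminant", {
  tab <- synthetic_cohort_table(n_per_arm = 12, shift = c(f1 = 1.5), seed = 4)
  res <- qda_cv(tab, "f1", k = 2, seed = 6)
  for (f in 1:2) {
    tr <- res$fold != f; te <- res$fold == f
    x_tr <- tab$f1[tr]; l_tr <- res$label[tr]
    # closed-form per-class Gaussian posterior, equal to QDA by definition
    post <- function(x) {
      d_t <- stats::dnorm(x, mean(x_tr[l_tr == "tumor"]), sd(x_tr[l_tr == "tumor"])) *
        mean(l_tr == "tumor")
      d_h <- stats::dnorm(x, mean(x_tr[l_tr == "healthy"]), sd(x_tr[l_tr == "healthy"])) *
        mean(l_tr == "healthy")
      d_t / (d_t + d_h)
    }
    expect_equal(res$scores[te], post(tab$f1[te]), tolerance = 1e-6)
  }
})

test_that("AUC equals the rank-based Mann-Whitney statistic", {
  tab <- synthetic_cohort_table(n_per_arm = 18, shift = c(f1 = 0.8), seed = 8)
  res <- qda_cv(tab, "f1", seed = 2)
  s_t <- res$scores[res$label == "tumor"]
  s_h <- res$scores[res$label == "healthy"]
  u <- mean(outer(s_t, s_h, function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(res$auc, u, tolerance = 1e-12)
})

test_that("combining complementary features beats each alone", {
  set.seed(21)
  n <- 40
  lab <- rep(c("healthy", "tumor"), each = n)
  u <- rnorm(2 * n)
  # each feature weakly informative alone, jointly separable
  tab <- data.frame(label = lab,
                    f1 = u + ifelse(lab == "tumor", 1, 0) + rnorm(2 * n, sd = 0.1),
                    f2 = u + rnorm(2 * n, sd = 0.1))
  cmp <- multi_vs_single_feature(tab, c("f1", "f2"), seed = 5)
  expect_true(cmp$combined_ge_single)
  expect_gt(cmp$combined_auc, max(cmp$table$auc[1:2]))
  # a single dominant feature is not substantially degraded by combination
  tab2 <- synthetic_cohort_table(n_per_arm = 40, shift = c(f1 = 3, f2 = 0),
                                 seed = 9)
  cmp2 <- multi_vs_single_feature(tab2, c("f1", "f2"), seed = 5)
  expect_gt(cmp2$combined_auc, cmp2$table$auc[1] - 0.05)
  # zero-signal cohort: everything near chance
  tab3 <- synthetic_cohort_table(n_per_arm = 50, shift = c(f1 = 0, f2 = 0),
                                 seed = 10)
  cmp3 <- multi_vs_single_feature(tab3, c("f1", "f2"), seed = 5)
  expect_lt(abs(cmp3$combined_auc - 0.5), 0.15)
})

test_that("grouped cross-validation keeps repeated measures in one fold", {
  tab <- synthetic_cohort_table(n_per_arm = 20, shift = c(f1 = 1), seed = 12)
  grp <- rep(sprintf("animal%02d", 1:10), each = 4)
  res <- qda_cv(tab, "f1", k = 5, seed = 4, group = grp)
  for (g in unique(grp))
    expect_equal(length(unique(res$fold[grp == g])), 1L)
})
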