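separable_data <- function(n = 10) {
  vals <- rbind(matrix(rlnorm(n * 2, 8, 0.2), n),    # high in both peptides
                matrix(rlnorm(n * 2, 3, 0.2), n))    # low in both
  m <- tiny_matrix(vals, sample_ids = sprintf("S%02d", 1:(2 * n)),
                   peptide_ids = c("A", "B"))
  g <- tiny_groups(m$sample_id, rep(c("fibrosis", "nofibrosis"), each = n))
  list(m = m, g = g)
}

test_that("a separable two-peptide problem is classified perfectly", {
  withr::with_seed(41, d <- separable_data())
  clf <- train_panel(d$m, d$g, c("A", "B"))
  pred <- apply_panel(clf, d$m)
  expect_equal(pred$predicted_label,
               as.character(d$g$group))
  expect_true(all(pred$score[d$g$group == "fibrosis"] >
                    pred$score[d$g$group == "nofibrosis"]))
})

test_that("scores and labels respect the threshold invariant", {
  withr::with_seed(42, d <- separable_data())
  clf <- train_panel(d$m, d$g, c("A", "B"))
  pred <- apply_panel(clf, d$m)
  expect_equal(pred$predicted_label == "fibrosis", pred$score >= clf$threshold)
})

test_that("serialization round-trips with identical scores", {
  withr::with_seed(43, d <- separable_data())
  clf <- train_panel(d$m, d$g, c("A", "B"))
  f <- withr::local_tempfile(fileext = ".json")
  write_classifier(clf, f)
  clf2 <- read_classifier(f)
  expect_equal(apply_panel(clf2, d$m)$score, apply_panel(clf, d$m)$score,
               tolerance = 1e-12)
  expect_equal(clf2$threshold, clf$threshold, tolerance = 1e-12)
})

test_that("the stored decision function reproduces the underlying SVM", {
  withr::with_seed(44, {
    spec <- small_cohort_spec(seed = 44, n = 20)
    co <- generate_cohort(spec)
  })
  g <- assign_groups(co$metadata)
  panel <- planted_truth(spec)
  clf <- train_panel(co$intensities, g, panel)
  # refit e1071 on the same transformed features and compare decision values
  x <- panel_mat <- as.matrix(co$intensities[, panel])
  z <- sweep(sweep(log1p(x), 2, clf$center, "-"), 2, clf$scale, "/")
  y <- factor(as.character(g$group), levels = c("fibrosis", "nofibrosis"))
  fit <- e1071::svm(z, y, type = "C-classification", kernel = "radial",
                    cost = clf$cost, gamma = clf$gamma, scale = FALSE)
  dv <- attr(predict(fit, z, decision.values = TRUE), "decision.values")
  sgn <- if (startsWith(colnames(dv)[1], "fibrosis/")) 1 else -1
  expect_equal(apply_panel(clf, co$intensities)$score,
               unname(sgn * dv[, 1]), tolerance = 1e-10)
})

test_that("LOO scores equal a brute-force retrain-per-sample oracle", {
  withr::with_seed(45, {
    vals <- matrix(rlnorm(8 * 3, 5, 1), 4 + 4)
    m <- tiny_matrix(vals, peptide_ids = c("A", "B", "C"))
  })
  g <- tiny_groups(m$sample_id, rep(c("fibrosis", "nofibrosis"), each = 4))
  loo <- loo_scores(m, g, c("A", "B", "C"))
  for (i in seq_len(8)) {
    clf_i <- train_panel(m[-i, ], g[-i, ], c("A", "B", "C"), threshold = 0)
    oracle <- apply_panel(clf_i, m[i, ])$score
    expect_equal(loo$score[i], oracle, tolerance = 1e-12)
  }
})

test_that("scores are invariant to sample order and panel column order", {
  withr::with_seed(46, d <- separable_data(8))
  clf <- train_panel(d$m, d$g, c("A", "B"))
  perm <- sample(nrow(d$m))
  s1 <- apply_panel(clf, d$m)
  s2 <- apply_panel(clf, d$m[perm, ])
  expect_equal(s2$score[match(s1$sample_id, s2$sample_id)], s1$score)
  # training with permuted matrix columns gives the same scores
  clf2 <- train_panel(d$m[, c(1, 3, 2)], d$g, c("A", "B"))
  expect_equal(apply_panel(clf2, d$m)$score, s1$score, tolerance = 1e-10)
})

test_that("all-identical samples receive identical scores", {
  vals <- matrix(rep(c(10, 20), each = 6), 6)
  m <- tiny_matrix(vals, peptide_ids = c("A", "B"))
  g <- tiny_groups(m$sample_id, rep(c("fibrosis", "nofibrosis"), 3))
  clf <- train_panel(m, g, c("A", "B"), threshold = 0)
  s <- apply_panel(clf, m)$score
  expect_equal(max(s) - min(s), 0)
})

test_that("applying to the training data reproduces in-sample scores", {
  withr::with_seed(47, d <- separable_data())
  clf <- train_panel(d$m, d$g, c("A", "B"))
  s1 <- apply_panel(clf, d$m)$score
  s2 <- apply_panel(clf, d$m)$score
  expect_identical(s1, s2)
})

test_that("missing panel peptides are scored as undetected with a warning", {
  withr::with_seed(48, d <- separable_data())
  clf <- train_panel(d$m, d$g, c("A", "B"))
  m_drop <- d$m[, c("sample_id", "A")]
  expect_warning(s <- apply_panel(clf, m_drop), "absent")
  expect_equal(nrow(s), nrow(d$m))
  expect_error(train_panel(m_drop, d$g, c("A", "B")), "absent")
})

test_that("degenerate single-class input is rejected", {
  withr::with_seed(49, d <- separable_data())
  g_one <- dplyr::mutate(d$g, group = "fibrosis")
  expect_error(train_panel(d$m, g_one, c("A", "B")), "non-empty|both groups")
})

test_that("held-out performance tracks the LOO estimate on planted effects", {
  spec <- cohort_spec(n_fibrosis = 40, n_nofibrosis = 40, seed = 50)
  co <- generate_cohort(spec)
  g <- assign_groups(co$metadata)
  panel <- planted_truth(spec)
  loo <- loo_scores(co$intensities, g, panel)
  auc_loo <- roc(loo, score, group)$auc
  spec2 <- cohort_spec(n_fibrosis = 40, n_nofibrosis = 40, seed = 51)
  co2 <- generate_cohort(spec2)
  g2 <- assign_groups(co2$metadata)
  clf <- train_panel(co$intensities, g, panel)
  held <- apply_panel(clf, co2$intensities) |>
    dplyr::inner_join(g2, by = "sample_id")
  auc_held <- roc(held, score, group)$auc
  expect_lt(abs(auc_held - auc_loo), 0.05)
})
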