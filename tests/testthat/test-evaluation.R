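scored <- function(pos, neg) {
  tibble::tibble(score = c(pos, neg),
                 group = rep(c("fibrosis", "nofibrosis"),
                             c(length(pos), length(neg))))
}

test_that("AUC matches hand-countable concordance cases", {
  expect_equal(roc(scored(c(0.9, 0.8), c(0.7, 0.1)), score, group)$auc, 1.0)
  expect_equal(roc(scored(c(0.9, 0.2), c(0.8, 0.1)), score, group)$auc, 0.75)
  expect_error(roc(scored(c(1, 2), numeric(0)), score, group), "both classes")
})

test_that("trapezoid AUC equals the pairwise-concordance oracle", {
  withr::with_seed(61, {
    for (rep in 1:10) {
      pos <- round(rnorm(30), 1)  # rounding forces ties
      neg <- round(rnorm(25, -0.3), 1)
      r <- roc(scored(pos, neg), score, group)
      expect_equal(r$auc, auc_oracle(pos, neg), tolerance = 1e-12)
      # complement symmetry (tie-free version)
      pos2 <- rnorm(20); neg2 <- rnorm(20)
      a1 <- roc(scored(pos2, neg2), score, group)$auc
      a2 <- roc(scored(-neg2, -pos2), score, group)$auc
      expect_equal(a1 + (1 - a2), 1, tolerance = 1e-12)
    }
  })
})

test_that("ROC sweep is monotone in sensitivity and specificity", {
  withr::with_seed(62, {
    r <- roc(scored(rnorm(40, 1), rnorm(40)), score, group)
  })
  expect_true(all(diff(r$points$sensitivity) >= 0))
  expect_true(all(diff(r$points$specificity) <= 0))
  expect_true(all(r$points$sensitivity >= 0 & r$points$sensitivity <= 1))
})

test_that("AUC confidence intervals behave across methods and sample sizes", {
  withr::with_seed(63, {
    r <- roc(scored(rnorm(100, 0.8), rnorm(100)), score, group)
  })
  hm <- auc_ci(r, "hanley_mcneil")
  dl <- auc_ci(r, "delong")
  expect_lt(abs(hm$conf_low - dl$conf_low), 0.02)
  expect_lt(abs(hm$conf_high - dl$conf_high), 0.02)
  # symmetric null data: CI straddles 0.5 roughly symmetrically
  withr::with_seed(64, {
    r0 <- roc(scored(rnorm(300), rnorm(300)), score, group)
  })
  ci0 <- auc_ci(r0)
  expect_lt(abs((ci0$conf_high - r0$auc) - (r0$auc - ci0$conf_low)), 0.01)
  # widths shrink with n under a fixed generator
  widths <- purrr::map_dbl(c(50, 200, 800), function(n) {
    withr::with_seed(65, {
      r <- roc(scored(rnorm(n, 0.5), rnorm(n)), score, group)
    })
    ci <- auc_ci(r)
    ci$conf_high - ci$conf_low
  })
  expect_true(all(diff(widths) < 0))
})

test_that("Youden point maximizes J with ties broken toward specificity", {
  r <- roc(scored(c(5, 4), c(1, 0)), score, group)
  y <- youden_point(r)
  expect_equal(y$j, 1)
  expect_equal(y$sensitivity, 1)
  expect_equal(y$specificity, 1)
  # printed operating point arithmetic: J = 0.74 + 0.90 - 1
  expect_equal(0.74 + 0.90 - 1, 0.64)
  withr::with_seed(66, {
    for (rep in 1:10) {
      pos <- round(rnorm(20, 0.5), 1); neg <- round(rnorm(20), 1)
      r <- roc(scored(pos, neg), score, group)
      y <- youden_point(r)
      # exhaustive sweep oracle over candidate thresholds
      thr <- c(Inf, sort(unique(c(pos, neg)), decreasing = TRUE))
      j <- vapply(thr, function(t) mean(pos >= t) + mean(neg < t) - 1,
                  numeric(1))
      expect_equal(y$j, max(j), tolerance = 1e-12)
      best_spec <- max(vapply(thr[j >= max(j) - 1e-12],
                              function(t) mean(neg < t), numeric(1)))
      expect_equal(y$specificity, best_spec, tolerance = 1e-12)
    }
  })
})

test_that("AUC and its parts agree with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(67, {
    pos <- rnorm(50, 0.7); neg <- rnorm(60)
  })
  r <- roc(scored(pos, neg), score, group)
  pr <- pROC::roc(response = c(rep(1, 50), rep(0, 60)),
                  predictor = c(pos, neg), quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  dl <- auc_ci(r, "delong")
  pci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(c(dl$conf_low, dl$conf_high), pci[c(1, 3)], tolerance = 1e-6)
})

test_that("exact binomial intervals are Clopper-Pearson", {
  ci <- exact_binomial_ci(36, 40)
  expect_equal(round(ci$conf_low, 3), 0.763)
  expect_equal(round(ci$conf_high, 3), 0.972)
  ci2 <- exact_binomial_ci(108, 146)
  expect_equal(round(ci2$conf_low, 3), 0.661)
  expect_equal(exact_binomial_ci(10, 10)$conf_high, 1.0)
  expect_error(exact_binomial_ci(5, 4), "successes")
})

test_that("Spearman correlation handles monotone, reversed and exact cases", {
  d <- tibble::tibble(a = 1:6, b = c(2, 4, 5, 7, 10, 30))
  expect_equal(spearman_cor(d, a, b)$rho, 1.0)
  expect_equal(spearman_cor(dplyr::mutate(d, b = rev(b)), a, b)$rho, -1.0)
  expect_error(spearman_cor(dplyr::mutate(d, b = 1), a, b), "zero variance")
  # n = 5: p equals the exact permutation enumeration (120 permutations)
  withr::with_seed(68, {
    x <- rnorm(5); y <- rnorm(5)
  })
  res <- spearman_cor(tibble::tibble(x = x, y = y), x, y)
  perms <- matrix(unlist(combinat_perms(5)), ncol = 5, byrow = TRUE)
  rho_obs <- cor(rank(x), rank(y))
  rhos <- apply(perms, 1, function(o) cor(rank(x), rank(y)[o]))
  p_exact <- mean(abs(rhos) >= abs(rho_obs) - 1e-12)
  expect_equal(res$p_value, p_exact, tolerance = 1e-12)
})

test_that("planted effect size drives the LOO AUC upward", {
  aucs <- purrr::map_dbl(c(0.25, 1, 2), function(mult) {
    eff <- panel_effect_spec()
    eff$log_fold_change <- eff$log_fold_change * mult
    spec <- cohort_spec(n_fibrosis = 25, n_nofibrosis = 25, effects = eff,
                        n_null_peptides = 0, seed = 69)
    co <- generate_cohort(spec)
    g <- assign_groups(co$metadata)
    loo <- loo_scores(co$intensities, g, planted_truth(spec))
    roc(loo, score, group)$auc
  })
  expect_true(all(diff(aucs) > 0))
})
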