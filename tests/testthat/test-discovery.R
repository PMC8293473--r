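test_that("frequency filter keeps peptides at or above 30% in one group", {
  withr::with_seed(31, {
    vals <- matrix(0, 200, 3)
    vals[1:30, 1] <- 1          # 30/100 fibrosis, 0/100 nofibrosis: kept
    vals[c(1:29, 101:129), 2] <- 1  # 29/100 in both: removed
    vals[101:200, 3] <- rlnorm(100)  # 100% in nofibrosis: kept
    m <- tiny_matrix(vals, sample_ids = sprintf("S%03d", 1:200))
  })
  g <- tiny_groups(m$sample_id, rep(c("fibrosis", "nofibrosis"), each = 100))
  ff <- frequency_filter(m, g)
  expect_equal(ff$retained, c(TRUE, FALSE, TRUE))
  expect_equal(ff$freq_fibrosis, c(0.30, 0.29, 0))
})

test_that("retained set equals a brute-force recount of nonzero cells", {
  withr::with_seed(32, {
    m <- random_matrix(40, 25, zero_frac = 0.6)
    g <- tiny_groups(m$sample_id, sample(c("fibrosis", "nofibrosis"), 40, TRUE,
                                         prob = c(0.5, 0.5)))
  })
  ff <- frequency_filter(m, g, threshold = 0.3)
  for (j in seq_len(25)) {
    pep <- ff$peptide_id[j]
    f <- sum(m[[pep]][g$group == "fibrosis"] > 0) / sum(g$group == "fibrosis")
    n <- sum(m[[pep]][g$group == "nofibrosis"] > 0) / sum(g$group == "nofibrosis")
    expect_equal(ff$retained[j], f >= 0.3 || n >= 0.3)
  }
})

test_that("rank-sum p-values match exact enumeration for small samples", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(wilcoxon_rank_sum(c(2, 2, 2), c(2, 2)), 1.0)  # degenerate ties
  withr::with_seed(33, {
    for (rep in 1:20) {
      n1 <- sample(2:7, 1); n2 <- sample(2:7, 1)
      x <- sample(0:4, n1, TRUE)  # heavy ties incl. zeros
      y <- sample(0:4, n2, TRUE)
      if (length(unique(c(x, y))) == 1) next
      expect_equal(wilcoxon_rank_sum(x, y), wilcoxon_oracle(x, y))
    }
  })
})

test_that("large-sample rank-sum p agrees with the normal-approximation oracle", {
  withr::with_seed(34, {
    for (rep in 1:5) {
      x <- rlnorm(100, 5, 1) * rbinom(100, 1, 0.8)
      y <- rlnorm(100, 5.3, 1) * rbinom(100, 1, 0.8)
      ref <- wilcox.test(x, y, exact = FALSE, correct = FALSE)$p.value
      expect_equal(wilcoxon_rank_sum(x, y), ref, tolerance = 1e-6)
    }
  })
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  withr::with_seed(35, {
    for (rep in 1:10) {
      p <- runif(sample(c(5, 50, 1000), 1))
      expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
      # permutation equivariance: values follow their p
      o <- sample(length(p))
      expect_equal(bh_adjust(p[o]), bh_adjust(p)[o], tolerance = 1e-12)
    }
  })
})

test_that("adjusted p-values are monotone in the rank order of raw p", {
  withr::with_seed(36, {
    p <- runif(200)
    adj <- bh_adjust(p)
    expect_true(all(adj >= 0 & adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  })
})

test_that("discover reproduces panel fold changes from group means", {
  # two peptides whose group means are exactly the printed panel means
  n <- 4
  vals <- cbind(c(rep(1151.22, n), rep(272.13, n)),
                c(rep(610.19, n), rep(14067.56, n)))
  m <- tiny_matrix(vals, peptide_ids = c("up", "down"))
  g <- tiny_groups(m$sample_id, rep(c("fibrosis", "nofibrosis"), each = n))
  d <- discover(m, g, threshold = 0)
  expect_equal(round(d$fold_change[d$peptide_id == "up"], 3), 4.230)
  expect_equal(round(d$fold_change[d$peptide_id == "down"], 3), 0.043)
  expect_equal(d$direction, c("up", "down"))
})

test_that("discover is invariant to peptide column order", {
  withr::with_seed(37, {
    m <- random_matrix(30, 12, zero_frac = 0.3)
    g <- tiny_groups(m$sample_id, rep(c("fibrosis", "nofibrosis"), 15))
  })
  d1 <- discover(m, g)
  perm <- c(1, 1 + sample(12))
  d2 <- discover(m[, perm], g)
  expect_equal(dplyr::arrange(d1, peptide_id),
               dplyr::arrange(d2, peptide_id))
})

test_that("BH is applied to the frequency-retained family only", {
  withr::with_seed(38, {
    m <- random_matrix(40, 30, zero_frac = 0.75)
    g <- tiny_groups(m$sample_id, rep(c("fibrosis", "nofibrosis"), each = 20))
  })
  d <- discover(m, g, threshold = 0.5)
  expect_true(any(!d$retained))
  expect_true(all(is.na(d$p_adj[!d$retained])))
  keep <- d$retained
  expect_equal(d$p_adj[keep], bh_oracle(d$p_raw[keep]), tolerance = 1e-12)
})

test_that("on all-null cohorts the selected fraction stays within FDR control", {
  eff <- tibble::tibble(peptide_id = character(), detect_prob_fibrosis = numeric(),
                        detect_prob_nofibrosis = numeric(),
                        log_fold_change = numeric(), base_log_mean = numeric(),
                        base_log_sd = numeric())
  frac <- purrr::map_dbl(1:40, function(s) {
    co <- generate_cohort(cohort_spec(n_fibrosis = 25, n_nofibrosis = 25,
                                      effects = eff, n_null_peptides = 60,
                                      n_standards = 0, seed = 1000 + s))
    g <- assign_groups(co$metadata)
    d <- discover(co$intensities, g)
    mean(d$selected[d$retained])
  })
  expect_lte(mean(frac), 0.05)
})
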