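#' Empirical ROC analysis of classifier scores
#'
#' Sweeps every distinct score as a decision threshold (predict positive
#' when `score >= threshold`), records the sensitivity/specificity pair at
#' each, and computes the area under the curve by the trapezoid rule. With
#' ties counted one half, the trapezoid AUC equals the Mann-Whitney
#' concordance statistic `U / (n_pos * n_neg)`.
#'
#' @param data Data frame of scored samples.
#' @param score Column holding the numeric score (bare name or string).
#' @param truth Column holding the class label.
#' @param positive Label of the positive (fibrosis) class.
#' @return A `roc_result` with `points` (threshold, sensitivity,
#'   specificity), `auc`, and class counts.
#' @export
roc <- function(data, score, truth, positive = "fibrosis") {
  s <- dplyr::pull(data, {{ score }})
  g <- as.character(dplyr::pull(data, {{ truth }}))
  keep <- !is.na(s) & !is.na(g)
  s <- s[keep]; g <- g[keep]
  pos <- g == positive
  if (!any(pos) || all(pos)) abort("both classes must be present")
  thr <- c(Inf, sort(unique(s), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(s[pos] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(s[!pos] < t), numeric(1))
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (head(sens, -1) + sens[-1]) / 2)
  structure(list(points = tibble::tibble(threshold = thr, sensitivity = sens,
                                         specificity = spec),
                 auc = auc, n_pos = sum(pos), n_neg = sum(!pos),
                 positive = positive,
                 scores_pos = s[pos], scores_neg = s[!pos]),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  ci <- auc_ci(x)
  cat("ROC: AUC = ", sprintf("%.3f", x$auc),
      " (95% CI ", sprintf("%.3f", ci$conf_low), "-",
      sprintf("%.3f", ci$conf_high), ", Hanley-McNeil); n_pos = ", x$n_pos,
      ", n_neg = ", x$n_neg, "\n", sep = "")
  y <- youden_point(x)
  cat("Youden point: threshold ", signif(y$threshold, 4), ", sensitivity ",
      sprintf("%.3f", y$sensitivity), ", specificity ",
      sprintf("%.3f", y$specificity), "\n", sep = "")
  invisible(x)
}

#' Confidence interval for the area under the ROC curve
#'
#' `"hanley_mcneil"` (default) uses the Hanley-McNeil variance formula for
#' the Mann-Whitney AUC; `"delong"` uses the DeLong placement-value
#' variance. Both give Wald intervals clipped to \[0, 1\].
#'
#' @param r A `roc_result`.
#' @param method `"hanley_mcneil"` or `"delong"`.
#' @param level Confidence level.
#' @return One-row tibble with `auc`, `conf_low`, `conf_high`, `method`.
#' @export
auc_ci <- function(r, method = c("hanley_mcneil", "delong"), level = 0.95) {
  stopifnot(inherits(r, "roc_result"))
  method <- match.arg(method)
  if (r$n_pos < 2 || r$n_neg < 2) abort("need at least 2 samples per class")
  a <- r$auc
  if (method == "hanley_mcneil") {
    q1 <- a / (2 - a)
    q2 <- 2 * a^2 / (1 + a)
    se <- sqrt((a * (1 - a) + (r$n_pos - 1) * (q1 - a^2) +
                  (r$n_neg - 1) * (q2 - a^2)) / (r$n_pos * r$n_neg))
  } else {
    psi <- function(xi, yj) (xi > yj) + 0.5 * (xi == yj)
    v10 <- vapply(r$scores_pos, function(xi) mean(psi(xi, r$scores_neg)),
                  numeric(1))
    v01 <- vapply(r$scores_neg, function(yj) mean(psi(r$scores_pos, yj)),
                  numeric(1))
    se <- sqrt(var(v10) / r$n_pos + var(v01) / r$n_neg)
  }
  if ((a == 0 || a == 1) && se == 0) {
    warn("degenerate AUC with zero variance estimate; interval clipped")
  }
  z <- qnorm(1 - (1 - level) / 2)
  tibble::tibble(auc = a, conf_low = max(0, a - z * se),
                 conf_high = min(1, a + z * se), method = method,
                 level = level)
}

#' Youden-index operating point
#'
#' Returns the threshold maximizing `J = sensitivity + specificity - 1`
#' along the ROC sweep. Ties in J are broken toward the higher-specificity
#' point.
#'
#' @param r A `roc_result`.
#' @return One-row tibble with `threshold`, `sensitivity`, `specificity`,
#'   `j`.
#' @export
youden_point <- function(r) {
  stopifnot(inherits(r, "roc_result"))
  pts <- dplyr::mutate(r$points, j = .data$sensitivity + .data$specificity - 1)
  pts <- dplyr::arrange(pts, dplyr::desc(.data$j), dplyr::desc(.data$specificity))
  pts[1, c("threshold", "sensitivity", "specificity", "j")]
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' @param successes,trials Non-negative counts with
#'   `0 <= successes <= trials`, `trials >= 1`.
#' @param level Confidence level.
#' @return One-row tibble with `estimate`, `conf_low`, `conf_high`.
#' @export
exact_binomial_ci <- function(successes, trials, level = 0.95) {
  if (length(successes) != 1 || length(trials) != 1 ||
      is.na(successes) || is.na(trials) ||
      successes < 0 || trials < 1 || successes > trials ||
      successes != round(successes) || trials != round(trials)) {
    abort("need integer counts with 0 <= successes <= trials, trials >= 1")
  }
  ci <- binom.test(successes, trials, conf.level = level)$conf.int
  tibble::tibble(estimate = successes / trials, conf_low = ci[1],
                 conf_high = ci[2], level = level)
}

#' Spearman rank correlation of scores with a continuous grade
#'
#' Rho is computed on mid-ranks. The p-value uses the exact permutation
#' distribution for n of at most 9 without ties, and the t-approximation
#' otherwise.
#'
#' @param data Data frame.
#' @param x,y Columns to correlate (bare names or strings).
#' @return One-row tibble with `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(data, x, y) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  keep <- !is.na(xv) & !is.na(yv)
  xv <- xv[keep]; yv <- yv[keep]
  n <- length(xv)
  if (n < 3) abort("need at least 3 paired observations")
  if (sd(xv) == 0 || sd(yv) == 0) abort("zero variance in one of the vectors")
  ties <- anyDuplicated(xv) > 0 || anyDuplicated(yv) > 0
  exact <- n <= 9 && !ties
  ct <- suppressWarnings(cor.test(xv, yv, method = "spearman", exact = exact))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = n)
}

#' @exportS3Method generics::tidy
tidy.roc_result <- function(x, ...) x$points

#' @exportS3Method generics::glance
glance.roc_result <- function(x, ...) {
  ci <- auc_ci(x)
  yp <- youden_point(x)
  tibble::tibble(auc = x$auc, auc_conf_low = ci$conf_low,
                 auc_conf_high = ci$conf_high,
                 youden_threshold = yp$threshold,
                 sens_at_youden = yp$sensitivity,
                 spec_at_youden = yp$specificity,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @exportS3Method ggplot2::autoplot
autoplot.roc_result <- function(object, ...) {
  pts <- object$points
  lab <- sprintf("AUC = %.3f", object$auc)
  ggplot2::ggplot(pts, ggplot2::aes(x = 1 - .data$specificity,
                                    y = .data$sensitivity)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3,
                         colour = "grey50") +
    ggplot2::annotate("text", x = 0.75, y = 0.1, label = lab) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity") +
    ggplot2::theme_minimal()
}

#' Scatter plot of classifier scores against IFTA percentage
#'
#' @param scores Tibble with `sample_id` and `score` (e.g. from
#'   [apply_panel()] or [loo_scores()]).
#' @param metadata Sample metadata with `sample_id` and `ifta_percent`.
#' @return A ggplot object annotated with the Spearman rho.
#' @export
plot_score_ifta <- function(scores, metadata) {
  d <- dplyr::inner_join(scores, metadata, by = "sample_id")
  sc <- spearman_cor(d, "ifta_percent", "score")
  lab <- sprintf("Spearman rho = %.3f (n = %d)", sc$rho, sc$n)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ifta_percent, y = .data$score)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey40", linetype = 2) +
    ggplot2::annotate("text", x = -Inf, y = Inf, hjust = -0.05, vjust = 1.5,
                      label = lab) +
    ggplot2::labs(x = "IFTA (%)", y = "classifier score") +
    ggplot2::theme_minimal()
}
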