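group_labels <- function(m, groups) {
  groups <- tibble::as_tibble(groups)
  if (!all(c("sample_id", "group") %in% names(groups))) {
    abort("groups must have 'sample_id' and 'group' columns")
  }
  groups <- dplyr::filter(groups, .data$group %in% c("fibrosis", "nofibrosis"))
  groups <- dplyr::filter(groups, .data$sample_id %in% m$sample_id)
  if (!any(groups$group == "fibrosis") || !any(groups$group == "nofibrosis")) {
    abort("both groups must be non-empty")
  }
  groups
}

#' Detection-frequency filter
#'
#' A peptide enters statistical testing only if it is detected (intensity
#' strictly positive) in at least `threshold` of the samples of at least one
#' group; rarely seen peptides carry too little rank information to test.
#'
#' @param m Intensity matrix tibble.
#' @param groups Data frame with `sample_id` and `group`
#'   (`fibrosis`/`nofibrosis`; other levels are ignored).
#' @param threshold Minimum detection fraction (default 0.30); the
#'   comparison is `>=` ("at least").
#' @return Tibble with `peptide_id`, `freq_fibrosis`, `freq_nofibrosis`,
#'   `retained`.
#' @export
frequency_filter <- function(m, groups, threshold = 0.30) {
  m <- validate_intensity_matrix(m)
  groups <- group_labels(m, groups)
  fib_ids <- groups$sample_id[groups$group == "fibrosis"]
  nof_ids <- groups$sample_id[groups$group == "nofibrosis"]
  vf <- as.matrix(m[match(fib_ids, m$sample_id), -1, drop = FALSE])
  vn <- as.matrix(m[match(nof_ids, m$sample_id), -1, drop = FALSE])
  ff <- colMeans(vf > 0)
  fn <- colMeans(vn > 0)
  tibble::tibble(peptide_id = peptide_ids(m), freq_fibrosis = unname(ff),
                 freq_nofibrosis = unname(fn),
                 retained = unname(ff >= threshold | fn >= threshold))
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Mid-ranks are used throughout; zeros (not-detected) take part as ordinary
#' tied values. For small samples (both groups at most `exact_limit`) the
#' p-value is computed by exact enumeration of all assignments of the
#' observed ranks to the first group; above that, a normal approximation
#' with tie correction (no continuity correction) is used. If every value in
#' both groups is identical the comparison is degenerate and p = 1.
#'
#' @param x,y Numeric intensity vectors of the two groups.
#' @param exact_limit Largest per-group size for exact enumeration.
#' @return Two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y, exact_limit = 8) {
  if (!length(x) || !length(y)) abort("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  v <- c(x, y)
  if (length(unique(v)) == 1L) return(1)
  r <- rank(v)
  w <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  if (n1 <= exact_limit && n2 <= exact_limit) {
    idx <- combn(n, n1)
    sums <- colSums(matrix(r[idx], nrow = n1))
    p <- mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (w - mu) / sqrt(sigma2)
    p <- 2 * pnorm(-abs(z))
  }
  min(p, 1)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up false-discovery-rate adjustment: with p-values sorted
#' ascending, `p_adj(i) = min over j >= i of p(j) * m / j`, capped at 1, and
#' returned in the input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Frequency-filtered rank-based differential abundance testing
#'
#' The discovery pipeline: detection-frequency filter, per-peptide two-sided
#' Wilcoxon rank-sum test on the retained peptides (zeros included as
#' values), Benjamini-Hochberg adjustment over the retained family only, and
#' group-mean fold changes. By default group means include non-detected
#' zeros, so the fold change reflects abundance and detection-rate
#' differences jointly; `means = "detected"` restricts means to detected
#' samples.
#'
#' @param m Normalized intensity matrix tibble.
#' @param groups Data frame with `sample_id`, `group`.
#' @param threshold Detection-frequency threshold, see [frequency_filter()].
#' @param alpha Adjusted-p significance cut-off for `selected`.
#' @param exact_limit Passed to [wilcoxon_rank_sum()].
#' @param means `"all"` (zeros included, default) or `"detected"`.
#' @return Tibble of per-peptide results: detection frequencies, group
#'   means, `fold_change` (fibrosis / no fibrosis), `p_raw`, `p_adj`
#'   (`NA` for filtered-out peptides), `direction` and `selected`.
#' @export
discover <- function(m, groups, threshold = 0.30, alpha = 0.05,
                     exact_limit = 8, means = c("all", "detected")) {
  means <- match.arg(means)
  m <- validate_intensity_matrix(m)
  groups <- group_labels(m, groups)
  fib_ids <- groups$sample_id[groups$group == "fibrosis"]
  nof_ids <- groups$sample_id[groups$group == "nofibrosis"]
  vf <- as.matrix(m[match(fib_ids, m$sample_id), -1, drop = FALSE])
  vn <- as.matrix(m[match(nof_ids, m$sample_id), -1, drop = FALSE])
  res <- frequency_filter(m, groups, threshold)
  if (means == "all") {
    mf <- colMeans(vf); mn <- colMeans(vn)
  } else {
    mf <- apply(vf, 2, function(v) if (any(v > 0)) mean(v[v > 0]) else 0)
    mn <- apply(vn, 2, function(v) if (any(v > 0)) mean(v[v > 0]) else 0)
  }
  fc <- ifelse(mn > 0, mf / mn, NA_real_)
  p_raw <- rep(NA_real_, nrow(res))
  keep <- which(res$retained)
  for (j in keep) {
    p_raw[j] <- wilcoxon_rank_sum(vf[, j], vn[, j], exact_limit = exact_limit)
  }
  p_adj <- rep(NA_real_, nrow(res))
  p_adj[keep] <- bh_adjust(p_raw[keep])
  dplyr::mutate(res,
                mean_fibrosis = unname(mf),
                mean_nofibrosis = unname(mn),
                fold_change = unname(fc),
                p_raw = p_raw,
                p_adj = p_adj,
                direction = dplyr::case_when(
                  is.na(fc) | fc == 1 ~ "none",
                  fc > 1 ~ "up",
                  TRUE ~ "down"),
                selected = !is.na(p_adj) & p_adj < alpha)
}

#' Volcano-style plot of discovery results
#'
#' @param biomarkers Result of [discover()].
#' @param alpha Significance line on the adjusted-p axis.
#' @return A ggplot object.
#' @export
plot_volcano <- function(biomarkers, alpha = 0.05) {
  d <- dplyr::filter(biomarkers, !is.na(.data$p_adj), !is.na(.data$fold_change),
                     .data$fold_change > 0)
  ggplot2::ggplot(d, ggplot2::aes(x = log2(.data$fold_change),
                                  y = -log10(.data$p_adj),
                                  colour = .data$selected)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::labs(x = "log2 fold change (fibrosis / no fibrosis)",
                  y = "-log10 adjusted p", colour = "selected") +
    ggplot2::theme_minimal()
}
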