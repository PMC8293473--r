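# Shared fixture builders. Everything is generated in code at test time.

tiny_matrix <- function(values, sample_ids = NULL, peptide_ids = NULL) {
  values <- as.matrix(values)
  sample_ids <- sample_ids %||% sprintf("S%02d", seq_len(nrow(values)))
  peptide_ids <- peptide_ids %||% sprintf("P%02d", seq_len(ncol(values)))
  colnames(values) <- peptide_ids
  dplyr::bind_cols(tibble::tibble(sample_id = sample_ids),
                   tibble::as_tibble(values))
}

tiny_groups <- function(sample_ids, groups) {
  tibble::tibble(sample_id = sample_ids, group = groups)
}

random_matrix <- function(n_samples, n_peptides, zero_frac = 0.2) {
  vals <- matrix(rlnorm(n_samples * n_peptides, 5, 1), n_samples)
  vals[runif(length(vals)) < zero_frac] <- 0
  tiny_matrix(vals)
}

# Independent step-up BH oracle (vector arithmetic, no p.adjust)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 1
  for (i in rev(seq_len(m))) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- running
  }
  adj
}

# Exact two-sided rank-sum oracle by enumeration of group assignments
wilcoxon_oracle <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  mu <- n1 * (length(r) + 1) / 2
  obs <- sum(r[seq_len(n1)])
  sums <- colSums(matrix(r[utils::combn(length(r), n1)], nrow = n1))
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

# Pairwise-concordance AUC oracle
auc_oracle <- function(pos, neg) {
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}

# All permutations of 1..n (recursive; used only at tiny n)
combinat_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- combinat_perms(n - 1)
  out <- list()
  for (p in sub) {
    for (k in 0:(n - 1)) {
      out[[length(out) + 1]] <- append(p, n, after = k)
    }
  }
  out
}

small_cohort_spec <- function(seed = 1, n = 30, ...) {
  cohort_spec(n_fibrosis = n, n_nofibrosis = n, seed = seed, ...)
}
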