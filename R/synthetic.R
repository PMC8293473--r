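#' Covariate model linking IFTA to clinical parameters
#'
#' In biopsied CKD cohorts the degree of interstitial fibrosis correlates
#' moderately with kidney function and demographics: eGFR falls with IFTA,
#' 24-h proteinuria and age rise with it. The generator draws each covariate
#' as a monotone linear (log-linear for proteinuria) function of the sample's
#' IFTA percentage plus Gaussian noise, which yields moderate Spearman
#' correlations (|rho| roughly 0.3-0.7 at the defaults) of the kind seen in
#' real biopsy series.
#'
#' @param egfr_intercept,egfr_slope,egfr_sd eGFR at IFTA 0, change per IFTA
#'   percent (negative), and noise SD, all in mL/min/1.73 m2.
#' @param log_proteinuria_intercept,log_proteinuria_slope,log_proteinuria_sd
#'   Natural-log scale intercept/slope/noise for proteinuria in mg/24 h.
#' @param age_intercept,age_slope,age_sd Years.
#' @param male_prob Probability that a sample is male.
#' @return A `covariate_model` list.
#' @export
covariate_model <- function(egfr_intercept = 75, egfr_slope = -0.6, egfr_sd = 15,
                            log_proteinuria_intercept = 7.4,
                            log_proteinuria_slope = 0.02,
                            log_proteinuria_sd = 0.7,
                            age_intercept = 48, age_slope = 0.25, age_sd = 11,
                            male_prob = 0.55) {
  structure(list(egfr_intercept = egfr_intercept, egfr_slope = egfr_slope,
                 egfr_sd = egfr_sd,
                 log_proteinuria_intercept = log_proteinuria_intercept,
                 log_proteinuria_slope = log_proteinuria_slope,
                 log_proteinuria_sd = log_proteinuria_sd,
                 age_intercept = age_intercept, age_slope = age_slope,
                 age_sd = age_sd, male_prob = male_prob),
            class = "covariate_model")
}

#' Effect specification table for planted biomarkers
#'
#' Builds the per-peptide effect table the cohort generator consumes from a
#' peptide panel carrying fold changes and no-fibrosis group means. Each
#' peptide's intensity is zero-inflated log-normal:
#' `Bernoulli(detect_prob) * LogNormal(base_log_mean + log_fold_change * 1[fibrosis], base_log_sd)`.
#'
#' Abundance shifts in CE-MS data express themselves jointly as intensity
#' shifts among detected samples and as detection-rate shifts, so the total
#' planted fold change `R` (the printed group-mean ratio, zeros included) is
#' split between the two channels: detection probabilities move apart on the
#' logit scale by `2 * detect_coupling * log(R)` and the residual
#' `log(R) - log(detect_ratio)` is planted as the intensity shift. With that
#' split the empirical zero-inclusive group-mean ratio converges to `R`.
#'
#' @param panel Peptide panel tibble with `peptide_id`, `fold_change` and
#'   `mean_nofibrosis` columns; defaults to [fpp_bh29_panel()].
#' @param base_detect Baseline detection probability at fold change 1.
#' @param detect_coupling Logit-scale coupling of detection to `log(R)`.
#' @param base_log_sd Log-scale SD of detected intensities.
#' @return Tibble with columns `peptide_id`, `detect_prob_fibrosis`,
#'   `detect_prob_nofibrosis`, `log_fold_change`, `base_log_mean`,
#'   `base_log_sd`.
#' @export
panel_effect_spec <- function(panel = fpp_bh29_panel(), base_detect = 0.85,
                              detect_coupling = 0.25, base_log_sd = 0.5) {
  stopifnot(all(c("peptide_id", "fold_change", "mean_nofibrosis") %in% names(panel)))
  lr <- log(panel$fold_change)
  p_f <- plogis(qlogis(base_detect) + detect_coupling * lr)
  p_nf <- plogis(qlogis(base_detect) - detect_coupling * lr)
  lfc <- lr - log(p_f / p_nf)
  tibble::tibble(
    peptide_id = panel$peptide_id,
    detect_prob_fibrosis = p_f,
    detect_prob_nofibrosis = p_nf,
    log_fold_change = lfc,
    # zero-inclusive no-fibrosis group mean matches the panel's printed mean
    base_log_mean = log(panel$mean_nofibrosis / p_nf) - base_log_sd^2 / 2,
    base_log_sd = base_log_sd
  )
}

validate_effects <- function(effects) {
  effects <- tibble::as_tibble(effects)
  need <- c("peptide_id", "detect_prob_fibrosis", "detect_prob_nofibrosis",
            "log_fold_change", "base_log_mean", "base_log_sd")
  miss <- setdiff(need, names(effects))
  if (length(miss)) abort(paste0("effects missing columns: ", paste(miss, collapse = ", ")))
  if (any(effects$detect_prob_fibrosis < 0 | effects$detect_prob_fibrosis > 1 |
          effects$detect_prob_nofibrosis < 0 | effects$detect_prob_nofibrosis > 1)) {
    abort("detection probabilities must lie in [0, 1]")
  }
  if (any(effects$base_log_sd <= 0)) abort("base_log_sd must be > 0")
  if (anyDuplicated(effects$peptide_id)) abort("duplicate peptide_id in effects")
  effects
}

#' Specification of a synthetic CE-MS cohort
#'
#' Describes a cohort with the structure the analysis assumes: a fibrosis
#' group (IFTA drawn uniformly on \[15, 60\]), a no-fibrosis group (IFTA on
#' \[0, 10)), optional intermediate samples (IFTA on \[10, 15), excluded from
#' discovery), planted biomarker effects, inert null peptides, internal
#' standard peptides with no group effect, and clinical covariates generated
#' from IFTA. One seed fixes all randomness.
#'
#' @param n_fibrosis,n_nofibrosis,n_intermediate Sample counts (the default
#'   100/100 mirrors the training design).
#' @param effects Effect table, see [panel_effect_spec()].
#' @param n_null_peptides Number of no-effect peptides.
#' @param null_detect_prob Detection probability of null peptides.
#' @param n_standards Number of internal standard peptides (ids `IS_01`, ...).
#' @param standard_log_mean,standard_log_sd Log-normal parameters of the
#'   standards (always detected, no group effect).
#' @param sample_scale_log_sd Log-SD of a per-sample global intensity factor
#'   (urine concentration / injection variability) that internal-standard
#'   normalization is meant to remove.
#' @param covariates A [covariate_model()].
#' @param seed Integer seed fixing all draws.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_fibrosis = 100, n_nofibrosis = 100,
                        n_intermediate = 0, effects = panel_effect_spec(),
                        n_null_peptides = 300, null_detect_prob = 0.6,
                        n_standards = 29, standard_log_mean = log(1000),
                        standard_log_sd = 0.2, sample_scale_log_sd = 0.15,
                        covariates = covariate_model(), seed = 1L) {
  if (n_fibrosis < 0 || n_nofibrosis < 0 || n_intermediate < 0 ||
      n_null_peptides < 0 || n_standards < 0) {
    abort("counts must be >= 0")
  }
  structure(list(n_fibrosis = as.integer(n_fibrosis),
                 n_nofibrosis = as.integer(n_nofibrosis),
                 n_intermediate = as.integer(n_intermediate),
                 effects = validate_effects(effects),
                 n_null_peptides = as.integer(n_null_peptides),
                 null_detect_prob = null_detect_prob,
                 n_standards = as.integer(n_standards),
                 standard_log_mean = standard_log_mean,
                 standard_log_sd = standard_log_sd,
                 sample_scale_log_sd = sample_scale_log_sd,
                 covariates = covariates,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic CE-MS cohort
#'
#' Draws sample metadata and a sample-by-peptide intensity matrix according
#' to a [cohort_spec()]. Identical specs (including the seed) produce
#' identical output.
#'
#' @param spec A [cohort_spec()].
#' @return A list with elements `intensities` (intensity matrix tibble),
#'   `metadata` (sample metadata tibble), `standards` (character vector of
#'   internal-standard peptide ids) and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(spec$seed, generate_cohort_impl(spec))
}

generate_cohort_impl <- function(spec) {
  n <- spec$n_fibrosis + spec$n_nofibrosis + spec$n_intermediate
  if (n == 0) abort("cohort has no samples")
  sample_id <- sprintf("S%04d", seq_len(n))
  group <- rep(c("fibrosis", "nofibrosis", "intermediate"),
               times = c(spec$n_fibrosis, spec$n_nofibrosis, spec$n_intermediate))
  ifta <- numeric(n)
  ifta[group == "fibrosis"] <- runif(spec$n_fibrosis, 15, 60)
  ifta[group == "nofibrosis"] <- runif(spec$n_nofibrosis, 0, 10 - 1e-9)
  ifta[group == "intermediate"] <- runif(spec$n_intermediate, 10, 15 - 1e-9)

  cm <- spec$covariates
  egfr <- pmax(5, cm$egfr_intercept + cm$egfr_slope * ifta + rnorm(n, 0, cm$egfr_sd))
  proteinuria <- exp(cm$log_proteinuria_intercept +
                       cm$log_proteinuria_slope * ifta +
                       rnorm(n, 0, cm$log_proteinuria_sd))
  age <- pmin(92, pmax(18, cm$age_intercept + cm$age_slope * ifta +
                         rnorm(n, 0, cm$age_sd)))
  sex <- ifelse(runif(n) < cm$male_prob, "M", "F")
  etiology <- sample(c("IGANP", "HINP", "DNP", "MEMGN", "VASC", "INTN"),
                     n, replace = TRUE,
                     prob = c(0.25, 0.25, 0.12, 0.12, 0.14, 0.12))
  metadata <- tibble::tibble(sample_id = sample_id, ifta_percent = ifta,
                             egfr = egfr, proteinuria = proteinuria,
                             age = age, sex = sex, etiology = etiology,
                             cohort = "training")

  eff <- spec$effects
  if (spec$n_null_peptides > 0) {
    null_eff <- tibble::tibble(
      peptide_id = sprintf("NULL_%03d", seq_len(spec$n_null_peptides)),
      detect_prob_fibrosis = spec$null_detect_prob,
      detect_prob_nofibrosis = spec$null_detect_prob,
      log_fold_change = 0,
      base_log_mean = runif(spec$n_null_peptides, log(50), log(20000)),
      base_log_sd = if (nrow(eff)) median(eff$base_log_sd) else 0.5
    )
    eff <- dplyr::bind_rows(eff, null_eff)
  }
  standards <- character(0)
  if (spec$n_standards > 0) {
    standards <- sprintf("IS_%02d", seq_len(spec$n_standards))
    std_eff <- tibble::tibble(
      peptide_id = standards,
      detect_prob_fibrosis = 1, detect_prob_nofibrosis = 1,
      log_fold_change = 0,
      base_log_mean = spec$standard_log_mean,
      base_log_sd = spec$standard_log_sd
    )
    eff <- dplyr::bind_rows(eff, std_eff)
  }
  is_fib <- as.numeric(group == "fibrosis")
  scale_factor <- exp(rnorm(n, 0, spec$sample_scale_log_sd))
  p <- nrow(eff)
  vals <- matrix(0, nrow = n, ncol = p, dimnames = list(NULL, eff$peptide_id))
  for (j in seq_len(p)) {
    dp <- ifelse(is_fib == 1, eff$detect_prob_fibrosis[j],
                 eff$detect_prob_nofibrosis[j])
    detected <- rbinom(n, 1, dp)
    mu <- eff$base_log_mean[j] + eff$log_fold_change[j] * is_fib
    vals[, j] <- detected * rlnorm(n, mu, eff$base_log_sd[j]) * scale_factor
  }
  intensities <- dplyr::bind_cols(tibble::tibble(sample_id = sample_id),
                                  tibble::as_tibble(vals))
  list(intensities = validate_intensity_matrix(intensities),
       metadata = metadata, standards = standards, spec = spec)
}

#' Peptides with a planted group effect
#'
#' Returns exactly those peptide ids in the spec's effect table whose
#' log fold change is nonzero or whose detection probabilities differ
#' between groups: the recovery oracle for discovery.
#'
#' @param spec A [cohort_spec()].
#' @return Character vector of peptide ids.
#' @export
planted_truth <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  eff <- spec$effects
  eff$peptide_id[eff$log_fold_change != 0 |
                   eff$detect_prob_fibrosis != eff$detect_prob_nofibrosis]
}
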