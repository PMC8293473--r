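#' IFTA-based group rule
#'
#' Samples are graded by the percentage of fibrotic interstitial area on
#' biopsy: at or above `fibrosis_min` percent they form the fibrosis group,
#' strictly below `nofibrosis_max` the no-fibrosis group, and the band in
#' between is excluded so that early borderline fibrosis does not dilute
#' either group.
#'
#' @param fibrosis_min Lower IFTA bound (inclusive) of the fibrosis group.
#' @param nofibrosis_max Upper IFTA bound (exclusive) of the no-fibrosis
#'   group.
#' @return A `group_rule` list.
#' @export
group_rule <- function(fibrosis_min = 15, nofibrosis_max = 10) {
  if (!(0 <= nofibrosis_max && nofibrosis_max <= fibrosis_min &&
        fibrosis_min <= 100)) {
    abort("need 0 <= nofibrosis_max <= fibrosis_min <= 100")
  }
  structure(list(fibrosis_min = fibrosis_min, nofibrosis_max = nofibrosis_max),
            class = "group_rule")
}

#' Assign fibrosis / no-fibrosis / excluded groups from IFTA
#'
#' @param meta Sample metadata tibble with an `ifta_percent` column.
#' @param rule A [group_rule()].
#' @return `meta` with an added factor column `group` with levels
#'   `fibrosis`, `nofibrosis`, `excluded`.
#' @export
assign_groups <- function(meta, rule = group_rule()) {
  meta <- tibble::as_tibble(meta)
  if (!"ifta_percent" %in% names(meta)) abort("metadata lacks ifta_percent")
  if (any(is.na(meta$ifta_percent))) abort("missing ifta_percent")
  stopifnot(inherits(rule, "group_rule"))
  g <- ifelse(meta$ifta_percent >= rule$fibrosis_min, "fibrosis",
              ifelse(meta$ifta_percent < rule$nofibrosis_max,
                     "nofibrosis", "excluded"))
  dplyr::mutate(meta, group = factor(g, levels = c("fibrosis", "nofibrosis",
                                                   "excluded")))
}

standardize_covariates <- function(meta, covariates, log_transform) {
  x <- meta[, covariates, drop = FALSE]
  for (v in intersect(log_transform, covariates)) x[[v]] <- log(x[[v]])
  for (v in covariates) {
    s <- sd(x[[v]])
    x[[v]] <- (x[[v]] - mean(x[[v]])) / (if (is.na(s) || s == 0) 1 else s)
  }
  as.matrix(x)
}

#' Nearest-neighbor covariate matching of fibrosis and no-fibrosis samples
#'
#' Builds a 1:1 matched sub-cohort by greedy nearest-neighbor matching
#' without replacement on standardized Euclidean distance over the
#' continuous covariates (proteinuria log-transformed first), with sex as an
#' exact-match constraint whenever a same-sex control remains (otherwise the
#' constraint is relaxed with a warning). Fibrosis samples are processed in
#' ascending `sample_id`; distance ties go to the control with the lower
#' `sample_id`, so the procedure is invariant to input row order.
#'
#' @param meta Metadata tibble with a `group` column (see [assign_groups()]).
#' @param covariates Continuous covariates used in the distance.
#' @param exact Covariates matched exactly (default `"sex"`; add
#'   `"etiology"` for an etiology-matched sub-cohort). `NULL` for none.
#' @param k Number of pairs; default the size of the smaller group.
#' @param log_transform Covariates log-transformed before standardization.
#' @return A `match_result` with `pairs` (tibble of matched ids and
#'   distances) and `balance` (per-covariate two-group p-values after
#'   matching: Wilcoxon for continuous covariates, Fisher exact for the
#'   exact-match factors).
#' @export
nearest_neighbor_match <- function(meta,
                                   covariates = c("egfr", "proteinuria", "age"),
                                   exact = "sex", k = NULL,
                                   log_transform = "proteinuria") {
  meta <- tibble::as_tibble(meta)
  if (!"group" %in% names(meta)) abort("run assign_groups() first: metadata lacks 'group'")
  miss <- setdiff(c(covariates, exact), names(meta))
  if (length(miss)) abort(paste0("metadata lacks covariates: ", paste(miss, collapse = ", ")))
  fib <- dplyr::filter(meta, .data$group == "fibrosis") |>
    dplyr::arrange(.data$sample_id)
  ctl <- dplyr::filter(meta, .data$group == "nofibrosis") |>
    dplyr::arrange(.data$sample_id)
  k <- k %||% min(nrow(fib), nrow(ctl))
  if (nrow(fib) < k || nrow(ctl) < k) {
    lim <- if (nrow(fib) < nrow(ctl)) "fibrosis" else "nofibrosis"
    abort(paste0("cannot form ", k, " pairs: ", lim, " group has only ",
                 min(nrow(fib), nrow(ctl)), " samples"))
  }
  pool <- dplyr::bind_rows(fib, ctl)
  z <- standardize_covariates(pool, covariates, log_transform)
  zf <- z[seq_len(nrow(fib)), , drop = FALSE]
  zc <- z[nrow(fib) + seq_len(nrow(ctl)), , drop = FALSE]
  # squared Euclidean distances fibrosis x control
  d2 <- outer(rowSums(zf^2), rowSums(zc^2), "+") - 2 * zf %*% t(zc)
  exact_keys <- if (length(exact)) {
    do.call(paste, c(lapply(exact, function(v) as.character(pool[[v]])),
                     sep = "\r"))
  } else NULL
  avail <- rep(TRUE, nrow(ctl))
  pairs <- vector("list", k)
  relaxed <- 0L
  n_pairs <- 0L
  for (i in seq_len(nrow(fib))) {
    if (n_pairs == k) break
    cand <- which(avail)
    if (!length(cand)) break
    if (!is.null(exact_keys)) {
      same <- cand[exact_keys[nrow(fib) + cand] == exact_keys[i]]
      if (length(same)) cand <- same else relaxed <- relaxed + 1L
    }
    di <- d2[i, cand]
    best <- cand[di <= min(di) + 1e-12]
    j <- best[order(ctl$sample_id[best])][1]  # tie-break: lower control id
    n_pairs <- n_pairs + 1L
    pairs[[n_pairs]] <- tibble::tibble(fibrosis_id = fib$sample_id[i],
                                       nofibrosis_id = ctl$sample_id[j],
                                       distance = sqrt(max(d2[i, j], 0)))
    avail[j] <- FALSE
  }
  if (n_pairs < k) abort("matching exhausted controls before reaching k pairs")
  if (relaxed > 0) {
    warn(paste0("exact-match constraint relaxed for ", relaxed, " sample(s)"))
  }
  pairs <- dplyr::bind_rows(pairs)
  mf <- meta[match(pairs$fibrosis_id, meta$sample_id), ]
  mc <- meta[match(pairs$nofibrosis_id, meta$sample_id), ]
  balance <- dplyr::bind_rows(
    purrr::map(covariates, function(v) {
      tibble::tibble(covariate = v, test = "wilcoxon",
                     p_value = suppressWarnings(
                       wilcox.test(mf[[v]], mc[[v]], exact = FALSE)$p.value))
    }),
    purrr::map(exact %||% character(0), function(v) {
      tab <- table(c(rep("fibrosis", nrow(mf)), rep("nofibrosis", nrow(mc))),
                   c(as.character(mf[[v]]), as.character(mc[[v]])))
      p <- if (ncol(tab) < 2) 1 else fisher.test(tab)$p.value
      tibble::tibble(covariate = v, test = "fisher", p_value = p)
    })
  )
  structure(list(pairs = pairs, balance = balance, covariates = covariates,
                 exact = exact, k = k,
                 matched_ids = c(pairs$fibrosis_id, pairs$nofibrosis_id)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat("Nearest-neighbor match: ", nrow(x$pairs), " pairs\n", sep = "")
  cat("Covariates: ", paste(x$covariates, collapse = ", "),
      if (length(x$exact)) paste0(" (exact: ", paste(x$exact, collapse = ", "), ")"),
      "\n", sep = "")
  print(x$balance)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.match_result <- function(x, ...) x$pairs

#' @exportS3Method generics::glance
glance.match_result <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$balance[, c("covariate", "p_value")],
                             names_from = "covariate", values_from = "p_value",
                             names_prefix = "p_")
  dplyr::bind_cols(tibble::tibble(n_pairs = nrow(x$pairs),
                                  mean_distance = mean(x$pairs$distance)), wide)
}
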