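panel_feature_matrix <- function(m, panel, strict = TRUE) {
  m <- validate_intensity_matrix(m)
  present <- intersect(panel, peptide_ids(m))
  missing <- setdiff(panel, present)
  if (length(missing)) {
    if (strict) {
      abort(paste0("panel peptides absent from matrix: ",
                   paste(missing, collapse = ", ")))
    }
    warn(paste0("panel peptides absent from matrix, treated as undetected: ",
                paste(missing, collapse = ", ")))
  }
  x <- matrix(0, nrow = nrow(m), ncol = length(panel),
              dimnames = list(m$sample_id, panel))
  if (length(present)) x[, present] <- as.matrix(m[, present, drop = FALSE])
  x
}

rbf_kernel <- function(x, sv, gamma) {
  d2 <- outer(rowSums(x^2), rowSums(sv^2), "+") - 2 * tcrossprod(x, sv)
  exp(-gamma * pmax(d2, 0))
}

classifier_decision <- function(clf, x) {
  z <- sweep(sweep(log1p(x), 2, clf$center, "-"), 2, clf$scale, "/")
  k <- switch(clf$kernel,
              radial = rbf_kernel(z, clf$sv, clf$gamma),
              linear = tcrossprod(z, clf$sv),
              abort(paste0("unsupported kernel: ", clf$kernel)))
  drop(clf$sign * (k %*% clf$coefs - clf$rho))
}

#' Train an SVM peptide-panel classifier
#'
#' Intensities are restricted to the panel peptides (in panel order),
#' `log1p`-transformed to tame the log-normal intensity scale, standardized
#' with training-set means and SDs, and fed to a C-classification support
#' vector machine (RBF kernel with `gamma = 1/panel size` and `cost = 1` by
#' default). The fitted decision function is stored as explicit support
#' coefficients so the classifier serializes to plain text and reloads with
#' bit-identical scores. Scores are oriented so that larger means more
#' fibrosis-like. The classification threshold defaults to the Youden-index
#' operating point of the in-sample score ROC.
#'
#' @param m Intensity matrix tibble.
#' @param groups Data frame with `sample_id`, `group`.
#' @param panel Character vector of panel peptide ids (must be present in
#'   `m`).
#' @param cost Soft-margin cost parameter.
#' @param gamma RBF kernel width; default `1/length(panel)`.
#' @param kernel `"radial"` or `"linear"`.
#' @param threshold Score cut-off for the fibrosis label; `NULL` derives it
#'   from the Youden index on the training scores.
#' @return A `panel_classifier` object.
#' @export
train_panel <- function(m, groups, panel, cost = 1, gamma = NULL,
                        kernel = c("radial", "linear"), threshold = NULL) {
  kernel <- match.arg(kernel)
  if (!length(panel)) abort("panel must be non-empty")
  groups <- group_labels(m, groups)
  if (!any(groups$group == "fibrosis") || !any(groups$group == "nofibrosis")) {
    abort("degenerate single-class input")
  }
  gamma <- gamma %||% (1 / length(panel))
  x <- panel_feature_matrix(intensity_submatrix(m, samples = groups$sample_id),
                            panel, strict = TRUE)
  y <- factor(groups$group, levels = c("fibrosis", "nofibrosis"))
  lx <- log1p(x)
  center <- colMeans(lx)
  scale <- apply(lx, 2, sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  z <- sweep(sweep(lx, 2, center, "-"), 2, scale, "/")
  fit <- e1071::svm(z, y, type = "C-classification", kernel = kernel,
                    cost = cost, gamma = gamma, scale = FALSE)
  dv <- attr(predict(fit, z, decision.values = TRUE), "decision.values")
  sign <- if (startsWith(colnames(dv)[1], "fibrosis/")) 1 else -1
  clf <- structure(list(panel = panel, center = center, scale = scale,
                        kernel = kernel, gamma = gamma, cost = cost,
                        sv = unname(as.matrix(fit$SV)),
                        coefs = as.numeric(fit$coefs), rho = as.numeric(fit$rho),
                        sign = sign, threshold = 0,
                        n_train = nrow(z), n_support = nrow(fit$SV),
                        levels = c("fibrosis", "nofibrosis")),
                   class = "panel_classifier")
  scores <- classifier_decision(clf, x)
  if (is.null(threshold)) {
    r <- roc(tibble::tibble(score = scores, group = as.character(y)),
             score = "score", truth = "group")
    threshold <- youden_point(r)$threshold
  }
  clf$threshold <- threshold
  clf
}

#' Score samples with a trained panel classifier
#'
#' Applies the training-time transform (log1p, stored standardization) and
#' decision function to new samples. Panel peptides missing from the matrix
#' are treated as undetected (intensity 0) with a warning. A sample is
#' labelled `fibrosis` exactly when its score is at or above the
#' classifier's threshold.
#'
#' @param clf A `panel_classifier`.
#' @param m Intensity matrix tibble.
#' @return Tibble with `sample_id`, `score`, `predicted_label`.
#' @export
apply_panel <- function(clf, m) {
  stopifnot(inherits(clf, "panel_classifier"))
  x <- panel_feature_matrix(m, clf$panel, strict = FALSE)
  s <- classifier_decision(clf, x)
  tibble::tibble(sample_id = rownames(x), score = unname(s),
                 predicted_label = unname(ifelse(s >= clf$threshold,
                                                 "fibrosis", "nofibrosis")))
}

#' Leave-one-out cross-validated panel scores
#'
#' For every sample in the two groups, the classifier (including the
#' standardization parameters) is refitted on all remaining samples and the
#' held-out sample is scored, so no sample influences its own transform or
#' decision function. The pooled out-of-fold scores estimate the
#' classifier's generalization ROC.
#'
#' @inheritParams train_panel
#' @return Tibble with `sample_id`, `score`, `group`.
#' @export
loo_scores <- function(m, groups, panel, cost = 1, gamma = NULL,
                       kernel = c("radial", "linear")) {
  kernel <- match.arg(kernel)
  groups <- group_labels(m, groups)
  m2 <- intensity_submatrix(m, samples = groups$sample_id)
  out <- numeric(nrow(groups))
  for (i in seq_len(nrow(groups))) {
    clf <- train_panel(m2[-i, , drop = FALSE], groups[-i, , drop = FALSE],
                       panel, cost = cost, gamma = gamma, kernel = kernel,
                       threshold = 0)
    x <- panel_feature_matrix(m2[i, , drop = FALSE], panel, strict = TRUE)
    out[i] <- classifier_decision(clf, x)
  }
  tibble::tibble(sample_id = groups$sample_id, score = out,
                 group = as.character(groups$group))
}

#' Serialize a panel classifier to JSON
#'
#' The complete decision function (panel order, transform parameters, kernel
#' settings, support coefficients, bias and threshold) is written as a
#' single structured text document with full numeric precision.
#'
#' @param clf A `panel_classifier`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_classifier <- function(clf, path) {
  stopifnot(inherits(clf, "panel_classifier"))
  jsonlite::write_json(unclass(clf), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a serialized panel classifier
#' @param path Path to a JSON file written by [write_classifier()].
#' @return A `panel_classifier`.
#' @export
read_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$sv <- matrix(as.numeric(obj$sv), nrow = NROW(obj$sv))
  obj$center <- stats::setNames(as.numeric(obj$center), obj$panel)
  obj$scale <- stats::setNames(as.numeric(obj$scale), obj$panel)
  structure(obj, class = "panel_classifier")
}

#' @export
print.panel_classifier <- function(x, ...) {
  cat("Peptide-panel SVM classifier\n")
  cat("  panel size: ", length(x$panel), " peptides\n", sep = "")
  cat("  kernel: ", x$kernel, " (gamma = ", signif(x$gamma, 4),
      ", cost = ", x$cost, ")\n", sep = "")
  cat("  support vectors: ", x$n_support, " of ", x$n_train,
      " training samples\n", sep = "")
  cat("  threshold: ", signif(x$threshold, 4), "\n", sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.panel_classifier <- function(x, ...) {
  tibble::tibble(peptide_id = x$panel, center = unname(x$center),
                 scale = unname(x$scale))
}

#' @exportS3Method generics::glance
glance.panel_classifier <- function(x, ...) {
  tibble::tibble(n_panel = length(x$panel), kernel = x$kernel,
                 gamma = x$gamma, cost = x$cost, n_train = x$n_train,
                 n_support = x$n_support, threshold = x$threshold)
}
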