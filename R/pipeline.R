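#' Default pipeline configuration
#'
#' Assembles the configuration list consumed by [run_pipeline()]. Any field
#' can be overridden; the defaults reproduce the reference design: IFTA groups
#' at < 10 / >= 15 percent, nearest-neighbor matching on eGFR, proteinuria
#' and age with exact sex matching, a 30 percent detection-frequency
#' threshold with BH control at 0.05, and an RBF SVM panel classifier.
#'
#' @param matrix,metadata Paths to the intensity matrix and metadata files.
#' @param out_dir Output directory for run artifacts.
#' @param standards Character vector of internal-standard peptide ids, or a
#'   regular expression prefix (default `"^IS_"`) matched against peptide
#'   ids; `NULL` skips normalization.
#' @param fibrosis_min,nofibrosis_max IFTA group cut-offs (percent).
#' @param covariates,exact,k Matching options, see
#'   [nearest_neighbor_match()].
#' @param threshold,alpha Discovery options, see [discover()].
#' @param cost,gamma,kernel SVM options, see [train_panel()].
#' @param protease_table Path to a protease association table, or `NULL` to
#'   skip the protease stage.
#' @param seed Integer seed recorded in the manifest.
#' @return A named configuration list.
#' @export
pipeline_config <- function(matrix, metadata, out_dir,
                            standards = "^IS_",
                            fibrosis_min = 15, nofibrosis_max = 10,
                            covariates = c("egfr", "proteinuria", "age"),
                            exact = "sex", k = NULL,
                            threshold = 0.30, alpha = 0.05,
                            cost = 1, gamma = NULL, kernel = "radial",
                            protease_table = NULL, seed = 1L) {
  list(matrix = matrix, metadata = metadata, out_dir = out_dir,
       standards = standards, fibrosis_min = fibrosis_min,
       nofibrosis_max = nofibrosis_max, covariates = covariates,
       exact = exact, k = k, threshold = threshold, alpha = alpha,
       cost = cost, gamma = gamma, kernel = kernel,
       protease_table = protease_table, seed = as.integer(seed))
}

#' Run the full fibrosis-peptidomics pipeline
#'
#' Executes group assignment, covariate matching, internal-standard
#' normalization, biomarker discovery, panel training with leave-one-out
#' validation, ROC/Youden/Spearman evaluation and (optionally) protease
#' summarization, writing every intermediate table plus a machine-readable
#' run manifest into `out_dir`. Identical configuration and inputs produce
#' byte-identical outputs.
#'
#' @param config Configuration list from [pipeline_config()], or the path
#'   to a YAML file holding one.
#' @return Invisibly, a list with all stage results and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (f in c("matrix", "metadata")) {
    if (is.null(config[[f]]) || !file.exists(config[[f]])) {
      abort(paste0("pipeline input missing: ", f, " file '",
                   config[[f]] %||% "<unset>", "' not found"))
    }
  }
  if (!is.null(config[["protease_table"]]) && !file.exists(config[["protease_table"]])) {
    abort(paste0("pipeline input missing: protease table '",
                 config[["protease_table"]], "' not found"))
  }
  dir.create(config[["out_dir"]], recursive = TRUE, showWarnings = FALSE)
  set.seed(config[["seed"]] %||% 1L)
  out <- function(name) file.path(config[["out_dir"]], name)

  m <- read_intensity_matrix(config[["matrix"]])
  meta <- read_sample_metadata(config[["metadata"]])

  inform("stage: group assignment")
  meta <- assign_groups(meta, group_rule(config[["fibrosis_min"]] %||% 15,
                                         config[["nofibrosis_max"]] %||% 10))
  readr::write_tsv(meta, out("groups.tsv"), progress = FALSE)

  inform("stage: covariate matching")
  mr <- nearest_neighbor_match(meta, covariates = config[["covariates"]],
                               exact = config[["exact"]], k = config[["k"]])
  readr::write_tsv(mr$pairs, out("match_pairs.tsv"), progress = FALSE)
  readr::write_tsv(mr$balance, out("match_balance.tsv"), progress = FALSE)
  matched <- dplyr::filter(meta, .data$sample_id %in% mr$matched_ids)

  if (!is.null(config[["standards"]])) {
    inform("stage: internal-standard normalization")
    std <- config[["standards"]]
    if (length(std) == 1 && grepl("^\\^", std)) {
      std <- grep(std, peptide_ids(m), value = TRUE)
    }
    if (!length(std)) abort("no internal standard peptides found in matrix")
    m <- normalize_to_standards(m, normalization_spec(std))
    m <- m[, !(names(m) %in% setdiff(std, "sample_id")), drop = FALSE]
  }
  mm <- intensity_submatrix(m, samples = matched$sample_id)

  inform("stage: biomarker discovery")
  bio <- discover(mm, matched, threshold = config[["threshold"]] %||% 0.30,
                  alpha = config[["alpha"]] %||% 0.05)
  readr::write_tsv(bio, out("biomarkers.tsv"), progress = FALSE)
  panel <- bio$peptide_id[bio$selected]
  panel <- panel[order(bio$p_adj[match(panel, bio$peptide_id)])]
  if (!length(panel)) abort("discovery selected no biomarkers; cannot train a panel")

  inform(paste0("stage: panel training (", length(panel), " peptides)"))
  clf <- train_panel(mm, matched, panel, cost = config[["cost"]] %||% 1,
                     gamma = config[["gamma"]], kernel = config[["kernel"]] %||% "radial")
  write_classifier(clf, out("classifier.json"))

  inform("stage: leave-one-out validation")
  loo <- loo_scores(mm, matched, panel, cost = config[["cost"]] %||% 1,
                    gamma = config[["gamma"]], kernel = config[["kernel"]] %||% "radial")
  readr::write_tsv(loo, out("loo_scores.tsv"), progress = FALSE)

  inform("stage: evaluation")
  r <- roc(loo, score = "score", truth = "group")
  readr::write_tsv(r$points, out("roc_points.tsv"), progress = FALSE)
  evaluation <- dplyr::bind_cols(
    glance(r),
    dplyr::rename(spearman_cor(dplyr::inner_join(loo, matched, by = "sample_id"),
                               "ifta_percent", "score"),
                  spearman_rho = "rho", spearman_p = "p_value",
                  spearman_n = "n"))
  readr::write_tsv(evaluation, out("evaluation.tsv"), progress = FALSE)

  prot <- NULL
  if (!is.null(config[["protease_table"]])) {
    inform("stage: protease summary")
    assoc <- read_protease_table(config[["protease_table"]])
    pan_tab <- bio[bio$selected, ]
    if (all(c("uniprot_id", "start_pos", "stop_pos") %in% names(pan_tab))) {
      sites <- peptide_to_sites(pan_tab)
      matches <- match_observed(sites, assoc)
      prot <- summarize_proteases(bio, matches, mm, matched)
      readr::write_tsv(prot, out("protease_summary.tsv"), progress = FALSE)
    } else {
      warn("biomarker table lacks uniprot/start/stop columns; protease stage skipped")
    }
  }

  manifest <- list(package = "fibropep",
                   version = as.character(utils::packageVersion("fibropep")),
                   r_version = R.version.string,
                   seed = config[["seed"]] %||% 1L,
                   config = config[setdiff(names(config), "out_dir")],
                   config_hash = rlang::hash(config[setdiff(names(config),
                                                            "out_dir")]),
                   n_matched_pairs = nrow(mr$pairs),
                   n_selected = length(panel))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(metadata = meta, match = mr, biomarkers = bio, panel = panel,
                 classifier = clf, loo = loo, roc = r,
                 evaluation = evaluation, proteases = prot,
                 out_dir = config[["out_dir"]]))
}

#' Write a synthetic demonstration dataset to disk
#'
#' Generates the default synthetic cohort (Table-2-scale planted effects,
#' 100/100 fibrosis/no-fibrosis design, 29 internal standards) and writes
#' the intensity matrix, metadata, planted panel and a ready-to-run pipeline
#' configuration into `dir`. The same seed always produces identical files.
#'
#' @param seed Integer seed.
#' @param dir Output directory.
#' @return Invisibly, a named list of the file paths.
#' @export
generate_demo <- function(seed = 1L, dir = tempfile("fibropep_demo")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- cohort_spec(seed = seed)
  cohort <- generate_cohort(spec)
  paths <- list(matrix = file.path(dir, "intensities.tsv"),
                metadata = file.path(dir, "metadata.tsv"),
                panel = file.path(dir, "planted_panel.tsv"),
                config = file.path(dir, "config.yaml"))
  write_intensity_matrix(cohort$intensities, paths$matrix)
  write_sample_metadata(cohort$metadata, paths$metadata)
  write_peptide_panel(fpp_bh29_panel(), paths$panel)
  cfg <- pipeline_config(matrix = paths$matrix, metadata = paths$metadata,
                         out_dir = file.path(dir, "run"), seed = seed)
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))], paths$config)
  invisible(paths)
}
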