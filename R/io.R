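#' Read a sample-by-peptide intensity matrix
#'
#' CE-MS peak-list data arrive as a delimited text table with one row per
#' urine sample and one column per peptide. The first column holds sample
#' identifiers, the header row holds peptide identifiers, and each cell is a
#' non-negative relative abundance (normalized ion signal intensity). An
#' empty cell means the peptide was not detected in that sample and is read
#' as intensity 0; zeros are kept in the table (no `NA`) because downstream
#' frequency filtering and rank tests use presence/absence and intensity
#' jointly.
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter (default tab).
#' @return A tibble whose first column is `sample_id` (character) followed by
#'   one numeric column per peptide.
#' @export
read_intensity_matrix <- function(path, delim = "\t") {
  if (!file.exists(path)) {
    abort(paste0("intensity matrix file not found: ", path))
  }
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE, na = c("", "NA"))
  if (ncol(x) < 2) {
    abort("malformed header: expected a sample id column plus at least one peptide column")
  }
  names(x)[1] <- "sample_id"
  x$sample_id <- as.character(x$sample_id)
  for (j in seq(2, ncol(x))) {
    v <- x[[j]]
    if (!is.numeric(v)) {
      v <- suppressWarnings(as.numeric(v))
      if (anyNA(v) && !anyNA(x[[j]])) {
        abort(paste0("malformed header or non-numeric intensity column: ", names(x)[j]))
      }
    }
    v[is.na(v)] <- 0
    x[[j]] <- v
  }
  validate_intensity_matrix(x)
}

#' Write an intensity matrix to delimited text
#'
#' Values are written with shortest round-trip precision so that
#' `read_intensity_matrix()` reproduces the matrix exactly.
#'
#' @param m Intensity matrix tibble (`sample_id` + numeric peptide columns).
#' @param path Output file path.
#' @param delim Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_intensity_matrix <- function(m, path, delim = "\t") {
  m <- validate_intensity_matrix(m)
  readr::write_delim(m, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Validate an intensity matrix tibble
#'
#' Enforces the invariants of the container: a character `sample_id` first
#' column without duplicates, unique peptide column names, and all
#' intensities finite and non-negative (zero encodes not-detected).
#'
#' @param m A data frame.
#' @return The validated tibble.
#' @export
validate_intensity_matrix <- function(m) {
  m <- tibble::as_tibble(m)
  if (ncol(m) < 2 || names(m)[1] != "sample_id") {
    abort("intensity matrix must have a leading 'sample_id' column plus peptide columns")
  }
  if (anyDuplicated(m$sample_id)) {
    abort(paste0("duplicate sample_id: ",
                 paste(unique(m$sample_id[duplicated(m$sample_id)]), collapse = ", ")))
  }
  pep <- names(m)[-1]
  if (anyDuplicated(pep)) {
    abort(paste0("duplicate peptide_id: ",
                 paste(unique(pep[duplicated(pep)]), collapse = ", ")))
  }
  for (j in seq(2, ncol(m))) {
    v <- m[[j]]
    if (!is.numeric(v)) abort(paste0("non-numeric intensity column: ", names(m)[j]))
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad)) {
      abort(paste0("negative or non-finite intensity at sample '",
                   m$sample_id[bad[1]], "', peptide '", names(m)[j], "'"))
    }
  }
  m
}

peptide_ids <- function(m) names(m)[-1]

#' @noRd
intensity_submatrix <- function(m, samples = NULL, peptides = NULL) {
  if (!is.null(samples)) m <- m[match(samples, m$sample_id), , drop = FALSE]
  if (!is.null(peptides)) m <- m[, c("sample_id", peptides), drop = FALSE]
  m
}

#' Internal-standard normalization specification
#'
#' CE-MS signal intensities are made comparable across samples by rescaling
#' each sample so that an aggregate over a set of "housekeeping" internal
#' standard peptides hits a common reference level. The specific standard
#' peptides are laboratory-defined, so they are a parameter here, not a
#' constant.
#'
#' @param standard_peptide_ids Character vector of internal-standard peptide
#'   ids (non-empty).
#' @param reference_level Target aggregate intensity for the standards after
#'   normalization. `NULL` (default) uses the grand mean of the per-sample
#'   aggregates, which preserves the overall intensity scale.
#' @param aggregate `"mean"` or `"median"` of the standards within a sample.
#' @return A `normalization_spec` list.
#' @export
normalization_spec <- function(standard_peptide_ids, reference_level = NULL,
                               aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  if (length(standard_peptide_ids) == 0) abort("standard_peptide_ids must be non-empty")
  if (!is.null(reference_level) &&
      (!is.numeric(reference_level) || reference_level <= 0)) {
    abort("reference_level must be > 0")
  }
  structure(list(standard_peptide_ids = as.character(standard_peptide_ids),
                 reference_level = reference_level, aggregate = aggregate),
            class = "normalization_spec")
}

#' Normalize intensities to internal standard peptides
#'
#' Each sample's intensities are multiplied by
#' `reference_level / aggregate(standards in that sample)`, so the standards'
#' per-sample aggregate equals the reference level afterwards. The operation
#' is a per-sample multiplicative rescaling and is idempotent.
#'
#' @param m Intensity matrix tibble.
#' @param spec A [normalization_spec()].
#' @return The rescaled intensity matrix tibble.
#' @export
normalize_to_standards <- function(m, spec) {
  m <- validate_intensity_matrix(m)
  stopifnot(inherits(spec, "normalization_spec"))
  std <- spec$standard_peptide_ids
  missing <- setdiff(std, peptide_ids(m))
  if (length(missing)) {
    abort(paste0("standard peptides absent from matrix: ",
                 paste(missing, collapse = ", ")))
  }
  smat <- as.matrix(m[, std, drop = FALSE])
  agg <- switch(spec$aggregate,
                mean = rowMeans(smat),
                median = apply(smat, 1, median))
  zero <- which(agg <= 0)
  if (length(zero)) {
    abort(paste0("all internal standards undetected in sample '",
                 m$sample_id[zero[1]], "'"))
  }
  ref <- spec$reference_level %||% mean(agg)
  factor <- ref / agg
  out <- m
  vals <- as.matrix(m[, -1, drop = FALSE]) * factor
  out[, -1] <- tibble::as_tibble(vals)
  out
}

#' Count basic residues in a peptide sequence
#'
#' Lysine (K), arginine (R) and histidine (H) carry positive charge at the
#' CE working pH of 2 and govern electrophoretic migration. Lowercase letters
#' are reserved for modified residues (`p` = hydroxyproline, `m` = oxidized
#' methionine) and are never basic, so only uppercase K/R/H are counted.
#'
#' @param sequence Character vector of peptide sequences.
#' @return Integer vector of basic-residue counts.
#' @export
count_basic_residues <- function(sequence) {
  stringr::str_count(sequence, "[KRH]")
}

#' Check CE-migration-time plausibility of sequence assignments
#'
#' A sequence candidate for a CE-MS peak is only plausible if the migration
#' time predicted from its basic-residue count agrees with the observed
#' migration time. The prediction is a least-squares linear fit of
#' user-supplied calibration pairs (basic-residue count, migration time);
#' a peptide is accepted when the absolute deviation between observed and
#' predicted time is within `tolerance` minutes.
#'
#' @param peptides Data frame with columns `sequence` and `migration_time`
#'   (minutes); other columns are carried through.
#' @param calibration Data frame with columns `n_basic` and `migration_time`,
#'   with at least two distinct `n_basic` values.
#' @param tolerance Acceptance window in minutes.
#' @return The input tibble with added columns `n_basic`, `predicted_time`,
#'   `deviation` and `status` (`"accepted"`/`"rejected"`).
#' @export
check_migration_time <- function(peptides, calibration, tolerance) {
  peptides <- tibble::as_tibble(peptides)
  if (!all(c("sequence", "migration_time") %in% names(peptides))) {
    abort("peptides must have 'sequence' and 'migration_time' columns")
  }
  if (any(is.na(peptides$sequence) | !nzchar(peptides$sequence))) {
    abort("empty peptide sequence")
  }
  calibration <- tibble::as_tibble(calibration)
  if (length(unique(calibration$n_basic)) < 2) {
    abort("calibration needs at least two distinct n_basic values")
  }
  fit <- lm(migration_time ~ n_basic, data = calibration)
  nb <- count_basic_residues(peptides$sequence)
  pred <- unname(coef(fit)[1] + coef(fit)[2] * nb)
  dev <- abs(peptides$migration_time - pred)
  dplyr::mutate(peptides,
                n_basic = nb,
                predicted_time = pred,
                deviation = dev,
                status = ifelse(dev <= tolerance, "accepted", "rejected"))
}

#' Read a peptide panel / peak-list annotation file
#'
#' The panel format is delimited text with columns `peptide_id`,
#' `gene_symbol` and `sequence`, optionally `mass_da`, `migration_time_min`,
#' `uniprot_id`, `start_pos`, `stop_pos` (1-based inclusive positions in the
#' parent protein) and any extra columns (e.g. discovery statistics), which
#' are carried through. Lowercase `p`/`m` in sequences denote hydroxyproline
#' and oxidized methionine.
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter (default tab).
#' @return A tibble of peptide records.
#' @export
read_peptide_panel <- function(path, delim = "\t") {
  if (!file.exists(path)) abort(paste0("panel file not found: ", path))
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE, na = c("", "NA"))
  validate_peptide_panel(x)
}

#' Write a peptide panel file
#' @param panel Peptide panel tibble.
#' @param path Output file path.
#' @param delim Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_peptide_panel <- function(panel, path, delim = "\t") {
  panel <- validate_peptide_panel(panel)
  readr::write_delim(panel, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Validate a peptide panel tibble
#'
#' Checks identifier uniqueness, positive masses and migration times,
#' 1-based inclusive positions, and agreement of sequence length with
#' `stop_pos - start_pos + 1` where both are present.
#'
#' @param panel A data frame of peptide records.
#' @return The validated tibble.
#' @export
validate_peptide_panel <- function(panel) {
  panel <- tibble::as_tibble(panel)
  need <- c("peptide_id", "gene_symbol", "sequence")
  miss <- setdiff(need, names(panel))
  if (length(miss)) abort(paste0("panel missing columns: ", paste(miss, collapse = ", ")))
  if (anyDuplicated(panel$peptide_id)) abort("duplicate peptide_id in panel")
  if ("mass_da" %in% names(panel) && any(panel$mass_da <= 0, na.rm = TRUE)) {
    abort("mass_da must be > 0")
  }
  if ("migration_time_min" %in% names(panel) &&
      any(panel$migration_time_min <= 0, na.rm = TRUE)) {
    abort("migration_time_min must be > 0")
  }
  if (all(c("start_pos", "stop_pos") %in% names(panel))) {
    ok <- is.na(panel$start_pos) | is.na(panel$stop_pos) |
      (panel$start_pos >= 1 & panel$stop_pos >= panel$start_pos)
    if (!all(ok)) abort("positions must satisfy 1 <= start_pos <= stop_pos")
    both <- !is.na(panel$start_pos) & !is.na(panel$stop_pos) & !is.na(panel$sequence)
    len_ok <- nchar(panel$sequence[both]) ==
      panel$stop_pos[both] - panel$start_pos[both] + 1
    if (!all(len_ok)) {
      abort(paste0("sequence length disagrees with start/stop for: ",
                   paste(panel$peptide_id[both][!len_ok], collapse = ", ")))
    }
  }
  panel
}

#' Read per-sample clinical metadata
#'
#' Expected columns: `sample_id`, `ifta_percent` (percent fibrotic
#' interstitial area, 0-100), `egfr` (mL/min/1.73 m2, CKD-EPI),
#' `proteinuria` (mg/24 h), `age` (years), `sex` (`"M"`/`"F"`), and
#' optionally `etiology` and `cohort`.
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter (default tab).
#' @return A tibble of sample metadata.
#' @export
read_sample_metadata <- function(path, delim = "\t") {
  if (!file.exists(path)) abort(paste0("metadata file not found: ", path))
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE, na = c("", "NA"))
  validate_sample_metadata(x)
}

#' Write per-sample clinical metadata
#' @param meta Metadata tibble.
#' @param path Output file path.
#' @param delim Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(meta, path, delim = "\t") {
  meta <- validate_sample_metadata(meta)
  readr::write_delim(meta, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Validate a sample metadata tibble
#' @param meta A data frame of per-sample clinical metadata.
#' @return The validated tibble.
#' @export
validate_sample_metadata <- function(meta) {
  meta <- tibble::as_tibble(meta)
  need <- c("sample_id", "ifta_percent", "egfr", "proteinuria", "age", "sex")
  miss <- setdiff(need, names(meta))
  if (length(miss)) abort(paste0("metadata missing columns: ", paste(miss, collapse = ", ")))
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id)) abort("duplicate sample_id in metadata")
  if (any(is.na(meta$ifta_percent))) abort("missing ifta_percent")
  if (any(meta$ifta_percent < 0 | meta$ifta_percent > 100)) {
    abort("ifta_percent must be within [0, 100]")
  }
  if (any(meta$egfr <= 0, na.rm = TRUE)) abort("egfr must be > 0")
  if (any(meta$proteinuria < 0, na.rm = TRUE)) abort("proteinuria must be >= 0")
  if (any(meta$age <= 0, na.rm = TRUE)) abort("age must be > 0")
  if (!all(meta$sex %in% c("M", "F", NA))) abort("sex must be coded 'M'/'F'")
  meta
}

#' The 29-peptide urinary fibrosis panel
#'
#' The bundled panel of 29 urinary peptides with differential abundance
#' between high-IFTA and low-IFTA kidneys, with gene symbols, sequences
#' (lowercase `p` = hydroxyproline, `m` = oxidized methionine), BH-adjusted
#' p-values, group mean intensities in the 100/100 training design and fold
#' changes (fibrosis / no fibrosis). Mass, migration time and parent-protein
#' positions were not published and are `NA`.
#'
#' @return A 29-row peptide panel tibble.
#' @export
fpp_bh29_panel <- function() {
  read_peptide_panel(system.file("extdata", "fpp_bh29_panel.tsv",
                                 package = "fibropep"))
}
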