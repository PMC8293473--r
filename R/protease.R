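#' Map naturally occurring peptides to candidate cleavage sites
#'
#' A urinary peptide observed at positions `start_pos`..`stop_pos` of its
#' parent protein implies a cleavage event before its first residue (site
#' position `start_pos - 1`, N-terminal) unless it begins at the protein
#' N-terminus, and one after its last residue (site position `stop_pos`,
#' C-terminal) unless it ends at the protein C-terminus. Cleavage position
#' `k` means cleavage between residues `k` and `k + 1` (1-based). When the
#' parent protein length is unknown the C-terminal site is still emitted,
#' flagged `uncertain`.
#'
#' @param peptides Peptide tibble with `peptide_id`, `uniprot_id`,
#'   `start_pos`, `stop_pos`.
#' @param protein_lengths Optional data frame with `uniprot_id`, `length`.
#' @return Tibble with `peptide_id`, `uniprot_id`, `position`, `terminus`
#'   (`"N"`/`"C"`), `uncertain`.
#' @export
peptide_to_sites <- function(peptides, protein_lengths = NULL) {
  peptides <- tibble::as_tibble(peptides)
  need <- c("peptide_id", "uniprot_id", "start_pos", "stop_pos")
  miss <- setdiff(need, names(peptides))
  if (length(miss)) abort(paste0("peptides missing columns: ", paste(miss, collapse = ", ")))
  bad <- is.na(peptides$start_pos) | is.na(peptides$stop_pos) |
    is.na(peptides$uniprot_id)
  if (any(bad)) {
    warn(paste0("skipping peptides without positions: ",
                paste(peptides$peptide_id[bad], collapse = ", ")))
    peptides <- peptides[!bad, , drop = FALSE]
  }
  len <- NULL
  if (!is.null(protein_lengths)) {
    len <- stats::setNames(protein_lengths$length, protein_lengths$uniprot_id)
  }
  out <- purrr::pmap(peptides[, need], function(peptide_id, uniprot_id,
                                                start_pos, stop_pos) {
    rows <- list()
    if (start_pos > 1) {
      rows <- c(rows, list(tibble::tibble(peptide_id = peptide_id,
                                          uniprot_id = uniprot_id,
                                          position = start_pos - 1,
                                          terminus = "N", uncertain = FALSE)))
    }
    plen <- if (!is.null(len)) unname(len[uniprot_id]) else NA_real_
    if (is.na(plen) || stop_pos < plen) {
      rows <- c(rows, list(tibble::tibble(peptide_id = peptide_id,
                                          uniprot_id = uniprot_id,
                                          position = stop_pos,
                                          terminus = "C",
                                          uncertain = is.na(plen))))
    }
    dplyr::bind_rows(rows)
  })
  dplyr::bind_rows(out)
}

#' Read a protease-cleavage-site association table
#'
#' Delimited text with columns `protease_gene`, `substrate_uniprot`,
#' `position` and `evidence` (a literature tag). The bundled demonstration
#' table (`system.file("extdata", "protease_associations_synthetic.tsv",
#' package = "fibropep")`) uses synthetic cleavage coordinates and is
#' illustrative, not a curated mirror of a protease database; replace it
#' with a curated table for real analyses.
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter (default tab).
#' @return Tibble of protease associations.
#' @export
read_protease_table <- function(path, delim = "\t") {
  if (!file.exists(path)) abort(paste0("protease table not found: ", path))
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE)
  need <- c("protease_gene", "substrate_uniprot", "position")
  miss <- setdiff(need, names(x))
  if (length(miss)) abort(paste0("protease table missing columns: ",
                                 paste(miss, collapse = ", ")))
  if (any(x$position < 1)) abort("association positions must be >= 1")
  x
}

#' Observed-mode protease matching
#'
#' Restricts protease prediction to cleavage sites with a
#' literature-reported protease association: every exact
#' (UniProt accession, cleavage position) coincidence between the observed
#' sites and the association table is returned. A site can match several
#' proteases and a protease several sites.
#'
#' @param sites Cleavage-site tibble from [peptide_to_sites()].
#' @param table Association tibble from [read_protease_table()].
#' @return Tibble with one row per (protease, site) match.
#' @export
match_observed <- function(sites, table) {
  sites <- tibble::as_tibble(sites)
  table <- tibble::as_tibble(table)
  if (!nrow(sites) || !nrow(table)) {
    return(tibble::tibble(protease_gene = character(), peptide_id = character(),
                          uniprot_id = character(), position = numeric(),
                          terminus = character(), evidence = character()))
  }
  dplyr::inner_join(sites,
                    dplyr::rename(table, uniprot_id = "substrate_uniprot"),
                    by = c("uniprot_id", "position"),
                    relationship = "many-to-many") |>
    dplyr::select(dplyr::any_of(c("protease_gene", "peptide_id", "uniprot_id",
                                  "position", "terminus", "evidence")))
}

#' Per-protease regulation summary
#'
#' Aggregates matched cleavage events per protease: `n_up` counts events on
#' peptides whose discovery fold change exceeds 1, `n_down` those below 1
#' (a fold change of exactly 1 counts as neither and is reported with a
#' warning). For intensity-level summaries, each sample's matched peptide
#' intensities are aggregated (sum by default), and the protease fold
#' change is the ratio of group means of that aggregate, with a
#' Mann-Whitney (Wilcoxon rank-sum) p-value. Proteases with no matched
#' peptide present in the matrix are omitted.
#'
#' @param biomarkers Discovery results from [discover()] (needs
#'   `peptide_id`, `fold_change`).
#' @param matches Match tibble from [match_observed()].
#' @param m Intensity matrix tibble.
#' @param groups Data frame with `sample_id`, `group`.
#' @param aggregate `"sum"` (default) or `"mean"` across a protease's
#'   matched peptides within each sample.
#' @return Tibble with `protease_gene`, `n_down`, `n_up`, `mean_fibrosis`,
#'   `mean_nofibrosis`, `fold_change`, `p_value`, ordered by fold change.
#' @export
summarize_proteases <- function(biomarkers, matches, m, groups,
                                aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  if (!nrow(matches)) {
    return(tibble::tibble(protease_gene = character(), n_down = integer(),
                          n_up = integer(), mean_fibrosis = numeric(),
                          mean_nofibrosis = numeric(), fold_change = numeric(),
                          p_value = numeric()))
  }
  m <- validate_intensity_matrix(m)
  groups <- group_labels(m, groups)
  fib_ids <- groups$sample_id[groups$group == "fibrosis"]
  nof_ids <- groups$sample_id[groups$group == "nofibrosis"]
  ev <- dplyr::inner_join(matches,
                          biomarkers[, c("peptide_id", "fold_change")],
                          by = "peptide_id")
  if (any(ev$fold_change == 1, na.rm = TRUE)) {
    warn("cleavage events on peptides with fold change exactly 1 counted as neither up nor down")
  }
  res <- ev |>
    dplyr::group_by(.data$protease_gene) |>
    dplyr::group_map(function(d, key) {
      peps <- intersect(unique(d$peptide_id), peptide_ids(m))
      if (!length(peps)) return(NULL)
      sub <- as.matrix(m[, peps, drop = FALSE])
      agg <- if (aggregate == "sum") rowSums(sub) else rowMeans(sub)
      names(agg) <- m$sample_id
      af <- agg[fib_ids]; an <- agg[nof_ids]
      tibble::tibble(
        protease_gene = key$protease_gene,
        n_down = sum(d$fold_change < 1, na.rm = TRUE),
        n_up = sum(d$fold_change > 1, na.rm = TRUE),
        mean_fibrosis = mean(af),
        mean_nofibrosis = mean(an),
        fold_change = if (mean(an) > 0) mean(af) / mean(an) else NA_real_,
        p_value = wilcoxon_rank_sum(af, an)
      )
    }) |>
    dplyr::bind_rows()
  dplyr::arrange(res, .data$fold_change)
}

#' Synthetic demonstration peptides for protease matching
#'
#' A subset of the bundled panel with synthetic parent-protein positions
#' consistent with each sequence length, used to demonstrate cleavage-site
#' mapping against the synthetic association table. The coordinates do not
#' correspond to the true parent-protein positions, which were not
#' published.
#'
#' @return Peptide tibble with `peptide_id`, `gene_symbol`, `sequence`,
#'   `uniprot_id`, `start_pos`, `stop_pos`.
#' @export
protease_demo_peptides <- function() {
  panel <- fpp_bh29_panel()
  pos <- tibble::tribble(
    ~peptide_id, ~start_pos, ~stop_pos,
    "FPP16", 110, 129,  # HBA1, 20 aa
    "FPP25", 110, 131,  # HBA1, 22 aa
    "FPP10", 238, 263,  # COL2A1, 26 aa
    "FPP23", 301, 324,  # COL18A1, 24 aa
    "FPP02", 489, 528,  # COL1A2, 40 aa
    "FPP03", 700, 739,  # COL1A2, 40 aa
    "FPP14", 600, 628   # COL1A1, 29 aa
  )
  out <- dplyr::inner_join(
    panel[, c("peptide_id", "gene_symbol", "sequence", "uniprot_id")],
    pos, by = "peptide_id")
  validate_peptide_panel(out)
}

#' Bundled transcription of the published per-protease summary
#'
#' The reference per-protease regulation table (protease gene, counts of
#' down-/up-regulated cleavage events, fold change and printed group-average
#' intensities), one row per protease.
#'
#' @return Tibble of the reference protease summary.
#' @export
protease_summary_reference <- function() {
  readr::read_delim(system.file("extdata", "protease_summary_reference.tsv",
                                package = "fibropep"),
                    delim = "\t", show_col_types = FALSE, progress = FALSE)
}
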