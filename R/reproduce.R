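# Recompute the headline statistics of an ortholog/paralog paired-activity
# study directly from deposited S2/S3-dialect tables.

#' Recompute summary statistics from deposited paired tables
#'
#' Given an S2-dialect ortholog table and/or an S3-dialect paralog table,
#' recomputes the study-level quantities: row/pair/compound/target counts, the
#' Pearson correlation between the two affinity columns (orthologs), the
#' Spearman correlation between sequence identity and absolute difference
#' (paralogs), Laplace fits to both difference distributions, and the per-pair
#' mean signed difference table.
#'
#' @param s2_path path to an S2-dialect (ortholog) table, or `NULL`.
#' @param s3_path path to an S3-dialect (paralog) table, or `NULL`.
#' @return list with elements `orthologs` and `paralogs` (either may be
#'   `NULL`), each a list of computed statistics; ortholog element includes
#'   `per_pair`, a tibble of per-pair mean differences.
#' @export
reproduce_supp <- function(s2_path = NULL, s3_path = NULL) {
  out <- list(orthologs = NULL, paralogs = NULL)

  if (!is.null(s2_path)) {
    s2 <- read_paired_table(s2_path, dialect = "S2")
    per_pair <- dplyr::summarise(
      dplyr::group_by(s2, .data$pref_name, .data$accession_a, .data$accession_b),
      delta_mean = mean(.data$diff),
      n_compounds = dplyr::n(),
      .groups = "drop"
    )
    out$orthologs <- list(
      n_rows = nrow(s2),
      n_pairs = nrow(unique(s2[, c("accession_a", "accession_b")])),
      n_compounds = length(unique(s2$compound_id)),
      pearson = pearson_correlation(s2$afnty1, s2$afnty2),
      laplace = fit_laplace(s2$diff),
      per_pair = per_pair[order(-abs(per_pair$delta_mean)), ]
    )
  }

  if (!is.null(s3_path)) {
    s3 <- read_paired_table(s3_path, dialect = "S3")
    out$paralogs <- list(
      n_rows = nrow(s3),
      n_pairs = nrow(unique(s3[, c("accession_a", "accession_b")])),
      n_compounds = length(unique(s3$compound_id)),
      n_targets = length(unique(c(s3$accession_a, s3$accession_b))),
      identity_spearman = spearman_correlation(s3$identity_full, abs(s3$diff)),
      laplace = fit_laplace(s3$diff)
    )
  }
  out
}
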