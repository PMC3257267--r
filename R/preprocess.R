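# Filtering raw activity records to usable binding data and harmonizing all
# permitted result types onto the pKi scale.

PERMITTED_TYPES <- c("Ki", "IC50", "EC50", "pA2", "pKi")
CONCENTRATION_TYPES <- c("Ki", "IC50", "EC50")
UNIT_TO_MOLAR <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9, pM = 1e-12)

#' Filter activity records to usable binding data
#'
#' Keeps records from binding assays (assay type code `B`) whose result type is
#' one of Ki, IC50, EC50, pA2 or pKi and whose target mapping is unambiguous.
#' Every rejected record carries a machine-readable reason; rejection is data,
#' not an error. Known misannotated assays can be removed via `exclusion_list`.
#'
#' @param records tibble of activity records (see [read_activity_table()]).
#' @param permitted_types allowed `standard_type` values.
#' @param assay_type_code assay type code for binding assays.
#' @param exclusion_list character vector of `assay_id`s to drop (curated
#'   misannotations, e.g. functional data labelled as binding).
#' @return list with `kept` and `rejected` tibbles; `rejected` gains a
#'   `reason` column with values `"assay_type"`, `"standard_type"`,
#'   `"ambiguous_target"` or `"excluded"`.
#' @export
filter_binding <- function(records,
                           permitted_types = PERMITTED_TYPES,
                           assay_type_code = "B",
                           exclusion_list = NULL) {
  reason <- rep(NA_character_, nrow(records))
  unamb <- if ("target_unambiguous" %in% names(records)) {
    records$target_unambiguous
  } else {
    rep(TRUE, nrow(records))
  }
  reason[is.na(reason) & records$assay_id %in% exclusion_list] <- "excluded"
  reason[is.na(reason) & records$assay_type != assay_type_code] <- "assay_type"
  reason[is.na(reason) & !records$standard_type %in% permitted_types] <-
    "standard_type"
  reason[is.na(reason) & !unamb] <- "ambiguous_target"

  keep <- is.na(reason)
  rejected <- records[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  list(kept = records[keep, , drop = FALSE], rejected = rejected)
}

#' Convert a bioactivity value to the pKi scale
#'
#' Concentration results (Ki, IC50, EC50) are converted to molar and
#' negative-log10 transformed; pA2 and pKi, already on a negative-log scale,
#' pass through unchanged. IC50/EC50 are treated as pKi-comparable without
#' Cheng-Prusoff correction, consistent with pooling heterogeneous literature
#' data; restrict `standard_type` upstream for a Ki-only analysis.
#'
#' @param value numeric vector of reported values; must be positive for
#'   concentration types.
#' @param standard_type vector of result types among Ki, IC50, EC50, pA2, pKi.
#' @param units vector of unit labels (M, mM, uM, nM, pM) for concentration
#'   types; ignored for pA2/pKi.
#' @return numeric vector of pKi-comparable values.
#' @export
to_pki <- function(value, standard_type, units = NA_character_) {
  n <- max(length(value), length(standard_type), length(units))
  value <- rep_len(value, n)
  standard_type <- rep_len(standard_type, n)
  units <- rep_len(units, n)

  unknown <- setdiff(unique(standard_type), PERMITTED_TYPES)
  if (length(unknown) > 0) {
    stop("unsupported standard_type: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  conc <- standard_type %in% CONCENTRATION_TYPES
  if (any(conc & (is.na(value) | value <= 0))) {
    stop("concentration-type values must be positive", call. = FALSE)
  }
  bad_units <- conc & !units %in% names(UNIT_TO_MOLAR)
  if (any(bad_units)) {
    stop("unknown units for concentration type: ",
         paste(unique(units[bad_units]), collapse = ", "), call. = FALSE)
  }
  out <- value
  out[conc] <- -log10(value[conc] * UNIT_TO_MOLAR[units[conc]])
  unname(out)
}

#' Harmonize filtered activity records to pKi measurements
#'
#' Applies [to_pki()] to each record and returns one measurement per record.
#' Values outside the plausible pKi window \[0, 15\] trigger a warning but are
#' retained (observed affinities typically span pKi 4-12).
#'
#' @param records tibble of kept activity records.
#' @return tibble with `compound_id`, `target_id`, `target_accession`,
#'   `pref_name`, `species`, `assay_id`, `standard_type`, `pki`.
#' @export
harmonize <- function(records) {
  pki <- to_pki(records$value, records$standard_type, records$units)
  out_of_range <- sum(pki < 0 | pki > 15, na.rm = TRUE)
  if (out_of_range > 0) {
    warning(out_of_range, " measurement(s) outside the plausible pKi range [0, 15]",
            call. = FALSE)
  }
  tibble::tibble(
    compound_id = records$compound_id,
    target_id = records$target_id,
    target_accession = if ("target_accession" %in% names(records))
      records$target_accession else NA_character_,
    pref_name = if ("pref_name" %in% names(records))
      records$pref_name else NA_character_,
    species = records$species,
    assay_id = records$assay_id,
    standard_type = records$standard_type,
    pki = pki
  )
}

#' Remove exact duplicate measurements
#'
#' Collapses rows identical on (compound, target, assay, pKi rounded to
#' `rounding` decimals) to a single row. The rounding absorbs re-publication
#' duplicates that differ only by formatting while leaving genuine replicates
#' (different assays, or same assay with a real numeric difference) intact.
#'
#' @param measurements tibble of measurements (see [harmonize()]).
#' @param rounding decimals used for the duplicate key (default 2).
#' @return deduplicated tibble; attribute `n_removed` holds the removed count.
#' @export
deduplicate <- function(measurements, rounding = 2) {
  key <- paste(measurements$compound_id, measurements$target_id,
               measurements$assay_id,
               sprintf("%.*f", rounding, measurements$pki), sep = "\r")
  keep <- !duplicated(key)
  out <- measurements[keep, , drop = FALSE]
  n_removed <- sum(!keep)
  if (n_removed > 0) {
    message("deduplicate: removed ", n_removed, " duplicate row(s)")
  }
  attr(out, "n_removed") <- n_removed
  out
}

#' Aggregate measurements per group
#'
#' @param measurements measurement tibble.
#' @param by character vector of grouping columns.
#' @param how `"median"` (default) or `"mean"`.
#' @return tibble with the key columns, aggregated `pki` and group size `n`.
#' @export
aggregate_measurements <- function(measurements,
                                   by = c("compound_id", "target_id"),
                                   how = c("median", "mean")) {
  how <- match.arg(how)
  f <- if (how == "median") stats::median else mean
  if (nrow(measurements) == 0) {
    out <- measurements[, by, drop = FALSE]
    out$pki <- numeric(0)
    out$n <- integer(0)
    return(tibble::as_tibble(out))
  }
  dplyr::summarise(
    dplyr::group_by(measurements, dplyr::across(dplyr::all_of(by))),
    pki = f(.data$pki),
    n = dplyr::n(),
    .groups = "drop"
  )
}
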