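# Readers and writers for the external table dialects the pipeline consumes:
# raw activity exports, paired-activity supplementary dialects (S1/S2/S3),
# two-record gapped FASTA alignments, domain and binding-site annotations.

#' Column mapping for raw activity tables
#'
#' Describes which columns of a ChEMBL-style activity export hold each field of
#' an activity record. Defaults follow common export column names; override any
#' entry to fit a local dialect.
#'
#' @param compound_id,smiles,target_id,target_accession,pref_name,species,assay_id,assay_type,standard_type,value,units,target_unambiguous
#'   column names in the file header. `smiles`, `target_accession` and
#'   `target_unambiguous` may be `NA` when the export lacks them.
#' @return named character vector usable as the `dialect` argument of
#'   [read_activity_table()].
#' @export
activity_dialect <- function(compound_id = "molregno",
                             smiles = "canonical_smiles",
                             target_id = "tid",
                             target_accession = "accession",
                             pref_name = "pref_name",
                             species = "organism",
                             assay_id = "assay_id",
                             assay_type = "assay_type",
                             standard_type = "standard_type",
                             value = "standard_value",
                             units = "standard_units",
                             target_unambiguous = NA_character_) {
  c(compound_id = compound_id, smiles = smiles, target_id = target_id,
    target_accession = target_accession, pref_name = pref_name,
    species = species, assay_id = assay_id, assay_type = assay_type,
    standard_type = standard_type, value = value, units = units,
    target_unambiguous = target_unambiguous)
}

#' Read a raw activity table
#'
#' Reads a tab-delimited bioactivity export into a tibble of activity records.
#' Rows whose value column cannot be parsed as a number are not silently
#' dropped: they are collected, with their line numbers and a reason, in the
#' `errors` element.
#'
#' @param path path to a tab-delimited file with a header row.
#' @param dialect column mapping from [activity_dialect()].
#' @return list with elements `records` (tibble, one row per clean data row)
#'   and `errors` (tibble with `line`, `reason`).
#' @export
read_activity_table <- function(path, dialect = activity_dialect()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- dialect[!is.na(dialect)]
  # optional fields may be absent from both dialect and file
  optional <- c("smiles", "target_accession", "target_unambiguous")
  hard <- required[setdiff(names(required), optional)]
  missing_cols <- setdiff(unname(hard), names(raw))
  if (length(missing_cols) > 0) {
    stop("mapped column(s) absent from header: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  get_col <- function(field) {
    col <- dialect[[field]]
    if (is.na(col) || !col %in% names(raw)) rep(NA_character_, nrow(raw))
    else raw[[col]]
  }

  value_num <- parse_signed_num(get_col("value"))
  bad <- which(!is.na(get_col("value")) & is.na(value_num))

  records <- tibble::tibble(
    compound_id = get_col("compound_id"),
    smiles = get_col("smiles"),
    target_id = get_col("target_id"),
    target_accession = get_col("target_accession"),
    pref_name = get_col("pref_name"),
    species = get_col("species"),
    assay_id = get_col("assay_id"),
    assay_type = get_col("assay_type"),
    standard_type = get_col("standard_type"),
    value = value_num,
    units = get_col("units"),
    target_unambiguous = {
      x <- get_col("target_unambiguous")
      ifelse(is.na(x), TRUE, toupper(x) %in% c("TRUE", "T", "1", "YES", "Y"))
    }
  )

  errors <- tibble::tibble(
    line = bad + 1L, # +1 for the header row
    reason = rep("unparseable numeric value", length(bad))
  )
  list(records = records[setdiff(seq_len(nrow(records)), bad), , drop = FALSE],
       errors = errors)
}

s1_cols <- c("prefName", "tid", "Afnty1", "Afnty2", "molregno", "measured", "diff")
s2_cols <- c("prefName", "Uniprot1", "Uniprot2", "Afnty1", "Afnty2", "molregno")
s3_cols <- c("Accession1", "Accession2", "seqId", "molregno", "Afnty1", "Afnty2")

#' Read a paired-activity table (supplementary dialects S1/S2/S3)
#'
#' Reads one of the three deposited tab-delimited dialects: S1 (inter-assay
#' pairs), S2 (human-rat ortholog pairs) or S3 (human paralog pairs). Negative
#' numbers written with the Unicode minus sign are accepted. The signed
#' difference is always recomputed as `Afnty1 - Afnty2`; for S1, a stored
#' `diff` column is cross-checked and discrepancies beyond 1e-6 are reported in
#' the `discrepancies` attribute. For S3, the `seqId` scale (percent vs
#' fraction) is auto-detected (percent if any value exceeds 1) unless
#' overridden; identities are stored as fractions.
#'
#' @param path path to the tab-delimited file.
#' @param dialect one of `"S1"`, `"S2"`, `"S3"`.
#' @param seqid_scale `"auto"` (default), `"percent"` or `"fraction"`; S3 only.
#' @return tibble with the dialect's identifier columns plus numeric `afnty1`,
#'   `afnty2`, `diff` (and `identity_full` for S3). Attribute `discrepancies`
#'   (S1 only) lists rows whose stored diff disagrees with the recomputed one.
#' @export
read_paired_table <- function(path, dialect = c("S2", "S1", "S3"),
                              seqid_scale = c("auto", "percent", "fraction")) {
  dialect <- match.arg(dialect)
  seqid_scale <- match.arg(seqid_scale)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  want <- switch(dialect, S1 = s1_cols, S2 = s2_cols, S3 = s3_cols)
  missing_cols <- setdiff(want, names(raw))
  if (length(missing_cols) > 0) {
    stop("dialect ", dialect, ": column(s) absent from header: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }

  afnty1 <- parse_signed_num(raw$Afnty1)
  afnty2 <- parse_signed_num(raw$Afnty2)
  diff <- afnty1 - afnty2

  out <- switch(dialect,
    S1 = tibble::tibble(
      pref_name = raw$prefName, target_id = raw$tid,
      compound_id = raw$molregno,
      measured = parse_signed_num(raw$measured),
      afnty1 = afnty1, afnty2 = afnty2, diff = diff
    ),
    S2 = tibble::tibble(
      pref_name = raw$prefName,
      accession_a = raw$Uniprot1, accession_b = raw$Uniprot2,
      compound_id = raw$molregno,
      afnty1 = afnty1, afnty2 = afnty2, diff = diff
    ),
    S3 = {
      seqid <- parse_signed_num(raw$seqId)
      is_percent <- switch(seqid_scale,
        auto = any(seqid > 1, na.rm = TRUE),
        percent = TRUE,
        fraction = FALSE
      )
      tibble::tibble(
        accession_a = raw$Accession1, accession_b = raw$Accession2,
        compound_id = raw$molregno,
        identity_full = if (is_percent) seqid / 100 else seqid,
        afnty1 = afnty1, afnty2 = afnty2, diff = diff
      )
    }
  )

  if (dialect == "S1") {
    stored <- parse_signed_num(raw$diff)
    mism <- which(!is.na(stored) & abs(stored - diff) > 1e-6)
    attr(out, "discrepancies") <- tibble::tibble(
      line = mism + 1L, stored_diff = stored[mism], recomputed_diff = diff[mism]
    )
  }
  out
}

#' Read a two-record gapped FASTA alignment
#'
#' @param path path to a FASTA file holding exactly two aligned (equal-length,
#'   `-`-gapped) sequences.
#' @return list with uppercase character scalars `seq_a`, `seq_b` and the two
#'   record `names`.
#' @export
read_alignment_pair <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) != 2L) {
    stop("alignment FASTA must contain exactly 2 records, found ",
         length(set), call. = FALSE)
  }
  if (Biostrings::width(set)[1] != Biostrings::width(set)[2]) {
    stop("aligned sequences have unequal lengths (",
         Biostrings::width(set)[1], " vs ", Biostrings::width(set)[2], ")",
         call. = FALSE)
  }
  list(seq_a = toupper(as.character(set[[1]])),
       seq_b = toupper(as.character(set[[2]])),
       names = names(set))
}

#' Read domain annotations
#'
#' @param path TSV with columns `accession`, `pfam_acc`, `start`, `end`
#'   (1-based inclusive residue coordinates).
#' @return tibble with those columns; `start`/`end` integer.
#' @export
read_domain_table <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    accession = "c", pfam_acc = "c", start = "i", end = "i"
  ), progress = FALSE)
  bad <- which(out$start > out$end)
  if (length(bad) > 0) {
    stop("domain rows with start > end at line(s): ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  }
  out
}

#' Read binding-site residue positions
#'
#' @param path TSV with columns `accession` and `positions`, the latter a
#'   comma-separated list of 1-based residue positions.
#' @return tibble with `accession` and a list-column `positions` of integer
#'   vectors.
#' @export
read_site_table <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    accession = "c", positions = "c"
  ), progress = FALSE)
  tibble::tibble(
    accession = raw$accession,
    positions = lapply(strsplit(raw$positions, ","), function(x) {
      as.integer(trimws(x))
    })
  )
}

#' Write a species-specificity screen report
#'
#' Writes the screen result as a TSV with columns `name`, `delta_mean`,
#' `n_compounds`, `n_chemotypes`, `mapped_domain`, `p_adj`, `flagged`, sorted
#' by adjusted p-value ascending. Absent chemotype counts are written as empty
#' cells, not zeros.
#'
#' @param results tibble of screen results (see [mwu_screen()]); columns
#'   `n_chemotypes` and `mapped_domain` are optional.
#' @param path output path.
#' @return the written tibble, invisibly.
#' @export
write_screen_table <- function(results, path) {
  need <- c("name", "delta_mean", "n_compounds", "p_adj", "flagged")
  missing_cols <- setdiff(need, names(results))
  if (length(missing_cols) > 0) {
    stop("results lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::tibble(
    name = results$name,
    delta_mean = results$delta_mean,
    n_compounds = results$n_compounds,
    n_chemotypes = if ("n_chemotypes" %in% names(results))
      results$n_chemotypes else NA_integer_,
    mapped_domain = if ("mapped_domain" %in% names(results))
      results$mapped_domain else NA_character_,
    p_adj = results$p_adj,
    flagged = results$flagged
  )
  out <- out[order(out$p_adj), , drop = FALSE]
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(out)
}

#' Read back a screen report written by [write_screen_table()]
#' @param path path to the TSV.
#' @return tibble with the report columns.
#' @export
read_screen_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    name = "c", delta_mean = "d", n_compounds = "i", n_chemotypes = "i",
    mapped_domain = "c", p_adj = "d", flagged = "l"
  ), progress = FALSE)
}

#' Write a paired-activity table in a supplementary dialect
#'
#' Inverse of [read_paired_table()] for the S2 and S3 dialects; used to emit
#' synthetic universes in the deposited formats.
#'
#' @param paired tibble as returned by [read_paired_table()].
#' @param path output path.
#' @param dialect `"S2"` or `"S3"`.
#' @param seqid_percent write S3 identities as percent (default) or fraction.
#' @return `path`, invisibly.
#' @export
write_paired_table <- function(paired, path, dialect = c("S2", "S3"),
                               seqid_percent = TRUE) {
  dialect <- match.arg(dialect)
  out <- switch(dialect,
    S2 = tibble::tibble(
      prefName = paired$pref_name,
      Uniprot1 = paired$accession_a, Uniprot2 = paired$accession_b,
      Afnty1 = paired$afnty1, Afnty2 = paired$afnty2,
      molregno = paired$compound_id
    ),
    S3 = tibble::tibble(
      Accession1 = paired$accession_a, Accession2 = paired$accession_b,
      seqId = if (seqid_percent) paired$identity_full * 100
              else paired$identity_full,
      molregno = paired$compound_id,
      Afnty1 = paired$afnty1, Afnty2 = paired$afnty2
    )
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
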