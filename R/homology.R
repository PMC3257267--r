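# Pairing activities across homologous targets and sequence-identity metrics
# at three resolutions: full sequence, binding-site-containing domain, and
# binding-site residues.

#' Pair activities across homologous targets
#'
#' For each homology pair and each compound measured on both members, emits one
#' paired activity with the signed difference `diff = afnty1 - afnty2`.
#' Measurements are aggregated (median by default) per (compound, target)
#' before pairing, so multi-assay compounds contribute one value per side. For
#' ortholog pairs the orientation is fixed: member `a` is the human target, so
#' a positive difference means higher affinity for the human protein.
#'
#' @param measurements harmonized measurement tibble with a `target_accession`
#'   (or `target_id`) column identifying the protein.
#' @param pairs tibble of homology pairs with columns `accession_a`,
#'   `accession_b`, `relation` (`"ortholog"`/`"paralog"`) and optionally
#'   `pair_id`, `pref_name`, `identity_full`.
#' @param how aggregation for multi-measurement sides, `"median"` or `"mean"`.
#' @param key measurement column naming the protein; default
#'   `"target_accession"`.
#' @return tibble with pair metadata, `compound_id`, `afnty1`, `afnty2`,
#'   `diff`.
#' @export
pair_activities <- function(measurements, pairs, how = c("median", "mean"),
                            key = "target_accession") {
  how <- match.arg(how)
  stopifnot(key %in% names(measurements))
  stopifnot(all(c("accession_a", "accession_b") %in% names(pairs)))
  if (any(pairs$accession_a == pairs$accession_b)) {
    stop("homology pair with identical accessions", call. = FALSE)
  }
  agg <- aggregate_measurements(measurements, by = c("compound_id", key),
                                how = how)
  names(agg)[names(agg) == key] <- "accession"

  meta_cols <- intersect(c("pair_id", "pref_name", "relation", "identity_full"),
                         names(pairs))
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- agg[agg$accession == pairs$accession_a[i], c("compound_id", "pki")]
    b <- agg[agg$accession == pairs$accession_b[i], c("compound_id", "pki")]
    m <- dplyr::inner_join(a, b, by = "compound_id", suffix = c("_a", "_b"))
    if (nrow(m) == 0) next
    row <- tibble::tibble(
      accession_a = pairs$accession_a[i],
      accession_b = pairs$accession_b[i],
      compound_id = m$compound_id,
      afnty1 = m$pki_a,
      afnty2 = m$pki_b,
      diff = m$pki_a - m$pki_b
    )
    for (mc in meta_cols) row[[mc]] <- pairs[[mc]][i]
    out[[i]] <- row
  }
  out <- dplyr::bind_rows(out)
  if (nrow(out) == 0) {
    out <- tibble::tibble(accession_a = character(), accession_b = character(),
                          compound_id = character(), afnty1 = numeric(),
                          afnty2 = numeric(), diff = numeric())
  }
  out
}

#' Randomly assign signs to paralog activity differences
#'
#' Paralog pairs have no natural orientation, unlike ortholog pairs where the
#' human member comes first. To make the paralog difference distribution
#' comparable with the species-grouped ortholog one, each difference is
#' multiplied by an independent fair coin flip in {-1, +1}. Magnitudes are
#' preserved and the draw is reproducible given the seed.
#'
#' @param paired paired-activity tibble with a `diff` column; `relation`, if
#'   present, must be `"paralog"` throughout.
#' @param seed integer seed.
#' @return the tibble with `diff` sign-randomized (and `afnty1`/`afnty2` left
#'   untouched).
#' @export
assign_random_signs <- function(paired, seed) {
  if ("relation" %in% names(paired) && any(paired$relation != "paralog")) {
    stop("random sign assignment applies to paralog pairs only", call. = FALSE)
  }
  signs <- with_seed(seed, sample(c(-1, 1), nrow(paired), replace = TRUE))
  paired$diff <- paired$diff * signs
  paired
}

#' Sequence identity of a gapped alignment
#'
#' The fraction of alignment columns in which both sequences carry identical
#' residues, taken over the overlapping region only: columns where either
#' sequence has a gap are excluded from both numerator and denominator.
#'
#' @param seq_a,seq_b equal-length gapped residue strings (gap symbol `-`), or
#'   a list with elements `seq_a`/`seq_b` as first argument.
#' @return identity fraction in \[0, 1\].
#' @export
sequence_identity <- function(seq_a, seq_b = NULL) {
  if (is.list(seq_a) && is.null(seq_b)) {
    seq_b <- seq_a$seq_b
    seq_a <- seq_a$seq_a
  }
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1]]
  if (length(a) != length(b)) {
    stop("aligned sequences have unequal lengths", call. = FALSE)
  }
  overlap <- a != "-" & b != "-"
  if (!any(overlap)) {
    stop("alignment has no overlap columns; identity undefined", call. = FALSE)
  }
  sum(a[overlap] == b[overlap]) / sum(overlap)
}

#' Global pairwise alignment (Needleman-Wunsch, linear gap penalty)
#'
#' Small utility aligner for domain subsequences of synthetic universes; real
#' analyses consume precomputed alignments. Ties in the dynamic program are
#' broken deterministically: diagonal (match/mismatch) preferred, then up
#' (gap in `seq_b`), then left.
#'
#' @param seq_a,seq_b ungapped residue strings.
#' @param match match score (default +1).
#' @param mismatch mismatch score (default -1).
#' @param gap per-residue gap score (default -2).
#' @return list with gapped `seq_a`, `seq_b` and the optimal `score`.
#' @export
global_align <- function(seq_a, seq_b, match = 1, mismatch = -1, gap = -2) {
  if (nchar(seq_a) == 0 || nchar(seq_b) == 0) {
    stop("sequences must be nonempty", call. = FALSE)
  }
  a <- strsplit(toupper(seq_a), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(seq_b), "", fixed = TRUE)[[1]]
  n <- length(a); m <- length(b)
  score <- matrix(0, n + 1, m + 1)
  score[, 1] <- gap * (0:n)
  score[1, ] <- gap * (0:m)
  for (i in seq_len(n)) {
    sub <- ifelse(a[i] == b, match, mismatch)
    for (j in seq_len(m)) {
      score[i + 1, j + 1] <- max(score[i, j] + sub[j],
                                 score[i, j + 1] + gap,
                                 score[i + 1, j] + gap)
    }
  }
  # traceback with the fixed preference diagonal > up > left
  out_a <- character(0); out_b <- character(0)
  i <- n; j <- m
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        score[i + 1, j + 1] ==
          score[i, j] + (if (a[i] == b[j]) match else mismatch)) {
      out_a <- c(a[i], out_a); out_b <- c(b[j], out_b)
      i <- i - 1; j <- j - 1
    } else if (i > 0 && score[i + 1, j + 1] == score[i, j + 1] + gap) {
      out_a <- c(a[i], out_a); out_b <- c("-", out_b)
      i <- i - 1
    } else {
      out_a <- c("-", out_a); out_b <- c(b[j], out_b)
      j <- j - 1
    }
  }
  list(seq_a = paste(out_a, collapse = ""),
       seq_b = paste(out_b, collapse = ""),
       score = score[n + 1, m + 1])
}

#' Sequence identity of the binding-site-containing domain
#'
#' Extracts the residue range annotated for `mapped_acc` from each (ungapped)
#' sequence, globally aligns the two domain subsequences and returns the
#' identity of that alignment.
#'
#' @param seq_a,seq_b ungapped full-length sequences.
#' @param annot_a,annot_b domain annotation tibbles (columns `pfam_acc`,
#'   `start`, `end`) for the two proteins.
#' @param mapped_acc Pfam accession of the binding-site-containing domain.
#' @param ... scoring parameters passed to [global_align()].
#' @return identity fraction in \[0, 1\].
#' @export
domain_identity <- function(seq_a, seq_b, annot_a, annot_b, mapped_acc, ...) {
  pick <- function(annot, seq, side) {
    hit <- which(annot$pfam_acc == mapped_acc)
    if (length(hit) == 0) {
      stop("domain ", mapped_acc, " not annotated on side ", side,
           call. = FALSE)
    }
    hit <- hit[1]
    substr(seq, annot$start[hit], annot$end[hit])
  }
  da <- pick(annot_a, seq_a, "a")
  db <- pick(annot_b, seq_b, "b")
  sequence_identity(global_align(da, db, ...))
}

#' Sequence identity over binding-site residues
#'
#' Compares residues at pre-corresponded binding-site positions: `positions_a`
#' and `positions_b` are equally long ordered lists of 1-based positions, the
#' i-th entries corresponding to one another (correspondence established
#' upstream, e.g. from a family alignment).
#'
#' @param seq_a,seq_b ungapped sequences.
#' @param positions_a,positions_b integer vectors of 1-based positions.
#' @return fraction of position pairs with identical residues.
#' @export
site_identity <- function(seq_a, seq_b, positions_a, positions_b) {
  if (length(positions_a) != length(positions_b)) {
    stop("site position lists have unequal lengths", call. = FALSE)
  }
  if (length(positions_a) == 0) {
    stop("site position lists are empty", call. = FALSE)
  }
  if (any(positions_a < 1 | positions_a > nchar(seq_a)) ||
      any(positions_b < 1 | positions_b > nchar(seq_b))) {
    stop("site position out of sequence range", call. = FALSE)
  }
  ra <- substring(toupper(seq_a), positions_a, positions_a)
  rb <- substring(toupper(seq_b), positions_b, positions_b)
  mean(ra == rb)
}
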