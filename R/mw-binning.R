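# Molecular-weight binning of absolute binding differences: do larger
# ligands, which rely on more contacts with the protein, diverge more between
# homologous targets? Compounds are split into equal-count MW bins and the
# bins compared by one-way ANOVA with neighbor-restricted multiple testing.

#' Adaptive (equal-count) binning
#'
#' Quantile-based edges producing `k` groups of (up to boundary ties) equal
#' size. Values equal to an interior edge go to the lower bin. Bin assignment
#' is monotone in the value.
#'
#' @param values numeric vector, `length(values) >= k`, not all equal.
#' @param k number of bins (default 5).
#' @return list with `bins` (integer assignment per value) and `lower_edges`
#'   (numeric, length `k`; reported under each box in figures).
#' @export
adaptive_bins <- function(values, k = 5) {
  values <- as.numeric(values)
  if (length(values) < k) stop("need at least k values", call. = FALSE)
  edges <- stats::quantile(values, probs = seq(0, 1, length.out = k + 1),
                           names = FALSE)
  interior <- edges[2:k]
  if (any(duplicated(edges)) && length(unique(values)) == 1) {
    stop("degenerate quantiles: all values equal", call. = FALSE)
  }
  if (length(unique(interior)) < length(interior)) {
    stop("degenerate quantiles: ties collapse bin edges", call. = FALSE)
  }
  bins <- vapply(values, function(x) sum(interior < x), 0L) + 1L
  list(bins = bins, lower_edges = edges[1:k])
}

#' One-way ANOVA across MW bins with neighbor comparisons
#'
#' Fits a one-way ANOVA of the absolute binding difference on the bin factor
#' and reports the F test plus multiple-testing-adjusted comparisons
#' restricted to neighbouring bins. The default neighbor procedure is Tukey's
#' honest significant difference filtered to adjacent bins; pairwise Welch
#' t-tests with Holm adjustment are available via `method`.
#'
#' @param absdiff numeric vector of absolute differences.
#' @param bins integer bin assignment (from [adaptive_bins()]).
#' @param method `"tukey"` (default) or `"welch_holm"`.
#' @return list with `f_statistic`, `p_value`, `adjacent` (tibble: `bin_pair`,
#'   `estimate`, `p_adj`, `stars`), `excluded_bins`.
#' @export
mw_anova <- function(absdiff, bins, method = c("tukey", "welch_holm")) {
  method <- match.arg(method)
  stopifnot(length(absdiff) == length(bins))
  sizes <- table(bins)
  small <- as.integer(names(sizes)[sizes < 2])
  if (length(small) > 0) {
    message("mw_anova: excluding bin(s) with < 2 values: ",
            paste(small, collapse = ", "))
    keep <- !bins %in% small
    absdiff <- absdiff[keep]
    bins <- bins[keep]
  }
  ub <- sort(unique(bins))
  if (length(ub) < 2) stop("need >= 2 nonempty bins", call. = FALSE)
  g <- factor(bins, levels = ub)
  fit <- stats::aov(absdiff ~ g)
  an <- summary(fit)[[1]]
  f_stat <- an[["F value"]][1]
  p_val <- an[["Pr(>F)"]][1]

  adjacent_pairs <- cbind(ub[-length(ub)], ub[-1])
  if (method == "tukey") {
    tk <- stats::TukeyHSD(fit)$g
    want <- paste(adjacent_pairs[, 2], adjacent_pairs[, 1], sep = "-")
    tk <- tk[rownames(tk) %in% want, , drop = FALSE]
    adj <- tibble::tibble(
      bin_pair = paste(adjacent_pairs[, 1], adjacent_pairs[, 2], sep = " vs "),
      estimate = tk[want, "diff"],
      p_adj = tk[want, "p adj"],
      stars = p_stars(tk[want, "p adj"])
    )
  } else {
    p_raw <- apply(adjacent_pairs, 1, function(ij) {
      stats::t.test(absdiff[bins == ij[1]], absdiff[bins == ij[2]])$p.value
    })
    est <- apply(adjacent_pairs, 1, function(ij) {
      mean(absdiff[bins == ij[2]]) - mean(absdiff[bins == ij[1]])
    })
    p_adj <- stats::p.adjust(p_raw, method = "holm")
    adj <- tibble::tibble(
      bin_pair = paste(adjacent_pairs[, 1], adjacent_pairs[, 2], sep = " vs "),
      estimate = est, p_adj = p_adj, stars = p_stars(p_adj)
    )
  }
  list(f_statistic = f_stat, p_value = p_val, adjacent = adj,
       excluded_bins = small)
}

#' Correlation between molecular weight and absolute binding difference
#'
#' Spearman rank correlation of ligand molecular weight with the absolute
#' difference in binding affinity across a homologous target pair.
#'
#' @param mol_weights,absdiffs paired numeric vectors.
#' @return list with `statistic` (Rho), `p_value`, `method`.
#' @export
mw_effect_correlation <- function(mol_weights, absdiffs) {
  spearman_correlation(mol_weights, absdiffs)
}

#' Write the MW bin report as TSV
#'
#' @param absdiff,bins,lower_edges data as produced by [adaptive_bins()].
#' @param anova result of [mw_anova()] on the same data.
#' @param path output path.
#' @return the report tibble, invisibly.
#' @export
write_mw_bin_report <- function(absdiff, bins, lower_edges, anova, path) {
  ub <- sort(unique(bins))
  rows <- lapply(seq_along(ub), function(i) {
    v <- absdiff[bins == ub[i]]
    tibble::tibble(
      bin = ub[i], lower_edge = lower_edges[ub[i]], n = length(v),
      median = stats::median(v),
      q1 = unname(stats::quantile(v, 0.25)), q3 = unname(stats::quantile(v, 0.75)),
      adjacent_pair = if (i < length(ub)) anova$adjacent$bin_pair[i] else NA,
      p_adj = if (i < length(ub)) anova$adjacent$p_adj[i] else NA,
      stars = if (i < length(ub)) anova$adjacent$stars[i] else NA
    )
  })
  out <- dplyr::bind_rows(rows)
  readr::write_tsv(out, path, na = "", progress = FALSE)
  invisible(out)
}
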