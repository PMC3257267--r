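# The species-specificity screen and the distribution-level statistics used
# throughout the analysis: Mann-Whitney screen against the inter-assay null,
# Laplace fits, correlation tests, variance and normality tests, and the
# identity-binned divergence summary.

#' Screen target pairs for species-specific pharmacology
#'
#' For each homology pair, compares the distribution of its per-compound
#' binding differences against the composite inter-assay control with a
#' two-sided Mann-Whitney U test (exact where sample size and ties permit,
#' normal approximation otherwise, as `stats::wilcox.test` decides). Raw
#' p-values are Bonferroni-adjusted by the number of pairs actually tested,
#' i.e. pairs passing the `min_n` compound floor.
#'
#' @param paired paired-activity tibble (see [pair_activities()]); pairs are
#'   identified by `pair_id` if present, else by `accession_a`/`accession_b`.
#' @param control `control_sample` object (see [build_control()]).
#' @param alpha family-wise significance level (default 0.05).
#' @param min_n minimum compounds per pair to test (default 5); smaller pairs
#'   are excluded and listed in the `excluded` attribute.
#' @return tibble with one row per tested pair: `name`, `n_compounds`,
#'   `delta_mean`, `u_stat`, `p_raw`, `p_adj`, `flagged`, plus pair metadata.
#' @export
mwu_screen <- function(paired, control, alpha = 0.05, min_n = 5) {
  stopifnot(inherits(control, "control_sample"))
  if (length(control$diffs) == 0) stop("empty control", call. = FALSE)
  pair_key <- if ("pair_id" %in% names(paired)) {
    paired$pair_id
  } else {
    paste(paired$accession_a, paired$accession_b, sep = "|")
  }
  name <- if ("pref_name" %in% names(paired)) paired$pref_name else pair_key
  groups <- split(seq_len(nrow(paired)), pair_key)
  sizes <- vapply(groups, length, 1L)
  tested <- groups[sizes >= min_n]
  excluded <- tibble::tibble(pair = names(groups)[sizes < min_n],
                             n_compounds = unname(sizes[sizes < min_n]))
  n_tests <- length(tested)
  rows <- lapply(names(tested), function(k) {
    idx <- tested[[k]]
    d <- paired$diff[idx]
    wt <- suppressWarnings(
      stats::wilcox.test(d, control$diffs, alternative = "two.sided")
    )
    tibble::tibble(
      pair = k,
      name = name[idx[1]],
      n_compounds = length(d),
      delta_mean = mean(d),
      u_stat = unname(wt$statistic),
      p_raw = wt$p.value
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(pair = character(), name = character(),
                          n_compounds = integer(), delta_mean = numeric(),
                          u_stat = numeric(), p_raw = numeric())
  }
  out$p_adj <- pmin(1, out$p_raw * n_tests)
  out$flagged <- out$p_adj < alpha
  attr(out, "excluded") <- excluded
  attr(out, "n_tests") <- n_tests
  out
}

#' Maximum-likelihood Laplace fit
#'
#' The Laplace (double-exponential) MLE in closed form: location is the sample
#' median, scale b the mean absolute deviation from the median.
#'
#' @param x numeric vector, length >= 2, not all equal.
#' @return object of class `laplace_fit`: list with `location`, `scale`, `n`.
#' @export
fit_laplace <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) stop("need at least 2 values", call. = FALSE)
  location <- stats::median(x)
  scale <- mean(abs(x - location))
  if (scale == 0) {
    stop("degenerate fit: all values identical (scale 0)", call. = FALSE)
  }
  structure(list(location = location, scale = scale, n = length(x)),
            class = "laplace_fit")
}

#' @export
print.laplace_fit <- function(x, ...) {
  cat(sprintf("Laplace fit: location %.4f, scale b %.4f (n = %d)\n",
              x$location, x$scale, x$n))
  invisible(x)
}

test_result <- function(statistic, p_value, method) {
  list(statistic = unname(statistic), p_value = unname(p_value),
       method = method)
}

#' Pearson correlation test
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list with `statistic` (r), `p_value`, `method`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("need equal-length vectors of length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  test_result(unname(ct$estimate), ct$p.value, "pearson")
}

#' Spearman rank correlation test
#'
#' Rho on average ranks (ties share their mean rank); two-sided p-value via
#' `stats::cor.test`, which uses the t approximation in the presence of ties.
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return list with `statistic` (Rho), `p_value`, `method`.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    stop("need equal-length vectors of length >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  test_result(unname(ct$estimate), ct$p.value, "spearman")
}

#' Levene's test for equal spread (Brown-Forsythe variant)
#'
#' Tests equality of spread between two groups using absolute deviations from
#' the group medians, the robust Brown-Forsythe form.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return list with `statistic` (F), `p_value`, `method`.
#' @export
levene_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs >= 2 values", call. = FALSE)
  }
  values <- c(a, b)
  group <- factor(rep(c("a", "b"), c(length(a), length(b))))
  lt <- car::leveneTest(values, group, center = stats::median)
  test_result(lt[["F value"]][1], lt[["Pr(>F)"]][1], "levene_brown_forsythe")
}

#' Anderson-Darling test of normality
#'
#' A-squared statistic against the normal family with estimated mean and
#' standard deviation.
#'
#' @param x numeric vector, n >= 8, non-constant.
#' @return list with `statistic` (A^2), `p_value`, `method`.
#' @export
anderson_darling_normality <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 8) stop("need n >= 8", call. = FALSE)
  if (stats::sd(x) == 0) stop("constant vector", call. = FALSE)
  at <- nortest::ad.test(x)
  test_result(at$statistic, at$p.value, "anderson_darling")
}

#' Divergence summarized in sequence-identity bins
#'
#' Bins homologous pairs by percent sequence identity (default edges 0, 20,
#' 40, 60, 80, 100; half-open bins \[lo, hi) except the last, \[80, 100\]) and
#' summarizes the absolute binding difference per bin. Adjacent bins are
#' compared with two-sided Mann-Whitney tests, Holm-adjusted, with stars at
#' the 0.05 / 0.01 / 0.001 levels. The mean absolute inter-assay difference
#' can be supplied as the reference line value.
#'
#' @param identity identities, fractions or percent (auto-scaled to percent
#'   when all values are <= 1).
#' @param diff signed differences; summaries use `abs(diff)`.
#' @param edges bin edges in percent.
#' @param level label of the comparison resolution (`"full"`, `"domain"`,
#'   `"site"`); recorded, not interpreted.
#' @param reference_diffs optional numeric vector (e.g. control diffs); its
#'   mean absolute value is reported as `reference`.
#' @return list with `bins` (tibble: `bin`, `lo`, `hi`, `n`, `median`, `q1`,
#'   `q3`), `adjacent` (tibble: `bin_pair`, `p_raw`, `p_adj`, `stars`),
#'   `level`, `reference`.
#' @export
identity_bin_summary <- function(identity, diff,
                                 edges = c(0, 20, 40, 60, 80, 100),
                                 level = c("full", "domain", "site"),
                                 reference_diffs = NULL) {
  level <- match.arg(level)
  stopifnot(length(identity) == length(diff))
  if (all(identity <= 1, na.rm = TRUE)) identity <- identity * 100
  k <- length(edges) - 1L
  # half-open [lo, hi), last bin closed
  bin <- findInterval(identity, edges, rightmost.closed = TRUE)
  bin[bin < 1 | bin > k] <- NA_integer_
  absdiff <- abs(diff)

  bins <- lapply(seq_len(k), function(i) {
    v <- absdiff[!is.na(bin) & bin == i]
    tibble::tibble(
      bin = sprintf("%g-%g", edges[i], edges[i + 1]),
      lo = edges[i], hi = edges[i + 1], n = length(v),
      median = if (length(v)) stats::median(v) else NA_real_,
      q1 = if (length(v)) unname(stats::quantile(v, 0.25)) else NA_real_,
      q3 = if (length(v)) unname(stats::quantile(v, 0.75)) else NA_real_
    )
  })
  bins <- dplyr::bind_rows(bins)

  occupied <- which(bins$n > 0)
  adj <- NULL
  if (length(occupied) >= 2) {
    pairs_idx <- cbind(occupied[-length(occupied)], occupied[-1])
    # only truly adjacent occupied bins are compared
    pairs_idx <- pairs_idx[pairs_idx[, 2] - pairs_idx[, 1] == 1, , drop = FALSE]
    if (nrow(pairs_idx) > 0) {
      p_raw <- apply(pairs_idx, 1, function(ij) {
        suppressWarnings(stats::wilcox.test(
          absdiff[!is.na(bin) & bin == ij[1]],
          absdiff[!is.na(bin) & bin == ij[2]],
          alternative = "two.sided"
        )$p.value)
      })
      p_adj <- stats::p.adjust(p_raw, method = "holm")
      adj <- tibble::tibble(
        bin_pair = paste(bins$bin[pairs_idx[, 1]], bins$bin[pairs_idx[, 2]],
                         sep = " vs "),
        p_raw = p_raw, p_adj = p_adj, stars = p_stars(p_adj)
      )
    }
  }
  if (is.null(adj)) {
    adj <- tibble::tibble(bin_pair = character(), p_raw = numeric(),
                          p_adj = numeric(), stars = character())
  }
  list(bins = bins, adjacent = adj, level = level,
       reference = if (is.null(reference_diffs)) NA_real_
                   else mean(abs(reference_diffs)))
}
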