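mk_control <- function(diffs, seed = 1) {
  structure(list(diffs = diffs, n_human = length(diffs) %/% 2,
                 n_rat = length(diffs) - length(diffs) %/% 2,
                 seed = seed, provenance = "test"),
            class = "control_sample")
}

test_that("screen flags shifted pairs and spares null pairs", {
  set.seed(31)
  control <- mk_control(rlaplace(3000, 0, 0.45))
  paired <- dplyr::bind_rows(
    tibble::tibble(pair_id = "null_pair",
                   diff = sample(control$diffs, 40)),
    tibble::tibble(pair_id = "shifted_pair",
                   diff = 1.0 + rlaplace(50, 0, 0.45)),
    tibble::tibble(pair_id = "tiny_pair", diff = rep(2, 3)) # below min_n
  )
  res <- mwu_screen(paired, control, alpha = 0.05, min_n = 5)
  expect_equal(attr(res, "n_tests"), 2L)
  expect_equal(attr(res, "excluded")$pair, "tiny_pair")
  expect_true(res$flagged[res$pair == "shifted_pair"])
  expect_false(res$flagged[res$pair == "null_pair"])
  expect_gt(res$p_raw[res$pair == "null_pair"], 0.1)
  expect_equal(res$delta_mean[res$pair == "shifted_pair"],
               mean(paired$diff[paired$pair_id == "shifted_pair"]))

  # delta_mean is the plain mean of the pair's differences
  one <- mwu_screen(tibble::tibble(pair_id = "p", diff = c(0.5, 0.7)),
                    control, min_n = 2)
  expect_equal(one$delta_mean, 0.6)
})

test_that("Bonferroni adjustment never rescues a pair and respects two-sidedness", {
  set.seed(77)
  control <- mk_control(rlaplace(1000, 0, 0.5))
  paired <- dplyr::bind_rows(lapply(1:8, function(i) {
    tibble::tibble(pair_id = sprintf("P%02d", i),
                   diff = rlaplace(20, (i - 4) * 0.3, 0.5))
  }))
  res <- mwu_screen(paired, control)
  expect_true(all(res$p_adj >= res$p_raw))
  # flagged under adjustment is a subset of flagged under raw p
  expect_true(all(res$pair[res$flagged] %in% res$pair[res$p_raw < 0.05]))

  # global sign flip of pairs and control leaves the screen unchanged
  flipped <- paired; flipped$diff <- -flipped$diff
  res_f <- mwu_screen(flipped, mk_control(-control$diffs))
  expect_equal(res_f$p_raw, res$p_raw, tolerance = 1e-12)
  expect_identical(res_f$flagged, res$flagged)
})

test_that("Laplace MLE has its closed form and recovers known scales", {
  fit <- fit_laplace(c(-1, 0, 1))
  expect_equal(fit$location, 0)
  expect_equal(fit$scale, 2 / 3)
  expect_error(fit_laplace(c(5, 5, 5)), "degenerate")
  expect_error(fit_laplace(3), "at least 2")

  set.seed(55)
  for (b in c(0.5, 0.7, 1.3)) {
    x <- rlaplace(1e4, 2, b)
    fit <- fit_laplace(x)
    expect_lt(abs(fit$scale - b) / b, 0.05)
    expect_lt(abs(fit$location - 2), 0.05)
  }
})

test_that("correlation tests match hand-computed values and reject degeneracy", {
  x <- c(0, 1, 2, 3, 4)
  expect_equal(pearson_correlation(x, 2 * x + 1)$statistic, 1)
  expect_equal(pearson_correlation(x, -x)$statistic, -1)
  # r = 0 by hand: cov((0,1,2),(0,1,0)) = 0
  expect_equal(pearson_correlation(c(0, 1, 2), c(0, 1, 0))$statistic, 0)
  expect_error(pearson_correlation(c(1, 1, 1), x[1:3]), "zero variance")
  expect_error(pearson_correlation(1:2, 1:2), "length >= 3")

  expect_equal(spearman_correlation(x, exp(x))$statistic, 1)
  expect_equal(spearman_correlation(x, rev(x))$statistic, -1)
})

test_that("spearman tie handling matches explicit average ranks", {
  set.seed(8)
  x <- sample(1:5, 20, replace = TRUE) # plenty of ties
  y <- sample(1:4, 20, replace = TRUE)
  rho <- spearman_correlation(x, y)$statistic
  # oracle: Pearson correlation of average ranks
  oracle <- stats::cor(rank(x, ties.method = "average"),
                       rank(y, ties.method = "average"))
  expect_equal(rho, oracle, tolerance = 1e-12)
})

test_that("variance and normality tests behave on known inputs", {
  set.seed(12)
  a <- rnorm(500)
  lv_same <- levene_test(a, a)
  expect_gt(lv_same$p_value, 0.99)
  lv_diff <- levene_test(rnorm(500, 0, 1), rnorm(500, 0, 3))
  expect_lt(lv_diff$p_value, 0.001)
  expect_error(levene_test(1, c(1, 2)), ">= 2")

  expect_error(anderson_darling_normality(rnorm(5)), "n >= 8")
  expect_error(anderson_darling_normality(rep(1, 100)), "constant")
  # calibration and power at n = 5000 over fixed seeds
  normal_pass <- laplace_reject <- 0
  for (s in 1:20) {
    set.seed(s)
    if (anderson_darling_normality(rnorm(5000))$p_value > 0.05)
      normal_pass <- normal_pass + 1
    if (anderson_darling_normality(rlaplace(5000, 0, 1))$p_value < 0.01)
      laplace_reject <- laplace_reject + 1
  }
  expect_gte(normal_pass, 17)
  expect_gte(laplace_reject, 19)
})

test_that("identity bins partition [0, 100] with the stated edge convention", {
  # a value exactly at 80 belongs to the closed last bin
  out <- identity_bin_summary(c(10, 25, 80, 95, 100), c(1, 2, 3, 4, 5))
  expect_equal(out$bins$n, c(1, 1, 0, 0, 3))
  expect_equal(out$bins$bin[5], "80-100")
  # fractions are auto-scaled to percent
  frac <- identity_bin_summary(c(0.1, 0.95), c(1, 1))
  expect_equal(frac$bins$n[c(1, 5)], c(1, 1))
  # all pairs in one bin -> no adjacent tests
  solo <- identity_bin_summary(rep(85, 10), rnorm(10))
  expect_equal(nrow(solo$adjacent), 0L)
})

test_that("identity bins detect rising divergence below high identity", {
  set.seed(91)
  n <- 400
  ident <- runif(n, 40, 100)
  # divergence grows below 80% identity, flat above
  scale <- ifelse(ident >= 80, 0.3, 0.3 + (80 - ident) * 0.05)
  diffs <- rlaplace(n, 0, scale)
  out <- identity_bin_summary(ident, diffs, reference_diffs = rlaplace(1000, 0, 0.3))
  med <- out$bins$median
  expect_gt(med[out$bins$bin == "60-80"], med[out$bins$bin == "80-100"])
  expect_gt(med[out$bins$bin == "40-60"], med[out$bins$bin == "60-80"])
  expect_false(is.na(out$reference))
  # at least the steepest adjacent contrast is starred
  expect_true(any(out$adjacent$stars != ""))
})
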