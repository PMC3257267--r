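mk_lingo <- function(grams, q = 4) {
  structure(list(grams = grams, q = q, source_smiles = ""), class = "lingo")
}

test_that("SMILES normalization zeroes ring closures but not bracket digits", {
  expect_equal(normalize_smiles("c1ccccc1"), "c0ccccc0")
  expect_equal(normalize_smiles("CCO"), "CCO")
  expect_equal(normalize_smiles("C1CC2CCC12"), "C0CC0CCC00")
  # digits inside atom brackets are isotopes/charges, not ring closures
  expect_equal(normalize_smiles("[13CH3]C1CC1"), "[13CH3]C0CC0")
  expect_error(normalize_smiles(""), "nonempty")
})

test_that("LINGO fingerprints enumerate q-gram multisets with the short-string rule", {
  fp <- lingo_fingerprint("CCCC")
  expect_equal(fp$grams, c(CCCC = 1L))

  fp2 <- lingo_fingerprint("c1ccccc1") # normalizes to c0ccccc0
  expect_equal(sum(fp2$grams), 5L) # 8 - 4 + 1 grams
  expect_equal(fp2$grams[["cccc"]], 2L)
  expect_equal(fp2$grams[["c0cc"]], 1L)
  expect_equal(fp2$grams[["0ccc"]], 1L)
  expect_equal(fp2$grams[["ccc0"]], 1L)

  short <- lingo_fingerprint("CO")
  expect_equal(short$grams, c(CO = 1L))
  # gram count identity: max(1, len - q + 1)
  for (s in c("CO", "CCCC", "c1ccccc1", "CCOCCN")) {
    fp <- lingo_fingerprint(s)
    expect_equal(sum(fp$grams), max(1L, nchar(s) - 4L + 1L))
  }
})

test_that("multiset Tanimoto matches the per-gram agreement formula", {
  a <- lingo_fingerprint("c1ccccc1")
  expect_equal(lingo_similarity(a, a), 1.0)

  b <- lingo_fingerprint("NNNNNNNN")
  expect_equal(lingo_similarity(a, b), 0.0)

  # worked example: a = {X:2, Y:1}, b = {X:1, Z:1}
  # terms: X -> 1 - 1/3 = 2/3, Y -> 0, Z -> 0; mean over 3 grams = 2/9
  wa <- mk_lingo(c(X = 2L, Y = 1L))
  wb <- mk_lingo(c(X = 1L, Z = 1L))
  expect_equal(lingo_similarity(wa, wb), 2 / 9)

  # set mode on the same pair: |{X}| / |{X,Y,Z}|
  expect_equal(lingo_similarity(wa, wb, mode = "set"), 1 / 3)

  expect_error(lingo_similarity(a, lingo_fingerprint("CCO", q = 3)),
               "differing q")
})

test_that("multiset similarity is symmetric and matches a direct oracle", {
  set.seed(19)
  gram_pool <- apply(expand.grid(c("C", "N"), c("C", "O"), "C", "N"), 1,
                     paste, collapse = "")
  direct <- function(a, b) {
    grams <- union(names(a), names(b))
    na <- ifelse(grams %in% names(a), a[grams], 0)
    nb <- ifelse(grams %in% names(b), b[grams], 0)
    sum(1 - abs(na - nb) / (na + nb)) / length(grams)
  }
  for (i in 1:25) {
    ga <- table(sample(gram_pool, sample(3:10, 1), replace = TRUE))
    gb <- table(sample(gram_pool, sample(3:10, 1), replace = TRUE))
    a <- mk_lingo(stats::setNames(as.integer(ga), names(ga)))
    b <- mk_lingo(stats::setNames(as.integer(gb), names(gb)))
    expect_equal(lingo_similarity(a, b), direct(a$grams, b$grams),
                 tolerance = 1e-12)
    expect_equal(lingo_similarity(a, b), lingo_similarity(b, a))
  }
})

test_that("chemotype clustering handles degenerate and extreme cutoffs", {
  expect_equal(cluster_ligands("CCO"), list(labels = 1L, n_clusters = 1L))

  # duplicates of one structure plus one dissimilar molecule -> 2 clusters
  cl <- cluster_ligands(c("CCCCCCCC", "CCCCCCCC", "NNNNNNNN"))
  expect_equal(cl$n_clusters, 2L)
  expect_equal(cl$labels[1], cl$labels[2])
  expect_false(cl$labels[1] == cl$labels[3])

  smiles <- c("CCCCCCCC", "CCCCCCCO", "NNNNNNNN", "NNNNNNNO")
  # cutoff 0 -> everything merges
  expect_equal(cluster_ligands(smiles, similarity_cutoff = 0)$n_clusters, 1L)
  # cutoff 1 -> every distinct fingerprint is its own cluster
  expect_equal(cluster_ligands(smiles, similarity_cutoff = 1)$n_clusters, 4L)
})

test_that("clustering equals the hclust complete-linkage oracle for n <= 8", {
  set.seed(23)
  alphabet <- c("C", "N", "O", "S", "c", "n")
  for (rep in 1:40) {
    n <- sample(2:8, 1)
    smiles <- vapply(seq_len(n), function(i) {
      paste(sample(alphabet, sample(6:14, 1), replace = TRUE), collapse = "")
    }, "")
    got <- cluster_ligands(smiles)
    d <- orthopharm:::lingo_distance_matrix(smiles)
    oracle <- stats::cutree(stats::hclust(stats::as.dist(d), "complete"),
                            h = 0.25)
    expect_true(same_partition(got$labels, unname(oracle)),
                info = paste(smiles, collapse = " "))
  }
})

test_that("cluster partition is invariant to input order", {
  set.seed(29)
  base <- planted_universe(seed = 303, n_pairs = 1, n_compounds = c(18, 18))
  smiles <- base$universe$compounds$smiles
  ref <- cluster_ligands(smiles)
  for (k in 1:5) {
    perm <- sample(length(smiles))
    got <- cluster_ligands(smiles[perm])
    expect_equal(got$n_clusters, ref$n_clusters)
    expect_true(same_partition(got$labels[order(perm)], ref$labels))
  }
})

test_that("per-cluster summaries recover a planted chemotype-specific offset", {
  # one chemotype with a +1 species offset among offset-free chemotypes
  planted <- tibble::tibble(pair_id = "ORT001", chemotype = 1L, offset = 1.0)
  cfg <- synthetic_config(n_ortholog_pairs = 1,
                          n_compounds_per_target = c(100, 100),
                          n_chemotypes_per_target = 2,
                          planted_effects = planted, seed = 404)
  uni <- generate_universe(cfg)
  act <- generate_activities(uni, cfg)
  meas <- harmonize(filter_binding(act)$kept)
  paired <- pair_activities(meas, uni$pairs)
  cl <- cluster_ligands(uni$compounds$smiles)
  labels <- tibble::tibble(compound_id = uni$compounds$compound_id,
                           cluster = cl$labels)
  out <- per_cluster_differences(labels, paired)
  truth <- uni$compounds$chemotype[match(labels$compound_id,
                                         uni$compounds$compound_id)]
  planted_cluster <- unique(cl$labels[truth == 1L])
  expect_length(planted_cluster, 1L)
  row <- out[out$cluster == as.character(planted_cluster), ]
  expect_gte(row$n, 50)
  expect_lt(abs(row$mean_diff - 1.0), 0.1)
  other <- out[out$cluster != as.character(planted_cluster), ]
  expect_true(all(abs(other$mean_diff) < 0.2))

  # a single global cluster reproduces the global summary
  one <- per_cluster_differences(
    tibble::tibble(compound_id = paired$compound_id, cluster = 1L), paired)
  expect_equal(one$mean_diff, mean(paired$diff))

  empty <- per_cluster_differences(labels, paired[0, ])
  expect_equal(nrow(empty), 0L)
})
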