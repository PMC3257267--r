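# LINGO q-gram SMILES fingerprints, Tanimoto similarity, and complete-linkage
# chemotype clustering. A chemotype is a cluster of ligands whose pairwise
# LINGO-Tanimoto similarity stays at or above the cutoff (0.75 by default)
# under complete linkage -- a practical proxy for a chemical series.

#' Normalize a SMILES string for LINGO fingerprinting
#'
#' Replaces ring-closure digits with `0` so that, e.g., two fused-ring systems
#' differing only in ring numbering produce identical q-grams. Digits inside
#' square-bracket atom expressions (isotopes, H counts, charges) are not ring
#' closures and are left alone. No re-canonicalization is performed: inputs
#' are taken as given, as database exports are assumed pre-canonicalized.
#'
#' @param smiles nonempty SMILES string.
#' @return normalized string.
#' @export
normalize_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || nchar(smiles) == 0) {
    stop("SMILES must be a single nonempty string", call. = FALSE)
  }
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  in_bracket <- FALSE
  for (i in seq_along(chars)) {
    if (chars[i] == "[") in_bracket <- TRUE
    else if (chars[i] == "]") in_bracket <- FALSE
    else if (!in_bracket && chars[i] >= "0" && chars[i] <= "9") chars[i] <- "0"
  }
  paste(chars, collapse = "")
}

#' LINGO fingerprint of a SMILES string
#'
#' The multiset of all length-`q` substrings (q-grams) of the normalized
#' SMILES. Strings shorter than `q` yield a single gram: the whole string.
#'
#' @param smiles nonempty SMILES string.
#' @param q gram length (default 4).
#' @return object of class `lingo`: list with `grams` (named integer counts),
#'   `q`, `source_smiles`.
#' @export
lingo_fingerprint <- function(smiles, q = 4) {
  s <- normalize_smiles(smiles)
  n <- nchar(s)
  grams <- if (n < q) s else substring(s, 1:(n - q + 1), q:n)
  counts <- table(grams)
  structure(
    list(grams = stats::setNames(as.integer(counts), names(counts)),
         q = q, source_smiles = smiles),
    class = "lingo"
  )
}

#' Tanimoto similarity of two LINGO fingerprints
#'
#' Default (`multiset`) form: with gram counts `Na_i`, `Nb_i` over the `l`
#' distinct grams present in either molecule,
#' `Tc = (1/l) * sum_i (1 - |Na_i - Nb_i| / (Na_i + Nb_i))`.
#' The `set` form ignores counts: `|A intersect B| / |A union B|` over
#' distinct grams.
#'
#' @param a,b `lingo` objects with the same `q`.
#' @param mode `"multiset"` (default) or `"set"`.
#' @return similarity in \[0, 1\].
#' @export
lingo_similarity <- function(a, b, mode = c("multiset", "set")) {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "lingo"), inherits(b, "lingo"))
  if (a$q != b$q) stop("fingerprints have differing q", call. = FALSE)
  all_grams <- union(names(a$grams), names(b$grams))
  na <- a$grams[all_grams]; na[is.na(na)] <- 0L
  nb <- b$grams[all_grams]; nb[is.na(nb)] <- 0L
  if (mode == "multiset") {
    mean(1 - abs(na - nb) / (na + nb))
  } else {
    sum(na > 0 & nb > 0) / length(all_grams)
  }
}

# Pairwise LINGO distance (1 - Tc) matrix for a SMILES vector.
lingo_distance_matrix <- function(smiles, q = 4, mode = "multiset") {
  fps <- lapply(smiles, lingo_fingerprint, q = q)
  n <- length(fps)
  d <- matrix(0, n, n)
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- 1 - lingo_similarity(fps[[i]], fps[[j]],
                                                   mode = mode)
      }
    }
  }
  d
}

#' Cluster ligands into chemotypes
#'
#' Complete-linkage agglomerative clustering on the LINGO-Tanimoto distance
#' `1 - Tc`, cut at `1 - similarity_cutoff`: every pair of compounds within a
#' chemotype has `Tc >= similarity_cutoff`. The agglomeration is deterministic
#' and order-invariant: at equal merge heights the pair of clusters with the
#' lowest original compound indices merges first, and final labels are
#' numbered by first compound occurrence.
#'
#' @param smiles character vector of SMILES (>= 1 compound).
#' @param similarity_cutoff Tanimoto cutoff defining a chemotype (default
#'   0.75).
#' @param q LINGO gram length.
#' @param mode Tanimoto form, `"multiset"` or `"set"`.
#' @return list with `labels` (integer per compound) and `n_clusters`.
#' @export
cluster_ligands <- function(smiles, similarity_cutoff = 0.75, q = 4,
                            mode = "multiset") {
  n <- length(smiles)
  if (n == 0) stop("need at least one compound", call. = FALSE)
  if (n == 1) return(list(labels = 1L, n_clusters = 1L))
  d <- lingo_distance_matrix(smiles, q = q, mode = mode)
  labels <- complete_linkage_cut(d, height = 1 - similarity_cutoff)
  list(labels = labels, n_clusters = max(labels))
}

# Complete-linkage agglomeration cut at `height`: repeatedly merge the two
# clusters with the smallest maximum inter-cluster distance while that
# distance is <= height. Ties at equal height are broken by the smallest pair
# of cluster representatives (minimum original member index), making the
# result invariant to input order for a fixed distance matrix.
complete_linkage_cut <- function(d, height) {
  n <- nrow(d)
  members <- as.list(seq_len(n))
  cd <- d # complete-linkage distance between live clusters
  live <- rep(TRUE, n)
  repeat {
    idx <- which(live)
    if (length(idx) < 2) break
    best <- NULL
    best_d <- Inf
    for (ai in seq_along(idx)[-length(idx)]) {
      for (bi in (ai + 1):length(idx)) {
        i <- idx[ai]; j <- idx[bi]
        dij <- cd[i, j]
        if (dij < best_d - 1e-12) {
          best_d <- dij; best <- c(i, j)
        } else if (abs(dij - best_d) <= 1e-12 && !is.null(best)) {
          # tie: prefer the pair with the smallest representative indices
          cand <- sort(c(min(members[[i]]), min(members[[j]])))
          cur <- sort(c(min(members[[best[1]]]), min(members[[best[2]]])))
          if (cand[1] < cur[1] || (cand[1] == cur[1] && cand[2] < cur[2])) {
            best <- c(i, j)
          }
        }
      }
    }
    if (best_d > height) break
    i <- best[1]; j <- best[2]
    members[[i]] <- c(members[[i]], members[[j]])
    live[j] <- FALSE
    upd <- which(live & seq_len(n) != i)
    cd[i, upd] <- pmax(cd[i, upd], cd[j, upd])
    cd[upd, i] <- cd[i, upd]
  }
  labels <- integer(n)
  firsts <- vapply(members[live], min, 1L)
  order_live <- which(live)[order(firsts)]
  for (k in seq_along(order_live)) {
    labels[members[[order_live[k]]]] <- k
  }
  labels
}

#' Per-chemotype distributions of paired binding differences
#'
#' Joins chemotype labels to paired activities and summarizes the signed
#' difference per cluster. Clusters below `min_size` compounds are pooled into
#' a `"singletons"` group.
#'
#' @param labels tibble with `compound_id` and `cluster`.
#' @param paired paired-activity tibble with `compound_id` and `diff`.
#' @param min_size minimum cluster size reported on its own (default 2).
#' @return tibble with `cluster`, `n`, `mean_diff`, `median_diff`.
#' @export
per_cluster_differences <- function(labels, paired, min_size = 2) {
  if (nrow(paired) == 0) {
    return(tibble::tibble(cluster = character(), n = integer(),
                          mean_diff = numeric(), median_diff = numeric()))
  }
  merged <- dplyr::inner_join(paired, labels, by = "compound_id")
  if (nrow(merged) == 0) {
    return(tibble::tibble(cluster = character(), n = integer(),
                          mean_diff = numeric(), median_diff = numeric()))
  }
  cluster_sizes <- table(labels$cluster)
  small <- names(cluster_sizes)[cluster_sizes < min_size]
  merged$cluster_label <- ifelse(as.character(merged$cluster) %in% small,
                                 "singletons", as.character(merged$cluster))
  out <- dplyr::summarise(
    dplyr::group_by(merged, cluster = .data$cluster_label),
    n = dplyr::n(),
    mean_diff = mean(.data$diff),
    median_diff = stats::median(.data$diff),
    .groups = "drop"
  )
  out[order(out$cluster == "singletons", suppressWarnings(as.numeric(out$cluster))), ]
}
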