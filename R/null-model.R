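# The screen's empirical null: differences in pKi for identical compound and
# target measured in different assays, pooled across species into a composite
# control distribution.

#' Inter-assay differences for one species
#'
#' For every (compound, target) measured in at least two distinct assays,
#' replicates are first averaged within each assay. With exactly two assays the
#' difference of the two assay means is taken, ordered by assay id so the
#' (arbitrary) sign is reproducible. With more than two assays the per-assay
#' means are split into two groups and the difference of the group averages is
#' taken; the default split is a seeded random bipartition, with a
#' "first-vs-rest" alternative behind `grouping`.
#'
#' @param measurements harmonized measurement tibble for one species.
#' @param seed integer seed for the >2-assay bipartitions.
#' @param grouping `"random"` (default) or `"first_vs_rest"`.
#' @return tibble with `compound_id`, `target_id`, `n_assays`, the two group
#'   means `afnty1`, `afnty2` and their difference `diff`.
#' @export
interassay_differences <- function(measurements, seed = 1,
                                   grouping = c("random", "first_vs_rest")) {
  grouping <- match.arg(grouping)
  per_assay <- dplyr::summarise(
    dplyr::group_by(measurements, .data$compound_id, .data$target_id,
                    .data$assay_id),
    pki = mean(.data$pki),
    .groups = "drop"
  )
  per_assay <- per_assay[order(per_assay$compound_id, per_assay$target_id,
                               per_assay$assay_id), ]
  groups <- split(per_assay,
                  paste(per_assay$compound_id, per_assay$target_id, sep = "\r"))
  groups <- groups[vapply(groups, nrow, 1L) >= 2L]
  if (length(groups) == 0) {
    return(tibble::tibble(compound_id = character(), target_id = character(),
                          n_assays = integer(), afnty1 = numeric(),
                          afnty2 = numeric(), diff = numeric()))
  }
  groups <- groups[order(names(groups))] # deterministic iteration order

  with_seed(seed, {
    rows <- lapply(groups, function(g) {
      k <- nrow(g)
      if (k == 2L) {
        m1 <- g$pki[1]; m2 <- g$pki[2]
      } else if (grouping == "first_vs_rest") {
        m1 <- g$pki[1]; m2 <- mean(g$pki[-1])
      } else {
        size1 <- sample(seq_len(k - 1L), 1L)
        idx1 <- sort(sample(k, size1))
        m1 <- mean(g$pki[idx1]); m2 <- mean(g$pki[-idx1])
      }
      tibble::tibble(compound_id = g$compound_id[1], target_id = g$target_id[1],
                     n_assays = k, afnty1 = m1, afnty2 = m2, diff = m1 - m2)
    })
    dplyr::bind_rows(rows)
  })
}

#' Build the composite inter-assay control distribution
#'
#' Draws `n_per_species` inter-assay differences from the human pool and the
#' same number from the rat pool, without replacement when the pool allows it
#' (with replacement otherwise, noted in the provenance), giving a composite
#' null of `2 * n_per_species` values sized to match the ortholog comparison.
#'
#' @param human_diffs,rat_diffs numeric pools of inter-assay differences.
#' @param n_per_species draws per species (default 1500).
#' @param seed integer seed.
#' @return object of class `control_sample`: list with `diffs`, `n_human`,
#'   `n_rat`, `seed`, `provenance`.
#' @export
build_control <- function(human_diffs, rat_diffs, n_per_species = 1500,
                          seed = 1) {
  if (length(human_diffs) == 0 || length(rat_diffs) == 0) {
    stop("empty inter-assay difference pool", call. = FALSE)
  }
  draw <- function(pool, n, label) {
    replace <- length(pool) < n
    list(x = with_seed(substream_seed(seed, paste0("control_", label)),
                       sample(pool, n, replace = replace)),
         replace = replace)
  }
  h <- draw(human_diffs, n_per_species, "human")
  r <- draw(rat_diffs, n_per_species, "rat")
  prov <- sprintf(
    "composite of %d human + %d rat inter-assay differences (%s/%s replacement)",
    n_per_species, n_per_species,
    if (h$replace) "with" else "without", if (r$replace) "with" else "without"
  )
  structure(
    list(diffs = c(h$x, r$x), n_human = n_per_species, n_rat = n_per_species,
         seed = seed, provenance = prov),
    class = "control_sample"
  )
}

#' @export
print.control_sample <- function(x, ...) {
  cat("Inter-assay control distribution\n")
  cat("  n =", length(x$diffs), sprintf("(%d human + %d rat)\n",
                                        x$n_human, x$n_rat))
  cat(sprintf("  median %.3f, mean |diff| %.3f\n",
              stats::median(x$diffs), mean(abs(x$diffs))))
  cat(" ", x$provenance, "\n")
  invisible(x)
}

#' Serialize / restore a control distribution
#'
#' Writes the differences as a one-column TSV next to a JSON metadata sidecar
#' (seed, counts, provenance).
#'
#' @param control `control_sample` object.
#' @param path TSV path; metadata goes to `<path>.json`.
#' @return `path` (write) or a `control_sample` (read).
#' @export
write_control <- function(control, path) {
  readr::write_tsv(tibble::tibble(diff = control$diffs), path, progress = FALSE)
  meta <- control[c("n_human", "n_rat", "seed", "provenance")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_control
#' @export
read_control <- function(path) {
  diffs <- readr::read_tsv(path, col_types = readr::cols(diff = "d"),
                           progress = FALSE)$diff
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(diffs = diffs, n_human = meta$n_human, n_rat = meta$n_rat,
                 seed = meta$seed, provenance = meta$provenance),
            class = "control_sample")
}
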