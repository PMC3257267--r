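# Heuristic mapping of small-molecule binding sites to Pfam domains. Most
# pharmacological targets carry a single annotated domain; those targets seed
# a frequency dictionary of binding-site-containing domains which then
# disambiguates multi-domain architectures.

#' Build the dictionary of binding-site-containing domains
#'
#' Counts, over single-domain targets only, how often each Pfam accession
#' occurs. A target with several copies of one accession (and no other
#' accession) still counts as single-domain, and contributes one count.
#'
#' @param annotations domain annotation tibble with columns `accession`,
#'   `pfam_acc` (one row per domain instance).
#' @return tibble with `pfam_acc` and `count`, sorted by decreasing count then
#'   accession.
#' @export
build_domain_dictionary <- function(annotations) {
  if (nrow(annotations) == 0) {
    return(tibble::tibble(pfam_acc = character(), count = integer()))
  }
  per_target <- dplyr::summarise(
    dplyr::group_by(annotations, .data$accession),
    n_distinct_domains = dplyr::n_distinct(.data$pfam_acc),
    pfam_acc = .data$pfam_acc[1],
    .groups = "drop"
  )
  single <- per_target[per_target$n_distinct_domains == 1L, ]
  if (nrow(single) == 0) {
    return(tibble::tibble(pfam_acc = character(), count = integer()))
  }
  counts <- dplyr::count(single, .data$pfam_acc, name = "count")
  counts <- counts[order(-counts$count, counts$pfam_acc), ]
  tibble::as_tibble(counts)
}

#' Map a target's binding site to one of its domains
#'
#' Applies the frequency heuristic: a single-domain target is mapped to that
#' domain immediately; a multi-domain target is matched against the dictionary
#' of domains known from single-domain targets — one hit maps directly, two or
#' more hits map to the hit with the highest dictionary count. Targets with no
#' dictionary hit stay unmapped. Duplicate copies of an accession within one
#' target count once. Exact count ties are resolved to the lexicographically
#' smallest accession and tagged.
#'
#' @param domains character vector of the target's Pfam accessions, or a
#'   domain annotation tibble with a `pfam_acc` column.
#' @param dictionary dictionary tibble from [build_domain_dictionary()].
#' @return list with `pfam_acc` (or `NA` if unmapped), `rule` (one of
#'   `"single"`, `"dictionary_unique"`, `"frequency_tiebreak"`, `"unmapped"`)
#'   and `tie` (logical: exact count tie encountered).
#' @export
map_binding_site <- function(domains, dictionary) {
  if (is.data.frame(domains)) domains <- domains$pfam_acc
  domains <- unique(domains)
  if (length(domains) == 0) {
    return(list(pfam_acc = NA_character_, rule = "unmapped", tie = FALSE))
  }
  if (length(domains) == 1L) {
    return(list(pfam_acc = domains, rule = "single", tie = FALSE))
  }
  hits <- intersect(domains, dictionary$pfam_acc)
  if (length(hits) == 0) {
    return(list(pfam_acc = NA_character_, rule = "unmapped", tie = FALSE))
  }
  if (length(hits) == 1L) {
    return(list(pfam_acc = hits, rule = "dictionary_unique", tie = FALSE))
  }
  counts <- dictionary$count[match(hits, dictionary$pfam_acc)]
  top <- hits[counts == max(counts)]
  list(pfam_acc = sort(top)[1], rule = "frequency_tiebreak",
       tie = length(top) > 1L)
}

#' Write / read a domain dictionary as two-column TSV
#' @param dictionary tibble from [build_domain_dictionary()].
#' @param path file path.
#' @return `path` (write) or the dictionary tibble (read).
#' @export
write_domain_dictionary <- function(dictionary, path) {
  readr::write_tsv(dictionary, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_domain_dictionary
#' @export
read_domain_dictionary <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(pfam_acc = "c", count = "i"),
                  progress = FALSE)
}
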