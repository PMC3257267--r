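# Shared fixture builders: all inputs are generated in code at test time.

write_tsv_lines <- function(lines, file = tempfile(fileext = ".tsv")) {
  writeLines(lines, file)
  file
}

# A minimal raw activity table in the default dialect.
toy_activity_file <- function(rows, file = tempfile(fileext = ".tsv")) {
  header <- paste("molregno", "canonical_smiles", "tid", "accession",
                  "pref_name", "organism", "assay_id", "assay_type",
                  "standard_type", "standard_value", "standard_units",
                  sep = "\t")
  writeLines(c(header, rows), file)
  file
}

toy_activity_row <- function(molregno = "M1", smiles = "CCO", tid = "T1",
                             accession = "P1", pref_name = "target",
                             organism = "human", assay_id = "A1",
                             assay_type = "B", standard_type = "Ki",
                             value = "10", units = "nM") {
  paste(molregno, smiles, tid, accession, pref_name, organism, assay_id,
        assay_type, standard_type, value, units, sep = "\t")
}

# Small planted-effect ortholog universe used by several suites.
planted_universe <- function(seed = 101, n_pairs = 6, delta = 1.5,
                             n_chemotypes = 3,
                             n_compounds = c(30, 40)) {
  planted <- tibble::tibble(
    pair_id = "ORT001",
    chemotype = seq_len(n_chemotypes),
    offset = delta
  )
  cfg <- synthetic_config(
    n_ortholog_pairs = n_pairs, n_paralog_pairs = 0,
    n_compounds_per_target = n_compounds,
    n_chemotypes_per_target = n_chemotypes,
    planted_effects = planted, seed = seed
  )
  uni <- generate_universe(cfg)
  act <- generate_activities(uni, cfg)
  list(cfg = cfg, universe = uni, activities = act)
}

# Partition equality up to label renaming.
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}
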