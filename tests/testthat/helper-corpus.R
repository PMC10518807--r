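# Shared corpora and cached candidate maps, built once per test session.

.corpus_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, envir = .corpus_cache)) {
    assign(key, build(), envir = .corpus_cache)
  }
  get(key, envir = .corpus_cache)
}

# The reference clean corpus: 20 series of 3-6 members, 10 singletons,
# 8 kinases, no injected pair-level pathologies beyond planted inactives and
# qualitative records (which are ordinary data, not pathologies).
clean_corpus <- function() {
  cached("clean_corpus", function() {
    dir <- file.path(tempdir(), "kinicurate-clean-corpus")
    generate_fixtures(
      fixture_spec(seed = 42L, n_series = 20L, series_size_range = c(3L, 6L),
                   n_singletons = 10L, n_kinases = 8L),
      out_dir = dir
    )
  })
}

clean_pipeline <- function() {
  cached("clean_pipeline", function() {
    fx <- clean_corpus()
    run_pipeline(fx$paths["chembl"], fx$paths["bindingdb"],
                 fx$paths["kinases"])
  })
}

# Corpus with injected pathologies and decoy records, for accounting tests.
pathology_corpus <- function() {
  cached("pathology_corpus", function() {
    dir <- file.path(tempdir(), "kinicurate-pathology-corpus")
    generate_fixtures(
      fixture_spec(seed = 11L, n_series = 6L, series_size_range = c(3L, 4L),
                   n_singletons = 4L, n_kinases = 6L, frac_conflict = 0.12,
                   frac_sd_violation = 0.12, decoy_rate = 0.3),
      out_dir = dir
    )
  })
}

pathology_pipeline <- function() {
  cached("pathology_pipeline", function() {
    fx <- pathology_corpus()
    run_pipeline(fx$paths["chembl"], fx$paths["bindingdb"],
                 fx$paths["kinases"], run_series = FALSE)
  })
}

# Compound pool for analogue-series randomization: planted series plus
# singletons, with engine and oracle candidate maps computed once.
analog_pool <- function() {
  cached("analog_pool", function() {
    fx <- generate_fixtures(
      fixture_spec(seed = 5L, n_series = 8L, series_size_range = c(3L, 4L),
                   n_singletons = 6L, n_kinases = 4L)
    )
    pool <- sort(standardize_smiles(fx$truth$compounds$smiles)$compound_key,
                 method = "radix")
    stopifnot(!anyDuplicated(pool))
    engine <- lapply(pool, fragment_compound)
    names(engine) <- pool
    oracle <- lapply(pool, oracle_candidate_cores)
    names(oracle) <- pool
    list(pool = pool, engine = engine, oracle = oracle)
  })
}

# Map pipeline compound keys to generator compound ids through record ids.
truth_key_map <- function(fx, result) {
  rm <- fx$truth$records
  rec <- result$records
  unique(data.frame(
    compound_key = rec$compound_key,
    gen_id = rm$gen_id[match(rec$record_id, rm$record_id)],
    stringsAsFactors = FALSE
  ))
}
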