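# End-to-end orchestration: ingest -> standardize/merge -> aggregate ->
# analogue series -> warheads -> export.

#' Run the full curation pipeline
#'
#' Reads the two dialect tables and the kinase annotation table, qualifies and
#' merges the records, aggregates per-pair potency annotations, extracts
#' analogue series from the curated compounds, scans the human active set for
#' covalent warheads, and (optionally) writes the four-file deposition schema.
#'
#' @param chembl_path,bindingdb_path activity tables in the two dialects;
#'   either may be `NULL`.
#' @param kinase_path kinase annotation TSV (`uniprot_id`, `pref_name`,
#'   `organism`).
#' @param out_dir if non-NULL, deposition files and `readme.txt` are written
#'   here.
#' @param config qualification settings, see [qualification_config()].
#' @param max_cuts,rules analogue-series fragmentation settings.
#' @param registry warhead registry, see [load_warhead_registry()].
#' @param warhead_scope `"human_active"` (default) scans only compounds in the
#'   human active set; `"all"` scans every curated compound.
#' @param run_series set `FALSE` to skip analogue-series extraction.
#' @return list with `report` (qualification report), `records` (qualified,
#'   merged records), `compounds`, `annotations`, `datasets`, `series`,
#'   `warheads`, and `summary`.
#' @export
run_pipeline <- function(chembl_path = NULL, bindingdb_path = NULL,
                         kinase_path, out_dir = NULL,
                         config = qualification_config(), max_cuts = 2,
                         rules = default_retro_rules(),
                         registry = load_warhead_registry(),
                         warhead_scope = c("human_active", "all"),
                         run_series = TRUE) {
  warhead_scope <- match.arg(warhead_scope)
  kin <- read_kinase_table(kinase_path)
  recs <- list()
  if (!is.null(chembl_path)) {
    recs$chembl <- read_activity_table(chembl_path, "chembl", kin)
  }
  if (!is.null(bindingdb_path)) {
    recs$bindingdb <- read_activity_table(bindingdb_path, "bindingdb", kin)
  }
  stopifnot(length(recs) > 0)
  records <- do.call(rbind, c(unname(recs), make.row.names = FALSE))

  q <- qualify_records(records, config)
  qualified <- q$records[q$records$outcome != "DISCARD", , drop = FALSE]
  merged <- merge_compounds(qualified)
  report <- q$report
  if (merged$n_failed_standardization > 0) {
    report$discard_counts["unparseable_smiles"] <-
      merged$n_failed_standardization
    report$n_qualified <- report$n_qualified - merged$n_failed_standardization
  }

  annotations <- aggregate_pairs(merged$records)
  datasets <- split_datasets(annotations)

  series <- NULL
  if (run_series) {
    curated <- unique(c(datasets$human_active$compound_key,
                        datasets$human_inactive$compound_key,
                        datasets$mouse_active$compound_key,
                        datasets$mouse_inactive$compound_key))
    series <- assign_series(sort(curated, method = "radix"),
                            max_cuts = max_cuts, rules = rules)
  }

  scan_ids <- if (warhead_scope == "human_active") {
    unique(datasets$human_active$compound_new_id)
  } else {
    merged$compounds$compound_new_id
  }
  warheads <- scan_warheads(
    merged$compounds[merged$compounds$compound_new_id %in% scan_ids, ,
                     drop = FALSE],
    registry
  )

  if (!is.null(out_dir)) {
    write_datasets(annotations, merged$compounds, cpki = warheads$cpki,
                   out_dir = out_dir)
    jsonlite::write_json(
      summarize_curation(annotations, series, warheads),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }

  list(report = report, records = merged$records,
       compounds = merged$compounds, annotations = annotations,
       datasets = datasets, series = series, warheads = warheads,
       summary = summarize_curation(annotations, series, warheads))
}
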