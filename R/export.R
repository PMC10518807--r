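# Deposition-schema output and summary statistics.

.deposition_cols <- c("Compound_new_ID", "nonstereo_aromatic_smile",
                      "Uniprot_ID", "pref_name", "activity_id", "mean_log",
                      "selected_stvalue", "ORGANISM")

.dataset_files <- c(human_active = "human_PKI_active.tsv",
                    human_inactive = "human_PKI_inactive.tsv",
                    mouse_active = "mouse_PKI_active.tsv",
                    mouse_inactive = "mouse_PKI_inactive.tsv")

organism_label <- function(code) {
  c(HUMAN = "Homo sapiens", MOUSE = "Mus musculus")[code]
}

# One deposition table from a set of pair annotations. mean_log is written
# with 10 significant digits; qualitative-only pairs carry the literal "NaN".
deposition_table <- function(annotations, compounds, cpki = NULL) {
  a <- annotations
  key <- compounds$compound_key[match(a$compound_new_id,
                                      compounds$compound_new_id)]
  d <- data.frame(
    Compound_new_ID = a$compound_new_id,
    nonstereo_aromatic_smile = key,
    Uniprot_ID = a$kinase_uniprot,
    pref_name = a$pref_name,
    activity_id = a$activity_ids,
    mean_log = ifelse(is.na(a$mean_log), "NaN",
                      sprintf("%.10g", a$mean_log)),
    selected_stvalue = a$selected_stvalue,
    ORGANISM = unname(organism_label(a$organism)),
    stringsAsFactors = FALSE
  )
  if (!is.null(cpki)) {
    flag <- cpki$cpki[match(d$Compound_new_ID, cpki$compound_new_id)]
    flag[is.na(flag)] <- FALSE
    d$CPKI <- ifelse(flag, "True", "False")
  }
  d <- d[order(d$Compound_new_ID, d$Uniprot_ID, method = "radix"), ,
         drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Write the four-file deposition schema
#'
#' Emits `human_PKI_active.tsv`, `human_PKI_inactive.tsv`,
#' `mouse_PKI_active.tsv` and `mouse_PKI_inactive.tsv` plus a generated
#' `readme.txt` into `out_dir`. Column names follow the deposition schema
#' verbatim; the covalent-inhibitor flag column `CPKI` appears only in the
#' human active file. Row order is stable (`Compound_new_ID`, then
#' `Uniprot_ID`) and the files round-trip losslessly through
#' [read_deposition_file()].
#'
#' @param annotations pair annotations from [aggregate_pairs()] (discarded
#'   pairs are dropped here).
#' @param compounds compound table from [merge_compounds()].
#' @param cpki CPKI flag table from [scan_warheads()], or `NULL` to scan the
#'   human-active compounds with the default registry.
#' @param out_dir output directory, created if missing.
#' @return invisibly, the named list of file paths written.
#' @export
write_datasets <- function(annotations, compounds, cpki = NULL,
                           out_dir = ".") {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  sets <- split_datasets(annotations)
  if (is.null(cpki)) {
    ha <- unique(sets$human_active$compound_new_id)
    cpki <- scan_warheads(compounds[compounds$compound_new_id %in% ha, ,
                                    drop = FALSE])$cpki
  }
  paths <- character(0)
  for (nm in names(.dataset_files)) {
    d <- deposition_table(sets[[nm]], compounds,
                          cpki = if (nm == "human_active") cpki else NULL)
    p <- file.path(out_dir, .dataset_files[[nm]])
    utils::write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    paths[nm] <- p
  }
  writeLines(readme_text(sets), file.path(out_dir, "readme.txt"))
  invisible(paths)
}

#' Read back a deposition TSV
#'
#' All columns are read as character so that a write-read-write cycle is
#' byte-identical.
#'
#' @param path a file written by [write_datasets()].
#' @return data.frame of character columns.
#' @export
read_deposition_file <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = "character", check.names = FALSE, quote = "")
}

readme_text <- function(sets) {
  tpl <- system.file("extdata", "readme_template.txt", package = "kinicurate")
  txt <- paste(readLines(tpl), collapse = "\n")
  counts <- vapply(sets, nrow, integer(1))
  cmpds <- vapply(sets, function(s) length(unique(s$compound_new_id)),
                  integer(1))
  for (nm in names(counts)) {
    txt <- gsub(paste0("{{", nm, "_pairs}}"), counts[[nm]], txt, fixed = TRUE)
    txt <- gsub(paste0("{{", nm, "_compounds}}"), cmpds[[nm]], txt,
                fixed = TRUE)
  }
  strsplit(txt, "\n", fixed = TRUE)[[1]]
}

#' Five-number summary of a log-potency distribution
#'
#' Quartiles use linear interpolation (`stats::quantile` type 7); whiskers
#' follow the Tukey rule (most extreme values within 1.5 IQR of the box),
#' values beyond them are listed as outliers.
#'
#' @param x numeric vector of log potencies (NA dropped).
#' @return list with `n`, `min`, `q1`, `median`, `q3`, `max`, `whisker_lo`,
#'   `whisker_hi`, `outliers`.
#' @export
distribution_summary <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) {
    return(list(n = 0L, min = NA_real_, q1 = NA_real_, median = NA_real_,
                q3 = NA_real_, max = NA_real_, whisker_lo = NA_real_,
                whisker_hi = NA_real_, outliers = numeric(0)))
  }
  q <- unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- x[x >= lo_fence & x <= hi_fence]
  list(n = length(x), min = min(x), q1 = q[1], median = q[2], q3 = q[3],
       max = max(x), whisker_lo = min(inside), whisker_hi = max(inside),
       outliers = sort(x[x < lo_fence | x > hi_fence]))
}

#' Summary statistics over a curated corpus
#'
#' Per organism: unique active and inactive compounds, unique compound-kinase
#' interactions, kinases with at least one active (and at least one inactive)
#' compound, and the log-potency distribution over active pairs. Optionally,
#' analogue-series counts (series, singletons, distinct cores = series +
#' singletons) and the covalent-warhead histogram.
#'
#' @param annotations pair annotations from [aggregate_pairs()].
#' @param series_result optional result of [assign_series()].
#' @param warhead_result optional result of [scan_warheads()].
#' @return nested list of summary statistics.
#' @export
summarize_curation <- function(annotations, series_result = NULL,
                               warhead_result = NULL) {
  sets <- split_datasets(annotations)
  per_org <- function(org) {
    act <- sets[[paste0(org, "_active")]]
    ina <- sets[[paste0(org, "_inactive")]]
    list(
      n_active_compounds = length(unique(act$compound_new_id)),
      n_inactive_compounds = length(unique(ina$compound_new_id)),
      n_interactions = nrow(act) + nrow(ina),
      n_active_interactions = nrow(act),
      n_kinases_with_active = length(unique(act$kinase_uniprot)),
      n_kinases_with_inactive = length(unique(ina$kinase_uniprot)),
      potency = distribution_summary(act$mean_log)
    )
  }
  out <- list(human = per_org("human"), mouse = per_org("mouse"),
              n_pairs_discarded_sd = sum(annotations$status == "DISCARDED_SD"),
              n_pairs_discarded_conflict =
                sum(annotations$status == "DISCARDED_CONFLICT"))
  if (!is.null(series_result)) {
    n_as <- nrow(series_result$series)
    n_single <- nrow(series_result$singletons)
    out$analog_series <- list(
      n_series = n_as, n_singletons = n_single,
      n_distinct_cores = length(unique(c(series_result$series$core_smiles,
                                         series_result$singletons$core_smiles)))
    )
  }
  if (!is.null(warhead_result)) {
    out$warheads <- list(
      n_cpki = sum(warhead_result$cpki$cpki),
      histogram = warhead_result$histogram
    )
  }
  out
}
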