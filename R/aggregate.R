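# Per-pair aggregation of potency measurements, consistency filtering and
# active/inactive classification.

#' Negative decadic logarithm of a molar potency given in nM
#'
#' `to_log(v)` = -log10(v * 1e-9) = 9 - log10(v). 1 nM maps to 9.0, 100 nM to
#' 7.0, and the 10,000 nM activity threshold to 5.0.
#'
#' @param value_nM positive potency value(s) in nanomolar.
#' @return numeric vector of log potencies.
#' @export
to_log <- function(value_nM) {
  stopifnot(all(is.finite(value_nM)), all(value_nM > 0))
  9 - log10(value_nM)
}

# Measurement-type selection priority: assay-independent binding constants
# before assay-dependent IC50; Kd ranks above Ki (configurable here).
.type_priority <- c(KD = 1L, KI = 2L, IC50 = 3L)

#' Aggregate all qualified measurements for one compound-kinase pair
#'
#' Applies the pair-level consistency rules, in order:
#' \enumerate{
#'   \item `=` measurements are pooled across sources and grouped by
#'     measurement type; within a type the final value is the arithmetic mean
#'     of log-transformed potencies.
#'   \item A type whose log values have sample standard deviation greater
#'     than 1 is invalid (singletons are exempt).
#'   \item Among valid types, the assay-independent constant is selected in
#'     priority over IC50 (Kd before Ki).
#'   \item Selected mean log potency >= 5.0 classifies the pair ACTIVE,
#'     otherwise INACTIVE.
#'   \item A pair with an ACTIVE quantitative result and any censored
#'     `>`/`>>` record is internally conflicting and discarded.
#'   \item A pair with only censored records is INACTIVE with no numeric
#'     potency (qualitative annotation).
#' }
#' A pair whose every type fails the dispersion gate is discarded outright.
#'
#' @param measurements data.frame of qualified records for a single pair, with
#'   columns `measurement_type`, `relation`, `value_nM`, `record_id` (and the
#'   identity columns `compound_new_id`, `kinase_uniprot`, `organism`,
#'   `pref_name` if available).
#' @param threshold_log classification threshold on the log scale (5.0
#'   corresponds to 10,000 nM).
#' @return one-row data.frame: identity columns, `selected_type`
#'   (`KD`/`KI`/`IC50`/`QUALITATIVE`), `mean_log` (`NA` for qualitative-only
#'   pairs), `selected_stvalue`, `status` (`ACTIVE`, `INACTIVE`,
#'   `DISCARDED_SD`, `DISCARDED_CONFLICT`), `n_measurements`, `activity_ids`.
#' @export
aggregate_pair <- function(measurements, threshold_log = 5.0) {
  stopifnot(nrow(measurements) > 0)
  m <- measurements
  ids <- paste(sort(as.character(m$record_id), method = "radix"),
               collapse = ";")
  eq <- m[m$relation == "EQ", , drop = FALSE]
  qual <- m[m$relation %in% c("GT", "GTGT"), , drop = FALSE]
  pick <- function(col) if (col %in% names(m)) m[[col]][1] else NA
  base <- data.frame(
    compound_new_id = pick("compound_new_id"),
    compound_key = pick("compound_key"),
    kinase_uniprot = pick("kinase_uniprot"),
    organism = pick("organism"),
    pref_name = pick("pref_name"),
    stringsAsFactors = FALSE
  )
  finish <- function(selected_type, mean_log, status) {
    cbind(base, data.frame(
      selected_type = selected_type,
      mean_log = mean_log,
      selected_stvalue = type_stvalue(selected_type),
      status = status,
      n_measurements = nrow(m),
      activity_ids = ids,
      stringsAsFactors = FALSE
    ))
  }
  if (nrow(eq) == 0) {
    return(finish("QUALITATIVE", NA_real_, "INACTIVE"))
  }
  logs <- split(to_log(eq$value_nM), eq$measurement_type)
  means <- vapply(logs, mean, numeric(1))
  valid <- vapply(logs, function(x) length(x) < 2 || stats::sd(x) <= 1,
                  logical(1))
  if (!any(valid)) {
    return(finish("QUALITATIVE", NA_real_, "DISCARDED_SD"))
  }
  types <- names(means)[valid]
  sel <- types[order(.type_priority[types])][1]
  mlog <- unname(means[sel])
  status <- if (mlog >= threshold_log) "ACTIVE" else "INACTIVE"
  if (status == "ACTIVE" && nrow(qual) > 0) status <- "DISCARDED_CONFLICT"
  finish(sel, mlog, status)
}

type_stvalue <- function(type) {
  switch(type, KD = "Kd", KI = "Ki", IC50 = "IC50",
         QUALITATIVE = "qualitative", type)
}

#' Aggregate all pairs in a qualified, merged record set
#'
#' Groups records by (compound, kinase) and applies [aggregate_pair()] to each
#' group. Output order is deterministic: by `compound_new_id`, then
#' `kinase_uniprot`.
#'
#' @param records data.frame of qualified records carrying `compound_new_id`,
#'   `compound_key`, `kinase_uniprot`, `organism`, `pref_name`,
#'   `measurement_type`, `relation`, `value_nM`, `record_id`.
#' @param threshold_log see [aggregate_pair()].
#' @return data.frame of pair annotations, one row per pair.
#' @export
aggregate_pairs <- function(records, threshold_log = 5.0) {
  stopifnot(nrow(records) > 0)
  key <- paste(records$compound_new_id, records$kinase_uniprot, sep = "\r")
  groups <- split(seq_len(nrow(records)), key)
  rows <- lapply(groups, function(ix) {
    aggregate_pair(records[ix, , drop = FALSE], threshold_log)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$compound_new_id, out$kinase_uniprot, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition pair annotations into the four deposition sets
#'
#' Splits by organism and activity status, dropping discarded pairs. A
#' compound active against one kinase and inactive against another appears in
#' both sets, once per pair.
#'
#' @param annotations data.frame from [aggregate_pairs()].
#' @return named list of data.frames: `human_active`, `human_inactive`,
#'   `mouse_active`, `mouse_inactive`.
#' @export
split_datasets <- function(annotations) {
  keep <- annotations[annotations$status %in% c("ACTIVE", "INACTIVE"), ,
                      drop = FALSE]
  sel <- function(org, st) {
    d <- keep[keep$organism == org & keep$status == st, , drop = FALSE]
    rownames(d) <- NULL
    d
  }
  list(
    human_active = sel("HUMAN", "ACTIVE"),
    human_inactive = sel("HUMAN", "INACTIVE"),
    mouse_active = sel("MOUSE", "ACTIVE"),
    mouse_inactive = sel("MOUSE", "INACTIVE")
  )
}
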