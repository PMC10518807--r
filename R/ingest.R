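# Parsing of the two source dialects and record-level qualification.

#' Column-mapping preset for a source dialect
#'
#' The exact column names of database exports are configuration, not code:
#' two presets ship with the package (`"chembl"` and `"bindingdb"`) as YAML
#' files under `extdata/`. A custom dialect can be supplied as a YAML path or
#' an equivalent named list.
#'
#' @param dialect `"chembl"`, `"bindingdb"`, a path to a YAML mapping, or a
#'   list with elements `dialect`, `columns`, and optionally `constants`.
#' @return the dialect definition as a list.
#' @export
dialect_preset <- function(dialect) {
  if (is.list(dialect)) return(dialect)
  if (dialect %in% c("chembl", "bindingdb")) {
    path <- system.file("extdata", paste0("dialect_", dialect, ".yaml"),
                        package = "kinicurate")
  } else {
    path <- dialect
  }
  if (!file.exists(path)) stop("unknown dialect or missing mapping file: ", dialect)
  yaml::read_yaml(path)
}

#' Read a kinase annotation table
#'
#' @param path TSV with columns `uniprot_id`, `pref_name`, `organism`.
#' @return data.frame with those columns plus `organism_code`
#'   (`"HUMAN"`/`"MOUSE"`/`NA`).
#' @export
read_kinase_table <- function(path) {
  k <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("uniprot_id", "pref_name", "organism")
  miss <- setdiff(need, names(k))
  if (length(miss) > 0) stop("kinase table is missing column(s): ",
                             paste(miss, collapse = ", "))
  org <- tolower(k$organism)
  k$organism_code <- ifelse(grepl("^homo", org), "HUMAN",
                     ifelse(grepl("^mus", org), "MOUSE", NA_character_))
  k
}

#' Parse an activity-record table in a given source dialect
#'
#' Reads a TSV export and maps its columns onto the normalized activity-record
#' schema. No qualification happens here: rows with unparseable values or
#' out-of-scope measurement types are carried through and discarded later,
#' with the reason logged in the qualification report.
#'
#' @param path TSV file with a header row.
#' @param dialect see [dialect_preset()].
#' @param kinase_table data.frame from [read_kinase_table()].
#' @return data.frame of normalized activity records, one per input row.
#' @export
read_activity_table <- function(path, dialect, kinase_table) {
  d <- dialect_preset(dialect)
  if (!file.exists(path)) stop("activity table not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character", quote = "")
  if (nrow(raw) == 0) {
    warning("empty activity table: ", path)
  }
  cols <- d$columns
  required <- unlist(cols, use.names = FALSE)
  miss <- setdiff(required, names(raw))
  if (length(miss) > 0) {
    stop("dialect '", d$dialect, "': required column(s) missing from ", path,
         ": ", paste(miss, collapse = ", "))
  }
  take <- function(field) {
    src <- cols[[field]]
    if (is.null(src)) {
      const <- d$constants[[field]]
      if (!is.null(const)) rep(as.character(const), nrow(raw))
      else rep(NA_character_, nrow(raw))
    } else raw[[src]]
  }
  rec <- data.frame(
    record_id = take("record_id"),
    source = toupper(d$dialect),
    compound_smiles = take("compound_smiles"),
    kinase_uniprot = take("kinase_uniprot"),
    measurement_type_raw = take("measurement_type"),
    relation_raw = take("relation"),
    value_raw = take("value"),
    units = take("units"),
    target_category = take("target_category"),
    confidence_score_raw = take("confidence_score"),
    activity_comment = take("activity_comment"),
    activity_label_raw = take("activity_label"),
    n_chains_raw = take("n_chains"),
    stringsAsFactors = FALSE
  )
  rec$measurement_type <- normalize_measurement_type(rec$measurement_type_raw)
  rec$relation <- normalize_relation(rec$relation_raw)
  rec$value_num <- suppressWarnings(as.numeric(rec$value_raw))
  rec$confidence_score <- suppressWarnings(as.integer(rec$confidence_score_raw))
  rec$n_chains <- suppressWarnings(as.integer(rec$n_chains_raw))
  rec$activity_label <- normalize_activity_label(rec$activity_label_raw)
  m <- match(rec$kinase_uniprot, kinase_table$uniprot_id)
  rec$organism <- kinase_table$organism_code[m]
  rec$pref_name <- kinase_table$pref_name[m]
  rec
}

normalize_measurement_type <- function(x) {
  up <- toupper(trimws(x))
  ifelse(up %in% c("IC50", "KI", "KD"), up, up)
}

normalize_relation <- function(x) {
  x <- trimws(x)
  out <- rep("OTHER", length(x))
  out[x == "="] <- "EQ"
  out[x == ">"] <- "GT"
  out[x == ">>"] <- "GTGT"
  out[x == "<"] <- "LT"
  out
}

normalize_activity_label <- function(x) {
  lo <- tolower(trimws(ifelse(is.na(x), "", x)))
  out <- rep("NONE", length(lo))
  out[lo == "active"] <- "ACTIVE"
  out[lo %in% c("not active", "inactive")] <- "INACTIVE"
  out
}

#' Qualification settings
#'
#' @param threshold_nM activity threshold in nM; `=` measurements at or below
#'   it are active candidates, above it inactive candidates. Censored `>`/`>>`
#'   records qualify as inactive only at or above the threshold.
#' @param confidence_required ChEMBL-dialect assay confidence score required.
#' @param target_category ChEMBL-dialect target category required.
#' @param comment_blacklist case-insensitive substrings of activity comments
#'   that disqualify a record. The shipped default carries the three standard
#'   phrases; the list is open for extension.
#' @param units_map named vector of unit-to-nM multipliers. Rows in units not
#'   listed here are discarded; listed non-nM units are converted (and
#'   counted in the report) rather than discarded.
#' @return a list of settings for [qualify_records()].
#' @export
qualification_config <- function(threshold_nM = 10000,
                                 confidence_required = 9L,
                                 target_category = "SINGLE PROTEIN",
                                 comment_blacklist = c("uncertain",
                                                       "potential transcription error",
                                                       "outside typical range"),
                                 units_map = c(nM = 1, uM = 1e3, `µM` = 1e3,
                                               mM = 1e6, M = 1e9, pM = 1e-3)) {
  list(threshold_nM = threshold_nM,
       confidence_required = confidence_required,
       target_category = target_category,
       comment_blacklist = comment_blacklist,
       units_map = units_map)
}

#' Qualify parsed activity records
#'
#' Applies all record-level filters and classifies each record as an active
#' candidate, an inactive candidate, or a discard with a reason code.
#' Qualification is a total, deterministic, order-independent function of the
#' individual record: ChEMBL-dialect records must be single-protein targets at
#' the required confidence score, carry one of the three standard measurement
#' types (IC50/Ki/Kd) in units convertible to nM, a non-blacklisted comment,
#' and an activity label consistent with the threshold classification.
#' Relation handling: `=` records are active candidates at or below the
#' threshold and inactive candidates above it; `>`/`>>` records are inactive
#' candidates at or above the threshold and uninformative below it; `<` and
#' other relations are uninformative.
#'
#' @param records data.frame from [read_activity_table()] (both dialects may
#'   be row-bound).
#' @param config list from [qualification_config()].
#' @return list with `records` (input plus `value_nM`, `outcome`, `reason`)
#'   and `report` (`n_read`, `n_qualified`, `discard_counts`,
#'   `n_unit_converted`); rows always balance:
#'   `n_read == n_qualified + sum(discard_counts)`.
#' @export
qualify_records <- function(records, config = qualification_config()) {
  n <- nrow(records)
  outcome <- character(n)
  reason <- character(n)
  value_nM <- rep(NA_real_, n)
  converted <- logical(n)
  for (i in seq_len(n)) {
    r <- records[i, ]
    res <- qualify_one(r, config)
    outcome[i] <- res$outcome
    reason[i] <- res$reason
    value_nM[i] <- res$value_nM
    converted[i] <- res$converted
  }
  rec <- records
  rec$value_nM <- value_nM
  rec$outcome <- outcome
  rec$reason <- reason
  qualified <- outcome != "DISCARD"
  discards <- table(reason[!qualified])
  report <- list(
    n_read = n,
    n_qualified = sum(qualified),
    discard_counts = stats::setNames(as.integer(discards), names(discards)),
    n_unit_converted = sum(converted & qualified)
  )
  list(records = rec, report = report)
}

qualify_one <- function(r, config) {
  discard <- function(why) list(outcome = "DISCARD", reason = why,
                                value_nM = NA_real_, converted = FALSE)
  if (is.na(r$organism)) return(discard("unknown_kinase"))
  chembl <- identical(r$source, "CHEMBL")
  if (chembl) {
    if (is.na(r$target_category) ||
        toupper(r$target_category) != toupper(config$target_category))
      return(discard("not_single_protein"))
    if (is.na(r$confidence_score) ||
        r$confidence_score != config$confidence_required)
      return(discard("low_confidence"))
  } else {
    if (!is.na(r$n_chains) && r$n_chains != 1L)
      return(discard("multi_chain_target"))
  }
  if (!r$measurement_type %in% c("IC50", "KI", "KD"))
    return(discard("nonstandard_type"))
  units <- ifelse(is.na(r$units), "", trimws(r$units))
  mult <- config$units_map[units]
  if (is.na(mult)) return(discard("nonstandard_units"))
  if (is.na(r$value_num)) {
    if (is.na(r$value_raw) || !nzchar(trimws(r$value_raw)))
      return(discard("missing_value"))
    return(discard("unparseable_value"))
  }
  v <- r$value_num * unname(mult)
  if (!is.finite(v) || v <= 0) return(discard("nonpositive_value"))
  if (!is.na(r$activity_comment) && nzchar(r$activity_comment)) {
    lo <- tolower(r$activity_comment)
    if (any(vapply(config$comment_blacklist,
                   function(b) grepl(b, lo, fixed = TRUE), logical(1))))
      return(discard("comment_blacklist"))
  }
  thr <- config$threshold_nM
  out <- if (r$relation == "EQ") {
    if (v <= thr) "ACTIVE_CANDIDATE" else "INACTIVE_CANDIDATE"
  } else if (r$relation %in% c("GT", "GTGT")) {
    if (v >= thr) "INACTIVE_CANDIDATE" else return(discard("uninformative_relation"))
  } else {
    return(discard("uninformative_relation"))
  }
  if (chembl && r$activity_label != "NONE") {
    implied <- if (out == "ACTIVE_CANDIDATE") "ACTIVE" else "INACTIVE"
    if (r$activity_label != implied) return(discard("label_conflict"))
  }
  list(outcome = out, reason = "", value_nM = v,
       converted = unname(mult) != 1)
}
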