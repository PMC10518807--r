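make_kinases <- function() {
  data.frame(uniprot_id = c("P9K001", "Q9K001"),
             pref_name = c("Synthetic kinase H1", "Synthetic kinase M1"),
             organism = c("Homo sapiens", "Mus musculus"),
             organism_code = c("HUMAN", "MOUSE"),
             stringsAsFactors = FALSE)
}

# A normalized record with qualifying ChEMBL-dialect defaults.
base_record <- function(...) {
  rec <- data.frame(
    record_id = "R1", source = "CHEMBL", compound_smiles = "CCO",
    kinase_uniprot = "P9K001", measurement_type_raw = "IC50",
    relation_raw = "=", value_raw = "50", units = "nM",
    target_category = "SINGLE PROTEIN", confidence_score_raw = "9",
    activity_comment = "", activity_label_raw = "", n_chains_raw = NA,
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec$measurement_type <- toupper(rec$measurement_type_raw)
  rec$relation <- kinicurate:::normalize_relation(rec$relation_raw)
  rec$value_num <- suppressWarnings(as.numeric(rec$value_raw))
  rec$confidence_score <- suppressWarnings(as.integer(rec$confidence_score_raw))
  rec$n_chains <- suppressWarnings(as.integer(rec$n_chains_raw))
  rec$activity_label <- kinicurate:::normalize_activity_label(rec$activity_label_raw)
  k <- make_kinases()
  m <- match(rec$kinase_uniprot, k$uniprot_id)
  rec$organism <- k$organism_code[m]
  rec$pref_name <- k$pref_name[m]
  rec
}

qualify1 <- function(rec) {
  q <- qualify_records(rec)
  q$records[, c("outcome", "reason", "value_nM")]
}

test_that("threshold and relation rules classify records as specified", {
  expect_equal(qualify1(base_record(value_raw = "12000"))$outcome,
               "INACTIVE_CANDIDATE")
  ex <- qualify1(base_record(value_raw = "10000"))
  expect_equal(ex$outcome, "ACTIVE_CANDIDATE") # boundary value is active
  gt <- qualify1(base_record(relation_raw = ">", value_raw = "10000"))
  expect_equal(gt$outcome, "INACTIVE_CANDIDATE")
  expect_equal(qualify1(base_record(relation_raw = ">>",
                                    value_raw = "50000"))$outcome,
               "INACTIVE_CANDIDATE")
  # censored below the threshold carries no usable information
  expect_equal(qualify1(base_record(relation_raw = ">",
                                    value_raw = "500"))$reason,
               "uninformative_relation")
  expect_equal(qualify1(base_record(relation_raw = "<",
                                    value_raw = "50"))$reason,
               "uninformative_relation")
  expect_equal(qualify1(base_record(relation_raw = "~",
                                    value_raw = "50"))$reason,
               "uninformative_relation")
})

test_that("ChEMBL-dialect filters fire with the right reasons", {
  cases <- list(
    list(base_record(target_category = "PROTEIN FAMILY"),
         "not_single_protein"),
    list(base_record(confidence_score_raw = "8"), "low_confidence"),
    list(base_record(measurement_type_raw = "EC50"), "nonstandard_type"),
    list(base_record(units = "%"), "nonstandard_units"),
    list(base_record(value_raw = "abc"), "unparseable_value"),
    list(base_record(value_raw = ""), "missing_value"),
    list(base_record(value_raw = "-5"), "nonpositive_value"),
    list(base_record(activity_comment = "Outside typical range"),
         "comment_blacklist"),
    list(base_record(activity_comment = "value uncertain (n=1)"),
         "comment_blacklist"),
    list(base_record(value_raw = "50000", activity_label_raw = "Active"),
         "label_conflict"),
    list(base_record(kinase_uniprot = "ZZZ999"), "unknown_kinase")
  )
  for (cs in cases) {
    q <- qualify1(cs[[1]])
    expect_equal(q$outcome, "DISCARD", info = cs[[2]])
    expect_equal(q$reason, cs[[2]])
  }
  # consistent label passes
  ok <- qualify1(base_record(activity_label_raw = "Active"))
  expect_equal(ok$outcome, "ACTIVE_CANDIDATE")
})

test_that("BindingDB-dialect records skip ChEMBL-only filters", {
  rec <- base_record(source = "BINDINGDB", target_category = NA,
                     confidence_score_raw = NA, measurement_type_raw = "Ki",
                     value_raw = "20")
  q <- qualify1(rec)
  expect_equal(q$outcome, "ACTIVE_CANDIDATE")
  expect_equal(q$value_nM, 20)
  multi <- base_record(source = "BINDINGDB", target_category = NA,
                       confidence_score_raw = NA, n_chains_raw = "2")
  expect_equal(qualify1(multi)$reason, "multi_chain_target")
})

test_that("non-nM units are converted, not discarded", {
  um <- qualify1(base_record(value_raw = "2", units = "uM"))
  expect_equal(um$outcome, "ACTIVE_CANDIDATE")
  expect_equal(um$value_nM, 2000)
  pm <- qualify1(base_record(value_raw = "500", units = "pM"))
  expect_equal(pm$value_nM, 0.5)
  q <- qualify_records(base_record(value_raw = "2", units = "uM"))
  expect_equal(q$report$n_unit_converted, 1)
})

test_that("qualification is order-independent and rows always balance", {
  recs <- do.call(rbind, list(
    base_record(), base_record(record_id = "R2", value_raw = "20000"),
    base_record(record_id = "R3", confidence_score_raw = "7"),
    base_record(record_id = "R4", relation_raw = ">", value_raw = "10000"),
    base_record(record_id = "R5", measurement_type_raw = "EC50"),
    base_record(record_id = "R6", value_raw = "oops")
  ))
  q1 <- qualify_records(recs)
  perm <- sample(nrow(recs))
  q2 <- qualify_records(recs[perm, , drop = FALSE])
  expect_equal(sort(paste(q1$records$record_id, q1$records$outcome)),
               sort(paste(q2$records$record_id, q2$records$outcome)))
  expect_equal(q1$report$n_read,
               q1$report$n_qualified + sum(q1$report$discard_counts))
  expect_equal(q1$report$discard_counts, q2$report$discard_counts)
})

test_that("dialect parsing validates files and columns", {
  kin <- make_kinases()
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("activity_id\tcanonical_smiles\taccession",
                     "A1\tCCO\tP9K001"), collapse = "\n"), tmp)
  expect_error(read_activity_table(tmp, "chembl", kin), "missing")
  expect_error(read_activity_table("/nonexistent.tsv", "chembl", kin),
               "not found")
  expect_error(dialect_preset("nosuch"), "unknown dialect")
  # a complete ChEMBL-dialect row maps onto the normalized schema
  hdr <- c("activity_id", "canonical_smiles", "accession", "standard_type",
           "standard_relation", "standard_value", "standard_units",
           "target_type", "confidence_score", "activity_comment",
           "activity_label")
  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste(hdr, collapse = "\t"),
               paste(c("A1", "CCO", "P9K001", "IC50", "=", "50", "nM",
                       "SINGLE PROTEIN", "9", "", ""), collapse = "\t")),
             tmp2)
  rec <- read_activity_table(tmp2, "chembl", kin)
  expect_equal(rec$measurement_type, "IC50")
  expect_equal(rec$relation, "EQ")
  expect_equal(rec$value_num, 50)
  expect_equal(rec$organism, "HUMAN")
})
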