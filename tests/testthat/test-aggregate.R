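pair_df <- function(type, relation, value_nM) {
  n <- length(value_nM)
  data.frame(
    record_id = sprintf("R%03d", seq_len(n)),
    compound_new_id = 1L, compound_key = "CCO", kinase_uniprot = "P9K001",
    organism = "HUMAN", pref_name = "k",
    measurement_type = rep_len(type, n), relation = rep_len(relation, n),
    value_nM = value_nM, stringsAsFactors = FALSE
  )
}

test_that("log transform maps nM potencies onto the negative decadic scale", {
  expect_identical(to_log(1), 9)
  expect_identical(to_log(10000), 5)
  expect_identical(to_log(100), 7)
  expect_error(to_log(0))
  expect_error(to_log(-3))
})

test_that("within-type means, the SD gate and type priority work as specified", {
  # two IC50 values 10 and 100 nM average to 7.5 on the log scale
  a <- aggregate_pair(pair_df("IC50", "EQ", c(10, 100)))
  expect_equal(a$mean_log, 7.5)
  expect_equal(a$status, "ACTIVE")
  expect_equal(a$selected_type, "IC50")
  # logs {8, 5} have sample SD ~2.12 > 1: the only aggregate is discarded
  b <- aggregate_pair(pair_df("IC50", "EQ", c(10, 10000)))
  expect_equal(b$status, "DISCARDED_SD")
  expect_true(is.na(b$mean_log))
  # assay-independent Ki outranks IC50
  d <- aggregate_pair(rbind(pair_df("IC50", "EQ", 50)[, ],
                            pair_df("KI", "EQ", 20)))
  expect_equal(d$selected_type, "KI")
  expect_equal(d$mean_log, 9 - log10(20), tolerance = 1e-12)
  expect_equal(d$selected_stvalue, "Ki")
  # Kd outranks Ki when both are valid
  e <- aggregate_pair(rbind(pair_df("KI", "EQ", 100), pair_df("KD", "EQ", 10)))
  expect_equal(e$selected_type, "KD")
  # an SD-violating Ki falls back to a consistent IC50
  f <- aggregate_pair(rbind(pair_df("KI", "EQ", c(1, 5000)),
                            pair_df("IC50", "EQ", 50)))
  expect_equal(f$selected_type, "IC50")
  expect_equal(f$status, "ACTIVE")
})

test_that("quantitative/qualitative conflicts and censored-only pairs", {
  # active measurement plus a censored inactive record: conflicting, dropped
  m <- rbind(pair_df("IC50", "EQ", 50), pair_df("IC50", "GT", 10000))
  expect_equal(aggregate_pair(m)$status, "DISCARDED_CONFLICT")
  # censored-only pair: qualitative inactive with no numeric potency
  q <- aggregate_pair(pair_df("IC50", "GT", 10000))
  expect_equal(q$status, "INACTIVE")
  expect_equal(q$selected_type, "QUALITATIVE")
  expect_equal(q$selected_stvalue, "qualitative")
  expect_true(is.na(q$mean_log))
  # quantitative inactive plus censored record agree: no conflict
  g <- rbind(pair_df("IC50", "EQ", 50000), pair_df("IC50", "GT", 10000))
  expect_equal(aggregate_pair(g)$status, "INACTIVE")
})

test_that("aggregation is permutation-invariant and monotone", {
  set.seed(7)
  for (i in 1:25) {
    m <- random_pair_measurements()
    a <- aggregate_pair(m)
    b <- aggregate_pair(m[sample(nrow(m)), , drop = FALSE])
    expect_identical(a[, c("selected_type", "status", "activity_ids")],
                     b[, c("selected_type", "status", "activity_ids")])
    expect_equal(a$mean_log, b$mean_log, tolerance = 1e-12)
    # scaling every value up strictly decreases the mean log potency
    if (!is.na(a$mean_log)) {
      m2 <- m
      m2$value_nM <- m2$value_nM * 10
      a2 <- aggregate_pair(m2)
      if (!is.na(a2$mean_log)) expect_lt(a2$mean_log, a$mean_log)
    }
  }
  # singleton sets are exact and never SD-gated
  s <- aggregate_pair(pair_df("KD", "EQ", 3.7))
  expect_identical(s$mean_log, to_log(3.7))
  expect_equal(s$status, "ACTIVE")
})

test_that("random measurement sets match the brute-force oracle", {
  set.seed(19)
  for (i in 1:100) {
    m <- random_pair_measurements()
    got <- aggregate_pair(m)
    exp <- oracle_aggregate_pair(m)
    expect_equal(got$selected_type, exp$selected_type)
    expect_equal(got$status, exp$status)
    expect_equal(got$mean_log, exp$mean_log, tolerance = 1e-12)
  }
})

test_that("pair grouping and the four-way dataset split are per-pair", {
  recs <- rbind(
    cbind(pair_df("IC50", "EQ", 50), key = "a"),
    cbind(pair_df("IC50", "EQ", 50000), key = "b"),
    cbind(pair_df("IC50", "GT", 10000), key = "c")
  )
  recs$compound_new_id <- c(1L, 1L, 2L)
  recs$kinase_uniprot <- c("P9K001", "P9K002", "P9K001")
  recs$organism <- c("HUMAN", "HUMAN", "MOUSE")
  recs$record_id <- sprintf("R%d", 1:3)
  ann <- aggregate_pairs(recs)
  expect_equal(nrow(ann), 3)
  sets <- split_datasets(ann)
  # compound 1 is active on one kinase and inactive on another
  expect_equal(sets$human_active$compound_new_id, 1L)
  expect_equal(sets$human_inactive$compound_new_id, 1L)
  expect_equal(sets$mouse_inactive$compound_new_id, 2L)
  expect_equal(nrow(sets$mouse_active), 0)
  # discarded pairs never reach a dataset
  disc <- aggregate_pairs(rbind(
    transform(pair_df("IC50", "EQ", c(10, 10000)), record_id = c("X1", "X2"))
  ))
  expect_equal(disc$status, "DISCARDED_SD")
  s2 <- split_datasets(disc)
  expect_true(all(vapply(s2, nrow, integer(1)) == 0))
})
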