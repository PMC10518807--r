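test_that("deposition files carry the verbatim schema and NaN convention", {
  res <- clean_pipeline()
  dir <- withr::local_tempdir()
  paths <- write_datasets(res$annotations, res$compounds,
                          cpki = res$warheads$cpki, out_dir = dir)
  expect_setequal(basename(unname(paths)),
                  c("human_PKI_active.tsv", "human_PKI_inactive.tsv",
                    "mouse_PKI_active.tsv", "mouse_PKI_inactive.tsv"))
  schema <- c("Compound_new_ID", "nonstereo_aromatic_smile", "Uniprot_ID",
              "pref_name", "activity_id", "mean_log", "selected_stvalue",
              "ORGANISM")
  for (nm in names(paths)) {
    d <- read_deposition_file(paths[[nm]])
    if (nm == "human_active") {
      expect_identical(names(d), c(schema, "CPKI"))
    } else {
      expect_identical(names(d), schema)
    }
    # qualitative-only rows carry the literal NaN and selected value tag
    qual <- d$selected_stvalue == "qualitative"
    expect_true(all(d$mean_log[qual] == "NaN"))
    expect_false(any(d$mean_log[!qual] == "NaN"))
  }
  ha <- read_deposition_file(paths[["human_active"]])
  expect_true(any(ha$CPKI == "True"))
  expect_true(file.exists(file.path(dir, "readme.txt")))
})

test_that("deposition output is byte-stable on rerun and on round-trip", {
  res <- clean_pipeline()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_datasets(res$annotations, res$compounds, cpki = res$warheads$cpki,
                 out_dir = d1)
  write_datasets(res$annotations, res$compounds, cpki = res$warheads$cpki,
                 out_dir = d2)
  for (f in c("human_PKI_active.tsv", "human_PKI_inactive.tsv",
              "mouse_PKI_active.tsv", "mouse_PKI_inactive.tsv")) {
    b1 <- readBin(file.path(d1, f), "raw", file.size(file.path(d1, f)))
    b2 <- readBin(file.path(d2, f), "raw", file.size(file.path(d2, f)))
    expect_identical(b1, b2, info = f)
    # read back and rewrite: identical bytes again
    d <- read_deposition_file(file.path(d1, f))
    out <- file.path(d2, paste0("rt_", f))
    utils::write.table(d, out, sep = "\t", quote = FALSE, row.names = FALSE,
                       fileEncoding = "UTF-8")
    b3 <- readBin(out, "raw", file.size(out))
    expect_identical(b1, b3, info = f)
  }
})

test_that("distribution summary follows type-7 quantiles and Tukey fences", {
  x <- c(6, 7, 8)
  s <- distribution_summary(x)
  expect_equal(s$median, 7)
  expect_equal(s$q1, unname(stats::quantile(x, 0.25, type = 7)))
  expect_equal(s$n, 3L)
  # an extreme value beyond 1.5 IQR lands in the outlier list
  y <- c(rep(6:8, 10), 15)
  sy <- distribution_summary(y)
  expect_true(15 %in% sy$outliers)
  expect_lt(sy$whisker_hi, 15)
  expect_true(sy$min <= sy$q1 && sy$q1 <= sy$median &&
                sy$median <= sy$q3 && sy$q3 <= sy$max)
  expect_equal(distribution_summary(numeric(0))$n, 0L)
})

test_that("summary counting matches hand-computed values on a toy corpus", {
  ann <- data.frame(
    compound_new_id = c(1L, 1L, 2L, 3L),
    compound_key = c("a", "a", "b", "c"),
    kinase_uniprot = c("P1", "P2", "P1", "P2"),
    organism = "HUMAN", pref_name = "k",
    selected_type = c("IC50", "IC50", "KI", "IC50"),
    mean_log = c(6, 7, 8, 4.5),
    selected_stvalue = c("IC50", "IC50", "Ki", "IC50"),
    status = c("ACTIVE", "ACTIVE", "ACTIVE", "INACTIVE"),
    n_measurements = 1L, activity_ids = sprintf("R%d", 1:4),
    stringsAsFactors = FALSE
  )
  s <- summarize_curation(ann)
  expect_equal(s$human$n_active_compounds, 2)
  expect_equal(s$human$n_inactive_compounds, 1)
  expect_equal(s$human$n_interactions, 4)
  expect_equal(s$human$n_kinases_with_active, 2)
  expect_equal(s$human$n_kinases_with_inactive, 1)
  expect_equal(s$human$potency$median, 7)
  expect_equal(s$mouse$n_interactions, 0)
})
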