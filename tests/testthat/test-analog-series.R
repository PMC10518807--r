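test_that("fragmentation enumerates retrosynthetic candidate cores", {
  # methane has no cuttable bonds: only the trivial candidate
  m <- fragment_compound("C")
  expect_length(m$candidates, 1)
  expect_equal(m$candidates[[1]]$n_sites, 0L)
  # N-phenylacetamide: the amide C-N environment is cut, anilide side is core
  f <- fragment_compound("CC(=O)Nc1ccccc1")
  cores <- vapply(f$candidates, `[[`, character(1), "core_smiles")
  expect_true(f$compound %in% cores) # trivial candidate always present
  expect_true("[1*]Nc1ccccc1" %in% cores)
  amide <- f$candidates[[which(cores == "[1*]Nc1ccccc1")]]
  expect_equal(amide$subs$sub_smiles, "[1*]C(=O)C")
  # a para-disubstituted benzamide exposes the shared two-site core
  g <- fragment_compound("CCOc1ccc(C(=O)Nc2ccc(NC(C)C)cc2)cc1")
  two_site <- Filter(function(x) x$n_sites == 2, g$candidates)
  expect_gt(length(two_site), 0)
  expect_true(any(vapply(two_site, function(x) {
    setequal(x$subs$site, 1:2)
  }, logical(1))))
})

test_that("candidate enumeration matches the exhaustive oracle", {
  mols <- c("CC(=O)Nc1ccccc1", "CCOc1ccc(C(=O)Nc2ccc(NC(C)C)cc2)cc1",
            "COc1ccc(Cc2ccccc2)cc1", "O=C(NC1CC1)c1ccc(N2CCOCC2)cc1")
  for (s in mols) {
    eng <- fragment_compound(s)
    got <- sort(vapply(eng$candidates, `[[`, character(1), "core_smiles"),
                method = "radix")
    exp <- sort(oracle_candidate_cores(s)$core, method = "radix")
    expect_identical(got, exp, info = s)
  }
})

test_that("reassembly reconstructs each compound from core and R-groups", {
  mols <- c("CCOc1ccc(C(=O)Nc2ccc(NC(C)C)cc2)cc1",
            "CC(=O)Nc1ccccc1", "COc1ccc(Cc2ccccc2)cc1")
  for (s in mols) {
    f <- fragment_compound(s)
    for (cand in f$candidates) {
      if (cand$n_sites == 0) next
      expect_identical(join_fragments(cand$core_smiles, cand$subs$sub_smiles),
                       f$compound, info = cand$core_smiles)
    }
  }
})

test_that("assignment forms planted series and leaves unrelated singletons", {
  # three analogues differing at one phenyl position form one series
  trio <- standardize_smiles(c("CCOc1ccc(C(=O)Nc2ccc(C)cc2)cc1",
                               "CCOc1ccc(C(=O)Nc2ccc(CC)cc2)cc1",
                               "CCOc1ccc(C(=O)Nc2ccc(OC)cc2)cc1"))$compound_key
  res <- assign_series(trio)
  expect_equal(nrow(res$series), 1)
  expect_equal(res$series$n_members, 3)
  expect_setequal(res$members$compound_key, trio)
  expect_equal(nrow(res$singletons), 0)
  # two structurally unrelated scaffolds: no series, two singletons
  duo <- standardize_smiles(c("c1ccc2[nH]ccc2c1", "CC(C)NCC(O)CO"))$compound_key
  res2 <- assign_series(duo)
  expect_equal(nrow(res2$series), 0)
  expect_equal(nrow(res2$singletons), 2)
  expect_identical(res2$singletons$core_smiles, res2$singletons$compound_key)
})

test_that("series/singleton partition is disjoint, covering and deterministic", {
  ap <- analog_pool()
  take <- ap$pool[seq(1, length(ap$pool), by = 2)]
  r1 <- assign_series(take, candidates = ap$engine[take])
  assigned <- c(r1$members$compound_key, r1$singletons$compound_key)
  expect_setequal(assigned, take)
  expect_false(anyDuplicated(assigned) > 0)
  # input order never matters
  r2 <- assign_series(rev(take), candidates = ap$engine[rev(take)])
  expect_identical(r1$series, r2$series)
  expect_identical(r1$members, r2$members)
  expect_identical(r1$singletons, r2$singletons)
  # distinct cores = series + singletons
  cores <- c(r1$series$core_smiles, r1$singletons$core_smiles)
  expect_equal(length(unique(cores)), nrow(r1$series) + nrow(r1$singletons))
})

test_that("assignment equals the candidate-core intersection oracle", {
  ap <- analog_pool()
  set.seed(3)
  for (i in 1:10) {
    take <- sort(sample(ap$pool, sample(6:14, 1)), method = "radix")
    got <- assign_series(take, candidates = ap$engine[take])
    exp <- oracle_assign(ap$oracle[take])
    got_sets <- lapply(split(got$members$compound_key, got$members$series_id),
                       sort, method = "radix")
    exp_cores <- if (length(exp$series)) names(exp$series) else character(0)
    expect_setequal(as.character(got$series$core_smiles), exp_cores)
    for (sid in seq_len(nrow(got$series))) {
      core <- got$series$core_smiles[sid]
      expect_identical(got_sets[[got$series$series_id[sid]]],
                       exp$series[[core]])
    }
    expect_identical(sort(got$singletons$compound_key, method = "radix"),
                     exp$singletons)
  }
})

test_that("r-group tables align members site by site", {
  smi <- standardize_smiles(c("CCOc1ccc(C(=O)Nc2ccc(C)cc2)cc1",
                              "CCOc1ccc(C(=O)Nc2ccc(CC)cc2)cc1",
                              "COc1ccc(C(=O)Nc2ccc(C)cc2)cc1"))$compound_key
  res <- assign_series(smi)
  expect_equal(nrow(res$series), 1)
  rg <- res$rgroups
  # every member has one substituent row per site
  n_sites <- res$series$n_sites
  expect_true(all(table(rg$compound_key) == n_sites))
  # reassembly invariant on every member
  for (cp in unique(rg$compound_key)) {
    subs <- rg$sub_smiles[rg$compound_key == cp]
    expect_identical(join_fragments(res$series$core_smiles, subs), cp)
  }
  # members differing at a single site differ in exactly one table entry
  a <- rg[rg$compound_key == smi[1], ]
  b <- rg[rg$compound_key == smi[2], ]
  if (n_sites > 0) {
    diff <- sum(a$sub_smiles[order(a$site)] != b$sub_smiles[order(b$site)])
    expect_equal(diff, 1)
  }
})
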