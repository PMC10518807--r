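# Seeded synthetic corpus generator with recorded ground truth.
#
# Compounds are built by decorating kinase-inhibitor-like scaffold templates
# (two attachment sites each) with R-groups from a small fragment library, so
# the analogue-series structure of the corpus is planted and known. Potencies
# are drawn per compound-kinase pair on the log scale and emitted as 1-4
# measurement records with small log-normal noise, split across the two
# source dialects. Salt forms, stereo flips, protonated forms, censored
# records, conflicting and over-dispersed measurement sets, and record-level
# decoys (blacklisted comments, low-confidence rows, off-type rows,
# multi-chain rows) are injected at configurable rates, and every planted
# fact is recorded in the returned ground truth before decoration.
#
# All identifiers in generated tables (kinase accessions, record ids) are
# synthetic.

# 34 structurally distinct scaffold templates with two labelled attachment
# sites. Distinctness (no two scaffolds share a candidate core under <= 2
# cuts) is what guarantees that planted series cannot merge.
.fixture_scaffolds <- c(
  "[1*]c1ccc(C(=O)Nc2ccc([2*])cc2)cc1",
  "[1*]c1ccc(C(=O)Nc2ccc([2*])cc2C)cc1",
  "[1*]c1cc(C)c(C(=O)Nc2ccc([2*])cc2)cc1",
  "[1*]c1ccc2ncnc(Nc3ccc([2*])cc3)c2c1",
  "[1*]c1ccc2ncnc(Nc3ccc([2*])cc3C)c2c1",
  "[1*]c1ccc(Nc2ncnc3cc(OC)c([2*])cc23)cc1",
  "[1*]c1ccc(S(=O)(=O)Nc2ccc([2*])cc2)cc1",
  "[1*]c1ccc(NC(=O)c2cc([2*])cs2)cc1",
  "[1*]c1ccc(NC(=O)c2cc([2*])co2)cc1",
  "[1*]c1ccc(NC(=O)c2cc([2*])c[nH]2)cc1",
  "[1*]c1ccc(-c2nc3cc([2*])ccc3[nH]2)cc1",
  "[1*]c1ccc(-c2nc3cc([2*])ccc3s2)cc1",
  "[1*]c1ccc(-c2nc3cc([2*])ccc3o2)cc1",
  "[1*]c1ccc(Cc2ccc([2*])cc2)cc1",
  "[1*]c1ccc(CNC(=O)c2ccc([2*])cc2)cc1",
  "[1*]c1ccc(C(=O)N2CCN(c3ccc([2*])cc3)CC2)cc1",
  "[1*]c1cc2cc([2*])ccc2[nH]1",
  "[1*]c1ccc2ncc([2*])cc2c1",
  "[1*]c1ccc(N(C)C(=O)c2ccc([2*])cc2)cc1",
  "[1*]c1ccc(OCc2ccc([2*])cc2)cc1",
  "[1*]c1ccc(C(=O)Nc2cccc([2*])c2)cc1",
  "[1*]c1ccc(NC(=O)C2CCN([2*])CC2)cc1",
  "[1*]c1ccc(-n2cc([2*])cn2)cc1",
  "[1*]c1ccc(NC(=O)Nc2ccc([2*])cc2)cc1",
  "[1*]c1nc2ccccc2n1Cc1ccc([2*])cc1",
  "[1*]c1ccc(C(=O)Nc2ccc([2*])nc2)cc1",
  "[1*]c1ccc(CN2CCC([2*])CC2)cc1",
  "[1*]c1ccc(Oc2ccc([2*])cc2)cc1",
  "[1*]c1cnc(Nc2ccc([2*])cc2)nc1C",
  "[1*]c1ccc(NS(=O)(=O)c2ccc([2*])cc2C)cc1",
  "[1*]c1csc(NC(=O)c2ccc([2*])cc2)n1",
  "[1*]c1ccc(-c2cc([2*])n(C)n2)cc1",
  "[1*]c1ccc(C(=O)NCc2ccc([2*])cn2)cc1",
  "[1*]c1ccc2[nH]c([2*])nc2c1"
)

# R-group fragment library. Entries deliberately avoid every motif in the
# shipped warhead registry so covalent ground truth stays planted, not
# accidental. `charged_from`/`charged_to` give a protonation-state rewrite
# for charge decorations; `stereo_from`/`stereo_to` an enantiomer flip.
.fixture_rgroups <- data.frame(
  sub_smiles = c("[*]C", "[*]CC", "[*]CCC", "[*]C(C)C", "[*]C(C)(C)C",
                 "[*]CCCC", "[*]OC", "[*]OCC", "[*]OC(C)C", "[*]O", "[*]CO",
                 "[*]CCO", "[*]N", "[*]NC", "[*]N(C)C", "[*]NCC",
                 "[*]NC(=O)C", "[*]C(=O)NC", "[*]C(=O)N(C)C", "[*]CN1CCOCC1",
                 "[*]N1CCOCC1", "[*]N1CCN(C)CC1", "[*]CC(=O)O", "[*]CCN(C)C",
                 "[*][C@@H](C)CC", "[*][C@H](O)CC", "[*]c1ccccc1",
                 "[*]Cc1ccccc1"),
  heavy = c(1, 2, 3, 3, 4, 4, 2, 3, 4, 1, 2, 3, 1, 2, 3, 3, 4, 4, 5, 7, 6,
            7, 4, 5, 4, 4, 6, 7),
  charged_from = c(rep("", 22), "C(=O)O", "N(C)C", rep("", 4)),
  charged_to = c(rep("", 22), "C(=O)[O-]", "[NH+](C)C", rep("", 4)),
  stereo_from = c(rep("", 24), "[C@@H]", "[C@H]", "", ""),
  stereo_to = c(rep("", 24), "[C@H]", "[C@@H]", "", ""),
  stringsAsFactors = FALSE
)

.warhead_rgroup <- list(sub_smiles = "[*]NC(=O)C=C", heavy = 5,
                        warhead = "acrylamide")

#' Specification of a synthetic fixture corpus
#'
#' @param seed integer seed; generation is bit-reproducible given the spec.
#' @param n_series number of planted analogue series.
#' @param series_size_range inclusive range of members per series.
#' @param n_singletons number of planted singletons (compounds whose core is
#'   shared with no other compound).
#' @param n_kinases number of kinases in the annotation table (three quarters
#'   human, rounded up; the rest mouse).
#' @param frac_inactive fraction of pairs planted as quantitatively inactive
#'   (`=` values above 10,000 nM).
#' @param frac_qualitative fraction of pairs planted as censored-only
#'   (`>` records, qualitative inactive).
#' @param frac_conflict fraction of pairs planted with both an active
#'   quantitative result and a censored record (discarded as conflicting).
#' @param frac_sd_violation fraction of pairs planted with one measurement
#'   type whose log values disperse beyond the SD gate (discarded).
#' @param warhead_insertion_rate fraction of compounds that receive an
#'   acrylamide R-group (planted covalent flag).
#' @param dialect_split probability that a record is emitted in the
#'   ChEMBL-like dialect (otherwise BindingDB-like).
#' @param salt_rate fraction of records whose SMILES is decorated as an HCl
#'   salt.
#' @param charged_rate fraction of records rewritten to a protonated or
#'   deprotonated form (when the compound carries an ionizable R-group).
#' @param decoy_rate fraction of pairs that receive one additional
#'   non-qualifying decoy record (off-type, low-confidence, blacklisted
#'   comment, conflicting label, or multi-chain).
#' @param unit_um_rate fraction of ChEMBL-dialect records expressed in uM
#'   instead of nM (conversion exercise; value unchanged).
#' @param mean_log_center,mean_log_sd center and spread of the true log
#'   potency distribution of active pairs (potencies mostly in the 6-8 log
#'   range).
#' @param noise_sd log-scale standard deviation of repeated measurements.
#' @return a list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_series = 20L,
                         series_size_range = c(3L, 6L), n_singletons = 10L,
                         n_kinases = 8L, frac_inactive = 0.15,
                         frac_qualitative = 0.08, frac_conflict = 0,
                         frac_sd_violation = 0, warhead_insertion_rate = 0.1,
                         dialect_split = 0.6, salt_rate = 0.15,
                         charged_rate = 0.3, decoy_rate = 0,
                         unit_um_rate = 0.1, mean_log_center = 7,
                         mean_log_sd = 0.8, noise_sd = 0.2) {
  spec <- list(seed = as.integer(seed), n_series = as.integer(n_series),
               series_size_range = as.integer(series_size_range),
               n_singletons = as.integer(n_singletons),
               n_kinases = as.integer(n_kinases),
               frac_inactive = frac_inactive,
               frac_qualitative = frac_qualitative,
               frac_conflict = frac_conflict,
               frac_sd_violation = frac_sd_violation,
               warhead_insertion_rate = warhead_insertion_rate,
               dialect_split = dialect_split, salt_rate = salt_rate,
               charged_rate = charged_rate, decoy_rate = decoy_rate,
               unit_um_rate = unit_um_rate,
               mean_log_center = mean_log_center, mean_log_sd = mean_log_sd,
               noise_sd = noise_sd)
  fr <- c(spec$frac_inactive, spec$frac_qualitative, spec$frac_conflict,
          spec$frac_sd_violation)
  stopifnot(all(fr >= 0), sum(fr) <= 1,
            spec$n_series + spec$n_singletons <= length(.fixture_scaffolds))
  class(spec) <- "fixture_spec"
  spec
}

#' Generate a synthetic two-dialect corpus with ground truth
#'
#' @param spec a [fixture_spec()].
#' @param out_dir if non-NULL, the three input tables are also written there
#'   as `chembl_activities.tsv`, `bindingdb_activities.tsv`, `kinases.tsv`.
#' @return list with `chembl`, `bindingdb` (activity tables in their dialect
#'   column schemas), `kinases` (annotation table), `truth` (ground truth:
#'   `compounds`, `pairs`, `records`, planted counts), and `paths` when
#'   `out_dir` was given.
#' @export
generate_fixtures <- function(spec = fixture_spec(), out_dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(spec$seed)

  kin <- fixture_kinases(spec$n_kinases)
  cmp <- fixture_compounds(spec)
  gen <- fixture_records(spec, cmp, kin)

  truth <- list(compounds = cmp$table, pairs = gen$pairs,
                records = gen$record_map, planted = gen$planted)
  out <- list(chembl = gen$chembl, bindingdb = gen$bindingdb, kinases = kin,
              truth = truth)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    paths <- c(chembl = file.path(out_dir, "chembl_activities.tsv"),
               bindingdb = file.path(out_dir, "bindingdb_activities.tsv"),
               kinases = file.path(out_dir, "kinases.tsv"))
    utils::write.table(gen$chembl, paths["chembl"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    utils::write.table(gen$bindingdb, paths["bindingdb"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(kin, paths["kinases"], sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths <- paths
  }
  out
}

fixture_kinases <- function(n_kinases) {
  n_h <- ceiling(n_kinases * 0.75)
  n_m <- n_kinases - n_h
  data.frame(
    uniprot_id = c(sprintf("P9K%03d", seq_len(n_h)),
                   if (n_m > 0) sprintf("Q9K%03d", seq_len(n_m))),
    pref_name = c(sprintf("Synthetic kinase H%d", seq_len(n_h)),
                  if (n_m > 0) sprintf("Synthetic kinase M%d", seq_len(n_m))),
    organism = c(rep("Homo sapiens", n_h), rep("Mus musculus", n_m)),
    stringsAsFactors = FALSE
  )
}

label_rgroup <- function(sub_smiles, site) {
  sub("[*]", sprintf("[%d*]", site), sub_smiles, fixed = TRUE)
}

# Textual grafting of two R-group bodies onto a scaffold template. Every
# template starts with "[1*]c1" and carries a parenthesised "([2*])" site, so
# substitution stays a pure string operation and preserves stereo marks in
# the substituents (graph-level reattachment would lose them).
graft_rgroups <- function(scaffold, sub1, sub2) {
  stopifnot(startsWith(scaffold, "[1*]c1"),
            grepl("([2*])", scaffold, fixed = TRUE))
  # ring-closure digits in the body would pair with the template's open ring
  # bonds; the library only uses digit 1, templates use 1-3, so move to 9
  body1 <- gsub("1", "9", sub("[*]", "", sub1, fixed = TRUE), fixed = TRUE)
  body2 <- gsub("1", "9", sub("[*]", "", sub2, fixed = TRUE), fixed = TRUE)
  s <- paste0("c1(", body1, ")", substring(scaffold, nchar("[1*]c1") + 1))
  sub("([2*])", paste0("(", body2, ")"), s, fixed = TRUE)
}

# Build the planted compound set: n_series scaffolds decorated with varying
# R-group pairs, n_singletons further scaffolds decorated once each.
fixture_compounds <- function(spec) {
  lib <- .fixture_rgroups
  scaff <- .fixture_scaffolds
  n_total <- spec$n_series + spec$n_singletons
  scaff_idx <- sample(length(scaff), n_total)
  series_scaff <- scaff_idx[seq_len(spec$n_series)]
  single_scaff <- scaff_idx[spec$n_series + seq_len(spec$n_singletons)]

  scaff_heavy <- vapply(scaff, function(s) {
    heavy_atom_count(smiles_to_mol(s))
  }, numeric(1))

  rows <- list()
  warhead_flags <- logical(0)
  draw_combo <- function(budget, force_warhead = FALSE) {
    repeat {
      i1 <- if (force_warhead) 0L else sample(nrow(lib), 1)
      i2 <- sample(nrow(lib), 1)
      h1 <- if (force_warhead) .warhead_rgroup$heavy else lib$heavy[i1]
      if (h1 + lib$heavy[i2] <= budget) return(c(i1, i2))
    }
  }
  cid <- 0L
  for (si in seq_len(spec$n_series)) {
    size <- sample(seq(spec$series_size_range[1], spec$series_size_range[2]),
                   1)
    budget <- floor(scaff_heavy[series_scaff[si]] / 2)
    n_war <- stats::rbinom(1, size, spec$warhead_insertion_rate)
    # the warhead fragment must fit the substituent budget, and at least one
    # member per site must differ so the planted core is the maximal cover
    n_war <- min(n_war, size - 1L)
    if (budget < .warhead_rgroup$heavy + 1) n_war <- 0L
    repeat {
      combos <- t(vapply(seq_len(size), function(m) {
        draw_combo(budget, force_warhead = m <= n_war)
      }, numeric(2)))
      if (anyDuplicated(combos) == 0 &&
          (size < 2 || (length(unique(combos[, 1])) >= 2 &&
                        length(unique(combos[, 2])) >= 2))) break
    }
    for (m in seq_len(size)) {
      cid <- cid + 1L
      rows[[cid]] <- list(gen_id = cid, group = sprintf("series%02d", si),
                          scaffold = series_scaff[si],
                          r1 = combos[m, 1], r2 = combos[m, 2])
      warhead_flags[cid] <- combos[m, 1] == 0L
    }
  }
  for (gi in seq_len(spec$n_singletons)) {
    cid <- cid + 1L
    budget <- floor(scaff_heavy[single_scaff[gi]] / 2)
    war <- stats::runif(1) < spec$warhead_insertion_rate &&
      budget >= .warhead_rgroup$heavy + 1
    combo <- draw_combo(budget, force_warhead = war)
    rows[[cid]] <- list(gen_id = cid, group = sprintf("singleton%02d", gi),
                        scaffold = single_scaff[gi],
                        r1 = combo[1], r2 = combo[2])
    warhead_flags[cid] <- war
  }

  sub1 <- function(r) if (r == 0L) .warhead_rgroup$sub_smiles
                      else lib$sub_smiles[r]
  smiles <- vapply(rows, function(r) {
    graft_rgroups(scaff[r$scaffold], sub1(r$r1), lib$sub_smiles[r$r2])
  }, character(1))
  std <- standardize_smiles(smiles)
  if (!all(std$ok)) {
    stop("internal error: grafted fixture SMILES failed to parse")
  }
  if (anyDuplicated(std$compound_key) > 0) {
    stop("infeasible fixture spec: R-group sampling produced duplicate ",
         "compounds; reduce series sizes or enlarge the fragment library")
  }
  tab <- data.frame(
    gen_id = vapply(rows, `[[`, integer(1), "gen_id"),
    group = vapply(rows, `[[`, character(1), "group"),
    scaffold = scaff[vapply(rows, `[[`, numeric(1), "scaffold")],
    smiles = smiles,
    r1 = vapply(rows, function(r) sub1(r$r1), character(1)),
    r2 = lib$sub_smiles[vapply(rows, `[[`, numeric(1), "r2")],
    warhead = warhead_flags,
    stringsAsFactors = FALSE
  )
  list(table = tab, lib = lib)
}

# Decorate a source SMILES for one record: optional enantiomer flip,
# protonation-state rewrite, and salt form. The standardized key is invariant
# under all three.
decorate_smiles <- function(smiles, lib, flip_stereo, charge, salt) {
  s <- smiles
  if (flip_stereo) {
    for (i in which(nzchar(lib$stereo_from))) {
      if (grepl(lib$stereo_from[i], s, fixed = TRUE)) {
        s <- sub(lib$stereo_from[i], lib$stereo_to[i], s, fixed = TRUE)
        break
      }
    }
  }
  if (charge) {
    for (i in which(nzchar(lib$charged_from))) {
      if (grepl(lib$charged_from[i], s, fixed = TRUE)) {
        s <- sub(lib$charged_from[i], lib$charged_to[i], s, fixed = TRUE)
        break
      }
    }
  }
  if (salt) s <- paste0(s, ".Cl")
  s
}

# Emit measurement records for every compound-kinase pair and record the
# pair-level ground truth from the exact values written to the tables.
fixture_records <- function(spec, cmp, kin) {
  lib <- cmp$lib
  compounds <- cmp$table
  chembl <- list(); bindingdb <- list()
  pairs <- list(); record_map <- list()
  planted <- c(conflict = 0L, sd_violation = 0L, qualitative = 0L,
               inactive = 0L, decoy = 0L, salt_records = 0L,
               stereo_records = 0L, charged_records = 0L,
               unit_converted = 0L)
  rid <- 0L
  next_id <- function(src) {
    rid <<- rid + 1L
    sprintf("%s%06d", if (src == "chembl") "CH" else "BDB", rid)
  }
  emit <- function(src, gen_id, smiles, kinase, type, relation, value,
                   units = "nM", comment = "", label = "",
                   confidence = "9", target = "SINGLE PROTEIN",
                   n_chains = "1") {
    id <- next_id(src)
    if (src == "chembl") {
      chembl[[length(chembl) + 1]] <<- data.frame(
        activity_id = id, canonical_smiles = smiles, accession = kinase,
        standard_type = type, standard_relation = relation,
        standard_value = value, standard_units = units,
        target_type = target, confidence_score = confidence,
        activity_comment = comment, activity_label = label,
        stringsAsFactors = FALSE)
    } else {
      bindingdb[[length(bindingdb) + 1]] <<- data.frame(
        reactant_set_id = id, ligand_smiles = smiles, uniprot_id = kinase,
        measurement_type = type, relation = relation, value_nM = value,
        n_protein_chains = n_chains, stringsAsFactors = FALSE)
    }
    record_map[[length(record_map) + 1]] <<- data.frame(
      record_id = id, gen_id = gen_id, stringsAsFactors = FALSE)
    id
  }

  categories <- c("active", "inactive", "qualitative", "conflict",
                  "sd_violation")
  probs <- c(1 - spec$frac_inactive - spec$frac_qualitative -
               spec$frac_conflict - spec$frac_sd_violation,
             spec$frac_inactive, spec$frac_qualitative, spec$frac_conflict,
             spec$frac_sd_violation)

  for (ci in seq_len(nrow(compounds))) {
    co <- compounds[ci, ]
    has_stereo <- grepl("@", co$smiles, fixed = TRUE)
    has_ionizable <- any(nzchar(lib$charged_from) &
                           vapply(lib$charged_from, function(p)
                             nzchar(p) && grepl(p, co$smiles, fixed = TRUE),
                             logical(1)))
    n_k <- sample(1:3, 1)
    kin_idx <- sample(nrow(kin), n_k)
    for (ki in kin_idx) {
      category <- sample(categories, 1, prob = probs)
      src_of <- function() if (stats::runif(1) < spec$dialect_split)
        "chembl" else "bindingdb"
      deco <- function() {
        flip <- has_stereo && stats::runif(1) < 0.5
        chg <- has_ionizable && stats::runif(1) < spec$charged_rate
        salt <- stats::runif(1) < spec$salt_rate
        if (flip) planted["stereo_records"] <<- planted["stereo_records"] + 1L
        if (chg) planted["charged_records"] <<- planted["charged_records"] + 1L
        if (salt) planted["salt_records"] <<- planted["salt_records"] + 1L
        decorate_smiles(co$smiles, lib, flip, chg, salt)
      }
      emit_eq <- function(type, log_value, src) {
        v_nM <- 10^(9 - log_value)
        if (src == "chembl" && stats::runif(1) < spec$unit_um_rate) {
          vs <- as.character(v_nM / 1000)
          planted["unit_converted"] <<- planted["unit_converted"] + 1L
          id <- emit(src, co$gen_id, deco(), kin$uniprot_id[ki], type, "=",
                     vs, units = "uM")
          true_v <- as.numeric(vs) * 1000
        } else {
          vs <- as.character(v_nM)
          id <- emit(src, co$gen_id, deco(), kin$uniprot_id[ki], type, "=",
                     vs)
          true_v <- as.numeric(vs)
        }
        list(id = id, log = 9 - log10(true_v))
      }

      rec_ids <- character(0)
      type_logs <- list()
      status <- NULL; sel_type <- NA_character_; mean_log <- NA_real_
      if (category %in% c("active", "inactive", "conflict")) {
        true_log <- if (category == "inactive") stats::runif(1, 3.6, 4.8)
                    else min(max(stats::rnorm(1, spec$mean_log_center,
                                              spec$mean_log_sd), 5.3), 9.5)
        types <- sample(c("IC50", "Ki", "Kd"),
                        size = sample(1:2, 1, prob = c(0.7, 0.3)),
                        prob = c(0.6, 0.25, 0.15))
        for (tp in types) {
          n_meas <- sample(1:2, 1)
          for (r in seq_len(n_meas)) {
            res <- emit_eq(tp, true_log + stats::rnorm(1, 0, spec$noise_sd),
                           src_of())
            rec_ids <- c(rec_ids, res$id)
            type_logs[[toupper(tp)]] <- c(type_logs[[toupper(tp)]], res$log)
          }
        }
        means <- vapply(type_logs, mean, numeric(1))
        prio <- c(KD = 1, KI = 2, IC50 = 3)
        sel_type <- names(means)[order(prio[names(means)])][1]
        mean_log <- unname(means[sel_type])
        status <- if (mean_log >= 5) "ACTIVE" else "INACTIVE"
        if (category == "conflict") {
          id <- emit(src_of(), co$gen_id, deco(), kin$uniprot_id[ki],
                     sample(c("IC50", "Ki", "Kd"), 1), ">", "10000")
          rec_ids <- c(rec_ids, id)
          if (status == "ACTIVE") {
            status <- "DISCARDED_CONFLICT"
            planted["conflict"] <- planted["conflict"] + 1L
          }
        } else if (category == "inactive") {
          planted["inactive"] <- planted["inactive"] + 1L
        }
      } else if (category == "qualitative") {
        for (r in seq_len(sample(1:2, 1))) {
          id <- emit(src_of(), co$gen_id, deco(), kin$uniprot_id[ki],
                     sample(c("IC50", "Ki", "Kd"), 1),
                     sample(c(">", ">>"), 1, prob = c(0.8, 0.2)),
                     as.character(sample(c(10000, 20000, 50000), 1)))
          rec_ids <- c(rec_ids, id)
        }
        sel_type <- "QUALITATIVE"
        status <- "INACTIVE"
        planted["qualitative"] <- planted["qualitative"] + 1L
      } else { # sd_violation: one type, two far-apart values
        tp <- sample(c("IC50", "Ki", "Kd"), 1)
        center <- stats::rnorm(1, spec$mean_log_center, spec$mean_log_sd)
        for (d in c(-1.2, 1.2)) {
          res <- emit_eq(tp, center + d, src_of())
          rec_ids <- c(rec_ids, res$id)
        }
        sel_type <- NA_character_
        status <- "DISCARDED_SD"
        planted["sd_violation"] <- planted["sd_violation"] + 1L
      }

      if (stats::runif(1) < spec$decoy_rate) {
        kind <- sample(c("type", "confidence", "comment", "label",
                         "multichain"), 1)
        v <- as.character(round(stats::runif(1, 10, 5000), 2))
        switch(kind,
          type = emit("chembl", co$gen_id, deco(), kin$uniprot_id[ki],
                      "EC50", "=", v),
          confidence = emit("chembl", co$gen_id, deco(), kin$uniprot_id[ki],
                            "IC50", "=", v, confidence = "8"),
          comment = emit("chembl", co$gen_id, deco(), kin$uniprot_id[ki],
                         "IC50", "=", v,
                         comment = "Outside typical range"),
          label = emit("chembl", co$gen_id, deco(), kin$uniprot_id[ki],
                       "IC50", "=", "50000", label = "Active"),
          multichain = emit("bindingdb", co$gen_id, deco(),
                            kin$uniprot_id[ki], "IC50", "=", v,
                            n_chains = "2"))
        planted["decoy"] <- planted["decoy"] + 1L
      }

      pairs[[length(pairs) + 1]] <- data.frame(
        gen_id = co$gen_id, kinase_uniprot = kin$uniprot_id[ki],
        organism = ifelse(grepl("^Homo", kin$organism[ki]), "HUMAN", "MOUSE"),
        status = status, selected_type = sel_type, mean_log = mean_log,
        record_ids = paste(sort(rec_ids, method = "radix"), collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  list(
    chembl = do.call(rbind, c(chembl, make.row.names = FALSE)),
    bindingdb = do.call(rbind, c(bindingdb, make.row.names = FALSE)),
    pairs = do.call(rbind, c(pairs, make.row.names = FALSE)),
    record_map = do.call(rbind, c(record_map, make.row.names = FALSE)),
    planted = planted
  )
}
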