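# Independent reference implementations used as oracles. They share only the
# low-level SMILES/molblock conversion helpers with the package; enumeration,
# selection, aggregation and assignment logic are re-implemented from the
# rules themselves.

# --- aggregation oracle -------------------------------------------------------

# Rule-by-rule reimplementation of per-pair aggregation: explicit loops, fixed
# Kd > Ki > IC50 scan order, no grouping machinery.
oracle_aggregate_pair <- function(m, threshold_log = 5) {
  eq <- m[m$relation == "EQ", , drop = FALSE]
  cens <- m[m$relation %in% c("GT", "GTGT"), , drop = FALSE]
  if (nrow(eq) == 0) {
    return(list(selected_type = "QUALITATIVE", mean_log = NA_real_,
                status = "INACTIVE"))
  }
  means <- c()
  for (tp in c("KD", "KI", "IC50")) {
    v <- eq$value_nM[eq$measurement_type == tp]
    if (length(v) == 0) next
    lg <- 9 - log10(v)
    if (length(lg) >= 2 && stats::sd(lg) > 1) next
    means[tp] <- mean(lg)
  }
  if (length(means) == 0) {
    return(list(selected_type = "QUALITATIVE", mean_log = NA_real_,
                status = "DISCARDED_SD"))
  }
  tp <- names(means)[1] # first valid in Kd, Ki, IC50 order
  ml <- unname(means[tp])
  status <- if (ml >= threshold_log) "ACTIVE" else "INACTIVE"
  if (status == "ACTIVE" && nrow(cens) > 0) status <- "DISCARDED_CONFLICT"
  list(selected_type = tp, mean_log = ml, status = status)
}

# Random qualified measurement set for one pair: <= 6 measurements, mixed
# types and relations, values straddling the 10,000 nM threshold. Censored
# records carry values >= 10,000 nM, as record qualification guarantees.
random_pair_measurements <- function() {
  n <- sample(1:6, 1)
  rel <- sample(c("EQ", "GT", "GTGT"), n, replace = TRUE,
                prob = c(0.7, 0.2, 0.1))
  type <- sample(c("IC50", "KI", "KD"), n, replace = TRUE)
  value <- ifelse(rel == "EQ", 10^stats::runif(n, 1, 6),
                  sample(c(1e4, 2e4, 1e5), n, replace = TRUE))
  data.frame(
    record_id = sprintf("R%03d", seq_len(n)),
    compound_new_id = 1L, compound_key = "C", kinase_uniprot = "P00001",
    organism = "HUMAN", pref_name = "k",
    measurement_type = type, relation = rel, value_nM = value,
    stringsAsFactors = FALSE
  )
}

# --- analogue-series oracle ---------------------------------------------------

.oracle_mass <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
                  F = 18.998, Cl = 35.45, Br = 79.904, I = 126.904, B = 10.81,
                  H = 1.008, `*` = 0)

# Exhaustive candidate-core enumeration: every subset of cuttable bonds up to
# max_cuts by bitmask, connected components by hand-rolled BFS, same size
# constraints, labelled-core identity as the lexicographic minimum over label
# permutations.
oracle_candidate_cores <- function(smiles, max_cuts = 2, min_core_ratio = 2,
                                   max_sub_heavy = 13,
                                   rules = default_retro_rules()) {
  can <- canonical_smiles(smiles)
  mol <- kinicurate:::smiles_to_mol(can)
  nat <- nrow(mol$atoms)
  heavy <- !mol$atoms$symbol %in% c("H", "*")
  mass <- .oracle_mass[mol$atoms$symbol]
  mass[is.na(mass)] <- 50
  adj <- vector("list", nat)
  for (r in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a1[r]; b <- mol$bonds$a2[r]
    adj[[a]] <- c(adj[[a]], r); adj[[b]] <- c(adj[[b]], r)
  }
  other_end <- function(r, at) {
    if (mol$bonds$a1[r] == at) mol$bonds$a2[r] else mol$bonds$a1[r]
  }
  bfs_components <- function(cut_rows) {
    comp <- integer(nat); cur <- 0L
    for (s in seq_len(nat)) {
      if (comp[s] != 0L) next
      cur <- cur + 1L
      queue <- s; comp[s] <- cur
      while (length(queue)) {
        at <- queue[1]; queue <- queue[-1]
        for (r in adj[[at]]) {
          if (r %in% cut_rows) next
          nb <- other_end(r, at)
          if (comp[nb] == 0L) { comp[nb] <- cur; queue <- c(queue, nb) }
        }
      }
    }
    comp
  }
  cb <- kinicurate:::cuttable_bonds(mol, rules)
  out <- data.frame(core = can, heavy = sum(heavy), stringsAsFactors = FALSE)
  if (length(cb) == 0) return(out)
  perms <- list(`1` = list(1L), `2` = list(c(1L, 2L), c(2L, 1L)),
                `3` = lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1),
                                  c(3,1,2), c(3,2,1)), as.integer))
  for (mask in seq_len(2^length(cb) - 1)) {
    bits <- which(bitwAnd(mask, 2^(seq_along(cb) - 1)) > 0)
    if (length(bits) > max_cuts) next
    cuts <- cb[bits]
    comp <- bfs_components(cuts)
    ch <- tapply(heavy, comp, sum)
    cm <- tapply(mass * heavy, comp, sum)
    cfirst <- tapply(seq_len(nat), comp, min)
    ord <- order(-ch, -cm, cfirst)
    core_id <- as.integer(names(ch)[ord[1]])
    e1 <- mol$bonds$a1[cuts]; e2 <- mol$bonds$a2[cuts]
    in1 <- comp[e1] == core_id; in2 <- comp[e2] == core_id
    if (!all(xor(in1, in2))) next
    core_side <- ifelse(in1, e1, e2)
    sub_side <- ifelse(in1, e2, e1)
    if (anyDuplicated(comp[sub_side]) > 0) next
    sub_h <- ch[as.character(comp[sub_side])]
    if (any(sub_h > max_sub_heavy)) next
    core_h <- ch[[as.character(core_id)]]
    if (core_h < min_core_ratio * sum(sub_h)) next
    blocks <- vapply(perms[[as.character(length(cuts))]], function(p) {
      kinicurate:::fragment_molblock(mol, which(comp == core_id), core_side,
                                     labels = p)
    }, character(1))
    smis <- kinicurate:::molblocks_to_smiles(kinicurate:::titled_blocks(blocks))
    if (anyNA(smis)) next
    key <- sort(smis, method = "radix")[1]
    if (!key %in% out$core) {
      out <- rbind(out, data.frame(core = key, heavy = as.integer(core_h),
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

# Independent greedy assignment over precomputed candidate-core sets:
# repeatedly take the core covering the most remaining compounds (ties by
# core heavy atoms, then core SMILES), stop when no core covers two.
oracle_assign <- function(cand_map) {
  remaining <- names(cand_map)
  series <- list()
  repeat {
    tally <- list()
    for (cp in remaining) {
      cc <- cand_map[[cp]]
      for (r in seq_len(nrow(cc))) {
        k <- cc$core[r]
        if (is.null(tally[[k]])) {
          tally[[k]] <- list(n = 0L, heavy = cc$heavy[r], members = character(0))
        }
        tally[[k]]$n <- tally[[k]]$n + 1L
        tally[[k]]$members <- c(tally[[k]]$members, cp)
      }
    }
    ns <- vapply(tally, `[[`, integer(1), "n")
    if (length(ns) == 0 || max(ns) < 2) break
    best <- names(tally)[ns == max(ns)]
    hv <- vapply(tally[best], function(x) as.numeric(x$heavy), numeric(1))
    best <- best[order(-hv, best, method = "radix")][1]
    mem <- sort(tally[[best]]$members, method = "radix")
    series[[best]] <- mem
    remaining <- setdiff(remaining, mem)
  }
  list(series = series, singletons = sort(remaining, method = "radix"))
}
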