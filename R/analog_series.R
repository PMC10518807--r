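# Analogue-series extraction via systematic retrosynthetic fragmentation and
# compound-core relationships.
#
# A candidate core of a compound is the largest fragment left after cutting
# 1..k acyclic single bonds whose environment matches a retrosynthetic rule;
# the removed fragments are the substituents. Attachment points are kept as
# isotope-labelled dummy atoms ([1*], [2*], ...) so that a core plus its
# R-groups reconstructs the member exactly. Compounds sharing a core form an
# analogue series; site numbering is canonicalized by taking, over all
# permutations of attachment labels, the lexicographically smallest canonical
# SMILES of the labelled core.

#' Names of the retrosynthetic bond rules
#'
#' The rule set is configuration: any subset can be passed to
#' [fragment_compound()] / [assign_series()]. A bond is cuttable when it is an
#' acyclic (non-ring) single bond between heavy atoms whose environment
#' matches at least one enabled rule:
#' \describe{
#'   \item{amide}{carbonyl carbon - nitrogen}
#'   \item{ester}{carbonyl carbon - bridging oxygen}
#'   \item{amine}{non-carbonyl carbon - nitrogen}
#'   \item{ether}{non-carbonyl carbon - bridging oxygen}
#'   \item{sulfonamide}{sulfonyl sulfur - nitrogen}
#'   \item{ring_ring}{bond joining two ring systems}
#'   \item{ring_attachment}{bond from a ring atom to an acyclic heavy atom}
#' }
#' @return character vector of rule names.
#' @export
default_retro_rules <- function() {
  c("amide", "ester", "amine", "ether", "sulfonamide",
    "ring_ring", "ring_attachment")
}

# Annotate a parsed molecule with ring membership and carbonyl flags, and
# list the indices of bonds cuttable under the enabled rules.
cuttable_bonds <- function(mol, rules = default_retro_rules()) {
  b <- mol$bonds
  if (nrow(b) == 0) return(integer(0))
  g <- igraph::graph_from_edgelist(cbind(b$a1, b$a2), directed = FALSE)
  if (igraph::vcount(g) < nrow(mol$atoms)) {
    g <- igraph::add_vertices(g, nrow(mol$atoms) - igraph::vcount(g))
  }
  bridge <- rep(FALSE, nrow(b))
  bridge[as.integer(igraph::bridges(g))] <- TRUE
  ring_bond <- !bridge
  sym <- mol$atoms$symbol
  ring_atom <- rep(FALSE, length(sym))
  if (any(ring_bond)) {
    ring_atom[unique(c(b$a1[ring_bond], b$a2[ring_bond]))] <- TRUE
  }
  # carbonyl carbon: C with a double bond to O; sulfonyl: S with >= 2 S=O
  dbl_o <- function(i, want) {
    nb <- c(b$a2[b$a1 == i & b$order == 2], b$a1[b$a2 == i & b$order == 2])
    sum(sym[nb] == "O") >= want
  }
  carbonyl <- vapply(seq_along(sym),
                     function(i) sym[i] == "C" && dbl_o(i, 1), logical(1))
  sulfonyl <- vapply(seq_along(sym),
                     function(i) sym[i] == "S" && dbl_o(i, 2), logical(1))
  deg <- tabulate(c(b$a1, b$a2), nbins = length(sym))
  hit <- logical(nrow(b))
  for (k in seq_len(nrow(b))) {
    if (!bridge[k] || b$order[k] != 1) next
    i <- b$a1[k]; j <- b$a2[k]
    if (sym[i] %in% c("H", "*") || sym[j] %in% c("H", "*")) next
    pairs <- list(c(i, j), c(j, i))
    for (p in pairs) {
      a <- p[1]; z <- p[2]
      if ("amide" %in% rules && carbonyl[a] && sym[z] == "N") hit[k] <- TRUE
      if ("ester" %in% rules && carbonyl[a] && sym[z] == "O" && deg[z] >= 2)
        hit[k] <- TRUE
      if ("amine" %in% rules && sym[a] == "C" && !carbonyl[a] && sym[z] == "N")
        hit[k] <- TRUE
      if ("ether" %in% rules && sym[a] == "C" && !carbonyl[a] &&
          sym[z] == "O" && deg[z] >= 2) hit[k] <- TRUE
      if ("sulfonamide" %in% rules && sulfonyl[a] && sym[z] == "N")
        hit[k] <- TRUE
    }
    if ("ring_ring" %in% rules && ring_atom[i] && ring_atom[j]) hit[k] <- TRUE
    if ("ring_attachment" %in% rules && xor(ring_atom[i], ring_atom[j]))
      hit[k] <- TRUE
  }
  which(hit)
}

all_permutations <- function(n) {
  if (n <= 1) return(list(seq_len(n)))
  out <- list()
  for (i in seq_len(n)) {
    for (p in all_permutations(n - 1)) {
      out[[length(out) + 1]] <- c(i, ifelse(p >= i, p + 1, p))
    }
  }
  out
}

#' Enumerate candidate cores of one compound
#'
#' Systematically cuts 1..`max_cuts` retrosynthetically cuttable bonds; for
#' each cut set the largest remaining fragment is the candidate core and the
#' detached fragments are substituents. Cut sets where a substituent is not
#' directly bonded to the core, where a substituent exceeds
#' `max_sub_heavy` heavy atoms, or where the core has fewer than
#' `min_core_ratio` times the combined heavy atoms of the substituents are
#' pruned. The uncut molecule is always a candidate with zero sites.
#'
#' @param smiles standardized compound SMILES (the merge key).
#' @param max_cuts maximum number of simultaneous bond cuts.
#' @param min_core_ratio minimum ratio of core heavy atoms to total
#'   substituent heavy atoms.
#' @param max_sub_heavy maximum heavy atoms per substituent.
#' @param rules enabled retrosynthetic rules, see [default_retro_rules()].
#' @return list with `compound` (canonical input) and `candidates`, a list of
#'   entries `core_smiles` (labelled, canonical), `n_sites`, `core_heavy`, and
#'   `subs` (data.frame `site`, `sub_smiles`, `sub_heavy`).
#' @export
fragment_compound <- function(smiles, max_cuts = 2, min_core_ratio = 2,
                              max_sub_heavy = 13,
                              rules = default_retro_rules()) {
  can <- canonical_smiles(smiles)
  stopifnot(!is.na(can))
  mol <- smiles_to_mol(can)
  total_heavy <- heavy_atom_count(mol)
  trivial <- list(core_smiles = can, n_sites = 0L, core_heavy = total_heavy,
                  subs = data.frame(site = integer(0),
                                    sub_smiles = character(0),
                                    sub_heavy = integer(0)))
  cb <- cuttable_bonds(mol, rules)
  if (length(cb) == 0) {
    return(list(compound = can, candidates = list(trivial)))
  }
  sym <- mol$atoms$symbol
  heavy_atom <- !sym %in% c("H", "*")
  mass <- .atomic_mass[sym]
  mass[is.na(mass)] <- 50
  g <- igraph::graph_from_edgelist(cbind(mol$bonds$a1, mol$bonds$a2),
                                   directed = FALSE)
  if (igraph::vcount(g) < nrow(mol$atoms)) {
    g <- igraph::add_vertices(g, nrow(mol$atoms) - igraph::vcount(g))
  }

  raw <- list() # per accepted cut set: core atom set, per-cut info
  for (nc in seq_len(min(max_cuts, length(cb)))) {
    sets <- utils::combn(cb, nc, simplify = FALSE)
    for (cs in sets) {
      comp <- igraph::components(igraph::delete_edges(g, cs))$membership
      comp_heavy <- tapply(heavy_atom, comp, sum)
      comp_mass <- tapply(mass * heavy_atom, comp, sum)
      comp_min <- tapply(seq_along(comp), comp, min)
      ord <- order(-comp_heavy, -comp_mass, comp_min)
      core_id <- as.integer(names(comp_heavy)[ord[1]])
      ends1 <- mol$bonds$a1[cs]; ends2 <- mol$bonds$a2[cs]
      in_core1 <- comp[ends1] == core_id
      in_core2 <- comp[ends2] == core_id
      if (!all(xor(in_core1, in_core2))) next
      core_side <- ifelse(in_core1, ends1, ends2)
      sub_side <- ifelse(in_core1, ends2, ends1)
      sub_comp <- comp[sub_side]
      if (anyDuplicated(sub_comp) > 0) next # two cuts into one substituent
      sub_heavy <- comp_heavy[as.character(sub_comp)]
      if (any(sub_heavy > max_sub_heavy)) next
      core_heavy <- comp_heavy[[as.character(core_id)]]
      if (core_heavy < min_core_ratio * sum(sub_heavy)) next
      raw[[length(raw) + 1]] <- list(
        core_atoms = which(comp == core_id), core_side = core_side,
        sub_side = sub_side,
        sub_atoms = lapply(sub_comp, function(sc) which(comp == sc)),
        core_heavy = as.integer(core_heavy),
        sub_heavy = as.integer(sub_heavy)
      )
    }
  }
  if (length(raw) == 0) {
    return(list(compound = can, candidates = list(trivial)))
  }

  # Batch 1: labelled core SMILES for every permutation of site labels; the
  # lexicographically smallest string is the canonical core identity.
  blocks <- character(0)
  index <- list()
  perms_of <- lapply(seq_len(max_cuts), all_permutations)
  for (ci in seq_along(raw)) {
    r <- raw[[ci]]
    n <- length(r$core_side)
    for (pi in seq_along(perms_of[[n]])) {
      perm <- perms_of[[n]][[pi]]
      blocks <- c(blocks, fragment_molblock(mol, r$core_atoms, r$core_side,
                                            labels = perm))
      index[[length(index) + 1]] <- c(ci, pi)
    }
  }
  core_smi <- molblocks_to_smiles(titled_blocks(blocks))
  choice <- integer(length(raw))
  core_key <- character(length(raw))
  for (ci in seq_along(raw)) {
    at <- which(vapply(index, function(x) x[1] == ci, logical(1)))
    smi <- core_smi[at]
    if (anyNA(smi)) { core_key[ci] <- NA_character_; next }
    ord <- order(smi, method = "radix")
    core_key[ci] <- smi[ord[1]]
    choice[ci] <- index[[at[ord[1]]]][2]
  }

  # Batch 2: substituents labelled with their final site numbers.
  sblocks <- character(0)
  sindex <- list()
  for (ci in seq_along(raw)) {
    if (is.na(core_key[ci])) next
    r <- raw[[ci]]
    n <- length(r$core_side)
    perm <- perms_of[[n]][[choice[ci]]]
    for (j in seq_len(n)) {
      sblocks <- c(sblocks,
                   fragment_molblock(mol, r$sub_atoms[[j]], r$sub_side[j],
                                     labels = perm[j]))
      sindex[[length(sindex) + 1]] <- c(ci, j, perm[j])
    }
  }
  sub_smi <- molblocks_to_smiles(titled_blocks(sblocks))

  cands <- list(trivial)
  seen <- trivial$core_smiles
  for (ci in seq_along(raw)) {
    if (is.na(core_key[ci]) || core_key[ci] %in% seen) next
    r <- raw[[ci]]
    n <- length(r$core_side)
    perm <- perms_of[[n]][[choice[ci]]]
    at <- which(vapply(sindex, function(x) x[1] == ci, logical(1)))
    smi <- sub_smi[at]
    if (anyNA(smi)) next
    sites <- vapply(sindex[at], function(x) x[3], numeric(1))
    ords <- order(sites)
    subs <- data.frame(site = as.integer(sites[ords]),
                       sub_smiles = smi[ords],
                       sub_heavy = r$sub_heavy[ords],
                       stringsAsFactors = FALSE)
    seen <- c(seen, core_key[ci])
    cands[[length(cands) + 1]] <- list(core_smiles = core_key[ci],
                                       n_sites = n,
                                       core_heavy = r$core_heavy,
                                       subs = subs)
  }
  list(compound = can, candidates = cands)
}

# Molblock of the induced fragment on `atoms`, with one isotope-labelled dummy
# atom per attachment atom in `attach` (labels aligned with `attach`).
fragment_molblock <- function(mol, atoms, attach, labels) {
  keep <- sort(atoms)
  remap <- integer(nrow(mol$atoms))
  remap[keep] <- seq_along(keep)
  b <- mol$bonds
  inb <- b$a1 %in% keep & b$a2 %in% keep
  bonds <- data.frame(a1 = remap[b$a1[inb]], a2 = remap[b$a2[inb]],
                      order = b$order[inb])
  at <- mol$atoms[keep, , drop = FALSE]
  for (j in seq_along(attach)) {
    at <- rbind(at, data.frame(symbol = "*", charge = 0L,
                               iso = as.integer(labels[j])))
    bonds <- rbind(bonds, data.frame(a1 = remap[attach[j]],
                                     a2 = nrow(at), order = 1L))
  }
  write_molblock(at, bonds)
}

titled_blocks <- function(blocks) {
  if (length(blocks) == 0) return(character(0))
  vapply(seq_along(blocks), function(i) {
    sub("^[^\n]*", as.character(i), blocks[i])
  }, character(1))
}

#' Assign compounds to analogue series and singletons
#'
#' Builds the full compound-to-candidate-core map over the input set and
#' greedily partitions it: repeatedly select the core shared by the most
#' remaining compounds (ties broken by larger core heavy-atom count, then
#' lexicographically smaller core SMILES), form a series from all remaining
#' compounds carrying it, and remove them. Compounds left when no core covers
#' at least two of them become singletons, each keeping its own uncut
#' structure as core. The result is a disjoint partition: every compound is in
#' exactly one series or is one singleton, and the number of distinct cores
#' equals the number of series plus the number of singletons.
#'
#' @param compounds character vector of unique standardized SMILES keys.
#' @param max_cuts,min_core_ratio,max_sub_heavy,rules forwarded to
#'   [fragment_compound()].
#' @param candidates optional precomputed list of [fragment_compound()]
#'   results named by compound key (useful for caching).
#' @return list with data.frames `series` (`series_id`, `core_smiles`,
#'   `n_sites`, `core_heavy`, `n_members`), `members` (`series_id`,
#'   `compound_key`), `rgroups` (`series_id`, `compound_key`, `site`,
#'   `sub_smiles`), and `singletons` (`singleton_id`, `compound_key`,
#'   `core_smiles`).
#' @export
assign_series <- function(compounds, max_cuts = 2, min_core_ratio = 2,
                          max_sub_heavy = 13, rules = default_retro_rules(),
                          candidates = NULL) {
  compounds <- as.character(compounds)
  stopifnot(!anyDuplicated(compounds))
  if (is.null(candidates)) {
    candidates <- lapply(compounds, fragment_compound, max_cuts = max_cuts,
                         min_core_ratio = min_core_ratio,
                         max_sub_heavy = max_sub_heavy, rules = rules)
    names(candidates) <- compounds
  }
  rows <- do.call(rbind, lapply(compounds, function(cp) {
    cc <- candidates[[cp]]$candidates
    data.frame(compound = cp,
               core = vapply(cc, `[[`, character(1), "core_smiles"),
               n_sites = vapply(cc, `[[`, integer(1), "n_sites"),
               core_heavy = vapply(cc, function(x) as.integer(x$core_heavy),
                                   integer(1)),
               cand_idx = seq_along(cc),
               stringsAsFactors = FALSE)
  }))

  remaining <- compounds
  series <- list(); members <- list(); rgroups <- list()
  repeat {
    live <- rows[rows$compound %in% remaining, , drop = FALSE]
    if (nrow(live) == 0) break
    cnt <- table(live$core)
    mx <- max(cnt)
    if (mx < 2) break
    top <- names(cnt)[cnt == mx]
    meta <- live[match(top, live$core), c("core", "n_sites", "core_heavy")]
    ord <- order(-meta$core_heavy, meta$core, method = "radix")
    core <- meta$core[ord[1]]
    sel <- live[live$core == core, , drop = FALSE]
    sel <- sel[order(sel$compound, method = "radix"), , drop = FALSE]
    sid <- sprintf("AS%04d", length(series) + 1)
    series[[sid]] <- data.frame(series_id = sid, core_smiles = core,
                                n_sites = sel$n_sites[1],
                                core_heavy = sel$core_heavy[1],
                                n_members = nrow(sel),
                                stringsAsFactors = FALSE)
    members[[sid]] <- data.frame(series_id = sid,
                                 compound_key = sel$compound,
                                 stringsAsFactors = FALSE)
    rg <- do.call(rbind, lapply(seq_len(nrow(sel)), function(r) {
      cand <- candidates[[sel$compound[r]]]$candidates[[sel$cand_idx[r]]]
      if (nrow(cand$subs) == 0) return(NULL)
      data.frame(series_id = sid, compound_key = sel$compound[r],
                 site = cand$subs$site, sub_smiles = cand$subs$sub_smiles,
                 stringsAsFactors = FALSE)
    }))
    rgroups[[sid]] <- rg
    remaining <- setdiff(remaining, sel$compound)
  }
  remaining <- sort(remaining, method = "radix")
  singles <- data.frame(
    singleton_id = if (length(remaining)) sprintf("S%04d",
                                                  seq_along(remaining))
                   else character(0),
    compound_key = remaining,
    core_smiles = remaining, # the maximal (uncut) structure
    stringsAsFactors = FALSE
  )
  list(
    series = if (length(series)) do.call(rbind, unname(series))
             else data.frame(series_id = character(0),
                             core_smiles = character(0),
                             n_sites = integer(0), core_heavy = integer(0),
                             n_members = integer(0)),
    members = if (length(members)) do.call(rbind, unname(members))
              else data.frame(series_id = character(0),
                              compound_key = character(0)),
    rgroups = if (length(rgroups)) do.call(rbind, c(unname(rgroups),
                                                    make.row.names = FALSE))
              else data.frame(series_id = character(0),
                              compound_key = character(0),
                              site = integer(0), sub_smiles = character(0)),
    singletons = singles
  )
}

#' Reattach R-groups to a labelled core
#'
#' Joins a core carrying isotope-labelled attachment dummies (`[1*]`, `[2*]`,
#' ...) with substituent fragments carrying matching labels, forming a single
#' bond between the dummy neighbours and removing the dummies. Used to verify
#' the reassembly invariant: every series member is reconstructed exactly from
#' its core and R-groups.
#'
#' @param core_smiles labelled core SMILES.
#' @param sub_smiles character vector of labelled substituent SMILES.
#' @return canonical SMILES of the reassembled molecule.
#' @export
join_fragments <- function(core_smiles, sub_smiles) {
  mols <- lapply(c(core_smiles, sub_smiles), smiles_to_mol)
  stopifnot(!any(vapply(mols, is.null, logical(1))))
  atoms <- do.call(rbind, lapply(mols, `[[`, "atoms"))
  off <- cumsum(c(0, utils::head(vapply(mols, function(m) nrow(m$atoms),
                                        integer(1)), -1)))
  bonds <- do.call(rbind, lapply(seq_along(mols), function(i) {
    b <- mols[[i]]$bonds
    if (nrow(b) == 0) return(b)
    b$a1 <- b$a1 + off[i]; b$a2 <- b$a2 + off[i]
    b
  }))
  is_dummy <- atoms$symbol == "*"
  core_n <- nrow(mols[[1]]$atoms)
  labels <- sort(unique(atoms$iso[is_dummy & seq_len(nrow(atoms)) <= core_n]))
  neighbor_of <- function(d) {
    nb <- c(bonds$a2[bonds$a1 == d], bonds$a1[bonds$a2 == d])
    stopifnot(length(nb) == 1)
    nb
  }
  drop <- integer(0)
  for (lab in labels) {
    cd <- which(is_dummy & atoms$iso == lab & seq_len(nrow(atoms)) <= core_n)
    sd <- which(is_dummy & atoms$iso == lab & seq_len(nrow(atoms)) > core_n)
    stopifnot(length(cd) == 1, length(sd) <= 1)
    if (length(sd) == 1) {
      bonds <- rbind(bonds, data.frame(a1 = neighbor_of(cd),
                                       a2 = neighbor_of(sd), order = 1L))
      drop <- c(drop, cd, sd)
    } else {
      drop <- c(drop, cd) # no substituent for this site: hydrogen fills in
    }
  }
  keep <- setdiff(seq_len(nrow(atoms)), drop)
  remap <- integer(nrow(atoms)); remap[keep] <- seq_along(keep)
  bonds <- bonds[!(bonds$a1 %in% drop | bonds$a2 %in% drop), , drop = FALSE]
  bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2]
  at <- atoms[keep, , drop = FALSE]
  smi <- molblocks_to_smiles(titled_blocks(write_molblock(at, bonds)))
  stopifnot(!is.na(smi))
  smi
}
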