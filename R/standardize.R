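# SMILES standardization and cross-source compound merging.

#' Standardize SMILES strings to the non-stereo canonical merge key
#'
#' Applies the standardization protocol used throughout the pipeline, in fixed
#' order: parse, keep the largest organic fragment (salt/solvent stripping),
#' neutralize protonation states, strip stereochemistry, and emit canonical
#' aromatic SMILES. The resulting key is the compound identity under which
#' records from different sources are merged.
#'
#' Largest-fragment selection is by heavy-atom count among carbon-containing
#' components (all components if none contains carbon), with ties broken by
#' summed heavy-atom mass and then lexicographic canonical SMILES.
#' Neutralization covers standard +1/-1 protonation states (carboxylate,
#' ammonium, and the like); quaternary nitrogen and charge-separated groups
#' such as nitro are retained as drawn. Tautomers are not canonicalized.
#'
#' @param smiles character vector of SMILES strings as exported.
#' @return a data.frame with one row per input: `input`, `compound_key`
#'   (`NA` on failure), `ok` (logical), and `reason` (`""` or a discard
#'   reason code such as `"unparseable_smiles"`).
#' @examples
#' \dontrun{
#' standardize_smiles(c("CC(=O)O.[Na+]", "C[C@@H](N)C(=O)O"))
#' }
#' @export
standardize_smiles <- function(smiles) {
  key <- vapply(as.character(smiles), standardize_one, character(1),
                USE.NAMES = FALSE)
  data.frame(
    input = as.character(smiles),
    compound_key = key,
    ok = !is.na(key),
    reason = ifelse(is.na(key), "unparseable_smiles", ""),
    stringsAsFactors = FALSE
  )
}

standardize_one <- function(s) {
  if (is.na(s) || !nzchar(trimws(s))) return(NA_character_)
  can <- canonical_smiles(trimws(s))
  if (is.na(can)) return(NA_character_)
  frag <- largest_organic_fragment(can)
  if (is.na(frag)) return(NA_character_)
  neut <- neutralized_smiles(frag)
  if (is.na(neut)) return(NA_character_)
  flat <- canonical_smiles(strip_stereo_tokens(neut))
  if (is.na(flat)) return(NA_character_)
  flat
}

# Pick one connected component from a (canonical) SMILES that may encode a
# mixture. Components containing carbon take precedence over purely
# inorganic counter-ions regardless of size.
largest_organic_fragment <- function(can_smiles) {
  comps <- strsplit(can_smiles, ".", fixed = TRUE)[[1]]
  if (length(comps) == 1) return(can_smiles)
  info <- lapply(comps, smiles_to_mol)
  ok <- !vapply(info, is.null, logical(1))
  comps <- comps[ok]
  info <- info[ok]
  if (length(comps) == 0) return(NA_character_)
  has_c <- vapply(info, function(m) any(m$atoms$symbol == "C"), logical(1))
  if (any(has_c)) {
    comps <- comps[has_c]
    info <- info[has_c]
  }
  heavy <- vapply(info, heavy_atom_count, numeric(1))
  mass <- vapply(info, heavy_mass, numeric(1))
  ord <- order(-heavy, -mass, comps, method = "radix")
  comps[ord[1]]
}

#' Merge qualified records from both sources on the standardized compound key
#'
#' Records whose SMILES standardize to the same non-stereo canonical key are
#' unified under one internal compound ID. IDs are assigned in lexicographic
#' (C-locale) order of the key, so reruns on the same record set are
#' bit-identical.
#'
#' @param records a data.frame of qualified activity records carrying a
#'   `compound_smiles` column.
#' @return a list with `records` (input plus `compound_key` and
#'   `compound_new_id`, rows whose SMILES failed standardization removed),
#'   `compounds` (one row per unique key: `compound_new_id`, `compound_key`,
#'   `source_smiles` semicolon-joined), and `n_failed_standardization`.
#' @export
merge_compounds <- function(records) {
  std <- standardize_smiles(records$compound_smiles)
  keep <- std$ok
  rec <- records[keep, , drop = FALSE]
  rec$compound_key <- std$compound_key[keep]
  keys <- sort(unique(rec$compound_key), method = "radix")
  rec$compound_new_id <- match(rec$compound_key, keys)
  compounds <- data.frame(
    compound_new_id = seq_along(keys),
    compound_key = keys,
    stringsAsFactors = FALSE
  )
  compounds$source_smiles <- vapply(keys, function(k) {
    paste(sort(unique(rec$compound_smiles[rec$compound_key == k]),
               method = "radix"), collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  rownames(rec) <- NULL
  list(records = rec, compounds = compounds,
       n_failed_standardization = sum(!keep))
}
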