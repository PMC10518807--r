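# Low-level chemistry helpers built on Open Babel (via ChemmineOB).
# All molecule identity in the package is carried as canonical SMILES strings;
# graph surgery (fragmentation, reattachment) goes through V2000 molblocks.

# Open Babel writes parse diagnostics to stderr; they are harmless but noisy,
# so conversions run with messages captured.
ob_convert <- function(from, to, source, options = NULL) {
  suppressWarnings(suppressMessages(tryCatch({
    if (is.null(options)) ChemmineOB::convertFormat(from, to, source)
    else ChemmineOB::convertFormat(from, to, source, options = options)
  }, error = function(e) "")))
}

#' Canonical SMILES of one or more SMILES strings
#'
#' Round-trips each string through Open Babel's canonical SMILES writer.
#' Unparseable input yields `NA_character_` rather than an error, so callers
#' can log a discard reason.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical (aromatic) SMILES, `NA` where the
#'   input did not parse.
#' @export
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    out <- ob_convert("SMI", "CAN", paste0(s, "\n"))
    out <- sub("\t.*$", "", strsplit(out, "\n", fixed = TRUE)[[1]][1])
    out <- trimws(out)
    if (is.na(out) || !nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

# Canonical SMILES after Open Babel's charge neutralization pass (adds or
# removes protons on +1/-1 centers where possible; charge-separated groups
# such as nitro and quaternary nitrogen are left intact).
neutralized_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    out <- ob_convert("SMI", "CAN", paste0(s, "\n"),
                      options = data.frame(names = "neutralize", args = ""))
    out <- sub("\t.*$", "", strsplit(out, "\n", fixed = TRUE)[[1]][1])
    out <- trimws(out)
    if (is.na(out) || !nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

# InChI of a SMILES string; used as a toolkit-bridging identity in tests.
smiles_to_inchi <- function(smiles) {
  vapply(smiles, function(s) {
    out <- ob_convert("SMI", "INCHI", paste0(s, "\n"))
    out <- trimws(strsplit(out, "\n", fixed = TRUE)[[1]][1])
    if (is.na(out) || !nzchar(out)) NA_character_ else out
  }, character(1), USE.NAMES = FALSE)
}

# ---- molblock graph representation ------------------------------------------

# Parse a V2000 molblock (as written by Open Babel) into an atom/bond table.
# Only the fields the pipeline needs are retained: element symbol, formal
# charge and isotope label (M CHG / M ISO property lines), and the bond list
# with orders.
parse_molblock <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  atom_lines <- lines[5:(4 + na)]
  symbol <- trimws(substr(atom_lines, 32, 34))
  charge <- integer(na)
  iso <- integer(na)
  bonds <- if (nb > 0) {
    bl <- lines[(5 + na):(4 + na + nb)]
    data.frame(
      a1 = as.integer(substr(bl, 1, 3)),
      a2 = as.integer(substr(bl, 4, 6)),
      order = as.integer(substr(bl, 7, 9))
    )
  } else {
    data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  }
  prop <- grep("^M  (CHG|ISO)", lines, value = TRUE)
  for (p in prop) {
    kind <- substr(p, 4, 6)
    n <- as.integer(substr(p, 7, 9))
    for (k in seq_len(n)) {
      off <- 10 + (k - 1) * 8
      at <- as.integer(substr(p, off, off + 3))
      vl <- as.integer(substr(p, off + 4, off + 7))
      if (kind == "CHG") charge[at] <- vl else iso[at] <- vl
    }
  }
  list(
    atoms = data.frame(symbol = symbol, charge = charge, iso = iso,
                       stringsAsFactors = FALSE),
    bonds = bonds
  )
}

# Serialize an atom/bond table back to a V2000 molblock. Coordinates are
# zeroed: only connectivity matters for SMILES output.
write_molblock <- function(atoms, bonds, title = "") {
  na <- nrow(atoms)
  nb <- nrow(bonds)
  head <- c(title, " kinicurate", "",
            sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  atom_lines <- sprintf(
    "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    0, 0, 0, atoms$symbol)
  bond_lines <- if (nb > 0) {
    sprintf("%3d%3d%3d  0  0  0  0", bonds$a1, bonds$a2, bonds$order)
  } else character(0)
  prop_lines <- c(
    molblock_prop_lines("CHG", which(atoms$charge != 0), atoms$charge),
    molblock_prop_lines("ISO", which(atoms$iso != 0), atoms$iso)
  )
  paste(c(head, atom_lines, bond_lines, prop_lines, "M  END"),
        collapse = "\n")
}

molblock_prop_lines <- function(kind, idx, values) {
  if (length(idx) == 0) return(character(0))
  chunks <- split(idx, ceiling(seq_along(idx) / 8))
  vapply(chunks, function(ix) {
    paste0(sprintf("M  %s%3d", kind, length(ix)),
           paste0(sprintf("%4d%4d", ix, values[ix]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

smiles_to_mol <- function(smiles) {
  sdf <- ob_convert("SMI", "SDF", paste0(smiles, "\n"))
  if (!nzchar(trimws(sdf))) return(NULL)
  parse_molblock(sdf)
}

# Convert a set of molblocks to canonical SMILES in one Open Babel call.
# Blocks are titled with their index so output can be realigned even if an
# entry fails to convert.
molblocks_to_smiles <- function(blocks) {
  if (length(blocks) == 0) return(character(0))
  txt <- paste0(paste(blocks, collapse = "\n$$$$\n"), "\n$$$$\n")
  out <- ob_convert("SDF", "CAN", txt)
  res <- rep(NA_character_, length(blocks))
  if (!nzchar(trimws(out))) return(res)
  for (line in strsplit(out, "\n", fixed = TRUE)[[1]]) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) >= 2) {
      i <- suppressWarnings(as.integer(trimws(parts[2])))
      if (!is.na(i) && i >= 1 && i <= length(blocks)) res[i] <- trimws(parts[1])
    }
  }
  res
}

# Heavy atoms = anything but hydrogen and attachment-point dummies.
heavy_atom_count <- function(mol) {
  sum(!mol$atoms$symbol %in% c("H", "*"))
}

# Summed atomic mass of heavy atoms; used only to break largest-fragment ties.
.atomic_mass <- c(
  C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
  F = 18.998, Cl = 35.45, Br = 79.904, I = 126.904, B = 10.81,
  Si = 28.085, Se = 78.971, H = 1.008, `*` = 0
)

heavy_mass <- function(mol) {
  m <- .atomic_mass[mol$atoms$symbol]
  m[is.na(m)] <- 50 # unusual elements: fixed nominal mass keeps order total
  sum(m[!mol$atoms$symbol %in% c("H", "*")])
}

# Remove stereochemistry tokens from a SMILES string (tetrahedral @ marks and
# cis/trans bond slashes). The result is re-canonicalized by the caller.
strip_stereo_tokens <- function(smiles) {
  gsub("[@/\\\\]", "", smiles)
}
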