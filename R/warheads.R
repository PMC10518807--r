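# Covalent-warhead annotation by SMARTS substructure search.

#' Load a warhead pattern registry
#'
#' The registry is data, not code: a TSV with columns `name`, `smarts`,
#' `residues` (semicolon-separated amino-acid codes the reactive group can
#' target). The shipped default covers 14 conventional warhead classes,
#' including acrylamide (Cys/Lys/Ser/Thr) and heterocyclic urea (Ser/Thr).
#' Every SMARTS is compiled against a probe molecule at load time; an invalid
#' pattern or a duplicated name is a fatal error naming the entry.
#'
#' @param path registry file; `NULL` loads the shipped default.
#' @return data.frame with columns `name`, `smarts`, `residues`.
#' @export
load_warhead_registry <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "warheads.tsv", package = "kinicurate")
  }
  reg <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("name", "smarts", "residues")
  miss <- setdiff(need, names(reg))
  if (length(miss)) stop("warhead registry missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(reg) == 0) stop("warhead registry is empty")
  dup <- reg$name[duplicated(reg$name)]
  if (length(dup)) stop("duplicate warhead name(s) in registry: ",
                        paste(unique(dup), collapse = ", "))
  probe <- ChemmineR::smiles2sdf(c(probe = "CC"))
  for (i in seq_len(nrow(reg))) {
    ok <- tryCatch({
      suppressWarnings(suppressMessages(
        ChemmineR::smartsSearchOB(probe, reg$smarts[i], uniqueMatches = TRUE)))
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop("invalid SMARTS for warhead '", reg$name[i], "': ",
                  reg$smarts[i])
  }
  reg
}

#' Scan compounds for covalent warheads
#'
#' Substructure-matches every registry pattern against every compound. A
#' compound is flagged as a potential covalent inhibitor (CPKI) if at least
#' one pattern matches. The per-warhead histogram counts compounds, so a
#' compound bearing two distinct warheads contributes once to each bar.
#' The scan is a pure function of the compound set and registry, with
#' deterministic output order (registry order, then compound ID).
#'
#' @param compounds data.frame with columns `compound_new_id` and
#'   `compound_key` (standardized SMILES).
#' @param registry data.frame from [load_warhead_registry()].
#' @return list with `hits` (`compound_new_id`, `warhead_name`,
#'   `match_count`), `histogram` (`warhead_name`, `n_compounds`; warheads with
#'   no hits are absent), and `cpki` (`compound_new_id`, `cpki` logical).
#' @export
scan_warheads <- function(compounds, registry = load_warhead_registry()) {
  stopifnot(all(c("compound_new_id", "compound_key") %in% names(compounds)))
  n <- nrow(compounds)
  cpki <- data.frame(compound_new_id = compounds$compound_new_id,
                     cpki = rep(FALSE, n))
  if (n == 0) {
    return(list(hits = data.frame(compound_new_id = integer(0),
                                  warhead_name = character(0),
                                  match_count = integer(0)),
                histogram = data.frame(warhead_name = character(0),
                                       n_compounds = integer(0)),
                cpki = cpki))
  }
  smi <- stats::setNames(compounds$compound_key,
                         paste0("cmp", seq_len(n)))
  sdf <- suppressWarnings(suppressMessages(ChemmineR::smiles2sdf(smi)))
  hits <- list()
  for (i in seq_len(nrow(registry))) {
    cnt <- suppressWarnings(suppressMessages(
      ChemmineR::smartsSearchOB(sdf, registry$smarts[i], uniqueMatches = TRUE)))
    hit <- which(cnt > 0)
    if (length(hit)) {
      hits[[registry$name[i]]] <- data.frame(
        compound_new_id = compounds$compound_new_id[hit],
        warhead_name = registry$name[i],
        match_count = as.integer(cnt[hit]),
        stringsAsFactors = FALSE
      )
      cpki$cpki[hit] <- TRUE
    }
  }
  hits <- if (length(hits)) do.call(rbind, c(unname(hits),
                                             make.row.names = FALSE))
          else data.frame(compound_new_id = integer(0),
                          warhead_name = character(0),
                          match_count = integer(0))
  histogram <- if (nrow(hits)) {
    tb <- table(hits$warhead_name)
    ord <- intersect(registry$name, names(tb))
    data.frame(warhead_name = ord, n_compounds = as.integer(tb[ord]),
               stringsAsFactors = FALSE)
  } else {
    data.frame(warhead_name = character(0), n_compounds = integer(0))
  }
  list(hits = hits, histogram = histogram, cpki = cpki)
}
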