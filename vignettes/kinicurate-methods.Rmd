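---
title: "Curating kinase inhibitor activity data: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating kinase inhibitor activity data: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinicurate)
```

# The problem

Public bioactivity databases hold hundreds of thousands of measurements of
small molecules against protein kinases, but the raw records are heterogeneous:
different measurement types (IC50, Ki, Kd), censored relations (`>`, `>>`),
inconsistent units, salts and stereoisomeric drawings of the same compound,
assay annotations of varying reliability, and repeated — sometimes
contradictory — measurements of the same compound–kinase pair. `kinicurate`
implements a complete curation pipeline that turns two such raw exports (a
ChEMBL-like dialect and a BindingDB-like dialect) into a deduplicated,
per-pair annotated data set of active and inactive protein kinase inhibitors
(PKIs), together with an analogue-series decomposition and covalent-warhead
flags.

# Record qualification

Each input row is qualified independently, so qualification is a total,
deterministic, order-independent function of the record. ChEMBL-dialect rows
must target a single protein at assay confidence 9 and carry a non-blacklisted
activity comment and a consistent active/inactive label; BindingDB-dialect
rows must describe single-chain targets. Both dialects are restricted to the
three standard measurement types IC50, Ki and Kd.

The activity threshold is 10,000 nM (log potency 5.0):

* `=` measurements at or below the threshold are *active candidates*, above it
  *inactive candidates*. The boundary value itself (exactly 10,000 nM) is
  treated as active: the inactive class is defined by values strictly *larger*
  than the threshold.
* `>` / `>>` measurements are censored: they qualify as inactive evidence only
  when the reported bound is at least 10,000 nM. A `>` record below the
  threshold says nothing usable and is discarded, as is any `<` record — a
  left-censored value cannot yield a point potency, and an "active" call based
  on it could not be checked against the threshold.
* Units are normalized rather than filtered: rows in µM, mM, M or pM are
  converted to nM before qualification and counted in the report. Rows in
  non-concentration units are discarded.

The comment blacklist ships with the three standard phrases ("uncertain",
"potential transcription error", "outside typical range") and matches
case-insensitive substrings; the list is configuration and can be extended,
e.g. with "potential duplicate" style annotations, which are deliberately not
in the default.

Every discard carries a reason code, and the qualification report always
balances: rows read = rows qualified + discards.

# Standardization and merging

Compound identity is the *non-stereo canonical SMILES* after a fixed
standardization cascade: parse → keep the largest organic fragment (salt and
solvent stripping; carbon-containing components take precedence, ties broken
by heavy-atom count, then summed heavy-atom mass, then lexicographic SMILES)
→ neutralize protonation states → strip stereochemistry → canonical aromatic
SMILES. Neutralization covers ordinary ±1 protonation states; quaternary
ammonium and charge-separated groups such as nitro are retained. The order
(neutralize before stereo stripping, both after fragment selection) is fixed;
whether the original-source protocol used the same internal order is
unknowable from the outside, but the composite map is idempotent either way.

Records from both dialects whose SMILES standardize to the same key are merged
under one internal compound ID, assigned in lexicographic key order so that
reruns are bit-identical.

Tautomers are *not* canonicalized: two records drawn as different tautomers of
one compound remain distinct compounds. This is a known merge limitation of
the key definition.

# Per-pair aggregation

All qualified `=` measurements for one (compound, kinase) pair are pooled
across sources and grouped by measurement type. Potencies are transformed to
the negative decadic logarithm of the molar value (1 nM ↦ 9.0, 100 nM ↦ 7.0,
10,000 nM ↦ 5.0) and averaged *within type on the log scale* — consistent with
the dispersion gate, which is stated in logarithmic units: a type whose log
values have sample standard deviation (n−1 denominator; singletons exempt)
greater than 1 is invalid.

Among valid types the assay-independent binding constants are preferred over
IC50; between Kd and Ki, Kd is selected (this priority is a package choice —
either constant is assay-independent — and is configurable in principle via
the recorded `selected_stvalue`). The selected mean classifies the pair:
log potency ≥ 5.0 is ACTIVE, below is INACTIVE.

Two situations discard the entire pair:

* every measurement type fails the dispersion gate (`DISCARDED_SD`); such a
  pair is dropped rather than demoted to a qualitative annotation, because the
  measurements are mutually inconsistent, not merely censored;
* the pair is ACTIVE on quantitative evidence but also carries a censored
  `>`/`>>` record (`DISCARDED_CONFLICT`). A quantitatively *inactive* pair
  with censored records is not a conflict — both agree on inactivity.

A pair with only censored records is a qualitative inactive: status INACTIVE,
no numeric potency (exported as the literal `NaN`). A mixed-type disagreement
(say a valid active Ki and a valid inactive IC50) is resolved silently by the
type priority; no flag is raised, since the priority rule exists precisely to
arbitrate assay-dependent versus assay-independent evidence.

Surviving pairs are partitioned into four data sets by organism × status; a
compound can be active on one kinase and inactive on another, and then appears
in both sets.

# Analogue series

An analogue series (AS) is a set of ≥ 2 compounds sharing a core structure and
differing only in R-groups at one or more substitution sites. Series are
found through compound–core relationships: each compound is systematically
fragmented and all its candidate cores are enumerated; compounds sharing a
core are grouped.

*Fragmentation.* Bonds are cuttable when they are acyclic single bonds between
heavy atoms whose environment matches a retrosynthetic rule (amide, ester,
amine, ether, sulfonamide, ring–ring link, ring-to-substituent attachment —
the rule set is data and can be restricted). Cut sets of 1..k bonds (default
k = 2, matching the common two-site series picture) are enumerated; the
largest remaining fragment is the candidate core, the detached pieces are the
substituents, and every cut must separate a substituent directly from the
core. Conventional size constraints prune degenerate candidates: each
substituent ≤ 13 heavy atoms, core at least twice the combined substituent
heavy atoms. Both bounds and the cut cardinality are configurable; they are
conventional values, and no claim is made that they reproduce any particular
published series count obtained with other implementations of the idea.

*Core identity.* Attachment points are kept as isotope-labelled dummy atoms
(`[1*]`, `[2*]`). Site numbering is canonicalized by taking, over all
permutations of the labels, the lexicographically smallest canonical SMILES.
Because cores arise from cut bonds, every site of a series core bears a
non-hydrogen substituent in every member; the degenerate zero-site core (the
uncut molecule) can only ever cover one compound and is what singletons keep
as their core.

*Assignment.* The compound↔core bipartite map is resolved greedily: repeatedly
select the core covering the most remaining compounds (ties broken by larger
core, then lexicographic core SMILES), form a series, remove its members.
This yields a disjoint partition — each compound lands in exactly one series
or becomes a singleton — so the number of distinct cores always equals
series + singletons. The R-group table records, per member and site, the
substituent fragment, and reattaching a member's R-groups to the core
reconstructs that member's standardized SMILES exactly; this reassembly
invariant is enforced in the test suite.

# Covalent warheads

Potential covalent inhibitors are flagged by substructure search with a
registry of 14 warhead patterns (acrylamide, propiolamide, vinyl sulfone,
haloacetyl, epoxide, aziridine, maleimide, aldehyde, nitrile, boronic acid,
β-lactam, sulfonyl fluoride, heterocyclic urea, activated haloheteroarene).
The registry is an editable TSV of SMARTS patterns with the targeted residues;
only the acrylamide (Cys/Lys/Ser/Thr) and heterocyclic-urea (Ser/Thr) entries
are anchored to named literature classes, the other twelve are conventional
stand-ins for the usual covalent chemotypes, and per-class counts from other
registries are not expected to be reproduced. A compound is CPKI if any
pattern matches; the histogram counts compounds per warhead, so a
two-warhead compound contributes to two bars. By default only the human
active set is scanned; the scan can be widened to any compound set.

# Deposition output

Four TSV files (`human_PKI_active.tsv`, `human_PKI_inactive.tsv`,
`mouse_PKI_active.tsv`, `mouse_PKI_inactive.tsv`) carry the verbatim columns
`Compound_new_ID`, `nonstereo_aromatic_smile`, `Uniprot_ID`, `pref_name`,
`activity_id` (semicolon-joined record provenance, sorted), `mean_log`,
`selected_stvalue`, `ORGANISM`, plus `CPKI` in the human active file only.
`mean_log` is written with 10 significant digits, `NaN` for qualitative-only
pairs. Rows are ordered by compound ID then kinase, and files are
byte-identical across reruns and across write→read→write round trips.
Box-plot summaries of the potency distribution use type-7 (linear
interpolation) quartiles with Tukey 1.5 × IQR whiskers; values beyond the
fences are reported as outliers.

# The synthetic corpus generator

Because the pipeline's inputs are database exports that cannot be shipped or
downloaded reproducibly, the package generates its own corpora with recorded
ground truth (`generate_fixtures()`). Compounds are built by decorating 34
structurally distinct kinase-inhibitor-like scaffolds (two attachment sites
each) with R-groups from a small fragment library; the scaffolds are mutually
distinct under ≤ 2 cuts, which is what guarantees that planted series cannot
merge during extraction. True log potencies are drawn from a normal
distribution centred at 7 (≈ 100 nM, the typical mid-range of curated kinase
potencies, which mostly fall between log 6 and 8) with SD 0.8, and each pair
emits 1–4 measurements with log-scale noise of SD 0.2 — small enough that the
dispersion gate only fires when a violation is planted deliberately.

Configurable rates inject, at known positions: quantitatively inactive pairs,
censored-only pairs, conflicting pairs, over-dispersed measurement sets,
HCl-salt and enantiomer-flip and protonation-state record variants, µM-unit
rows, and non-qualifying decoys (off-type, low-confidence, blacklisted
comment, conflicting label, multi-chain). Ground truth — per-pair status and
mean log potency computed from the exact values written to the tables, series
membership, covalent flags, planted pathology counts — is recorded at
construction.

What the generator does *not* emulate: real export schemas beyond the
configured column mappings, kinome-scale target panels, assay-format
heterogeneity beyond log-normal noise, tautomeric drawings, and realistic
medicinal-chemistry R-group distributions. Passing the planted-truth tests
therefore demonstrates that the pipeline's logic implements its stated rules
exactly, not that any particular published corpus statistic would be
reproduced from live database snapshots.

# Numerical and determinism choices

* Potency logs are `9 − log10(value in nM)`; means on the log scale.
* Sample SD (n−1); a single measurement never triggers the gate.
* All lexicographic orderings (compound IDs, tie-breaks, provenance joins)
  use C-locale radix sorting, so results do not depend on the session locale.
* Fixture generation saves and restores the global RNG state and is
  bit-reproducible for a given spec.
* Problem sizes used by the shipped tests and the acceptance script — a
  corpus of 20 series (3–6 members), 10 singletons and 8 kinases, a
  standardization panel of ≥ 200 decorated molecules, 1000 randomized
  aggregation sets, and 100 randomized series sets of ≤ 20 molecules — were
  chosen as the smallest sizes at which every rule and pathology path is
  exercised multiple times.

# Known limitations

* No tautomer or protomer canonicalization in the merge key.
* The retrosynthetic rule set and the CCR size constraints are conventional,
  not calibrated against any external series catalogue.
* Warhead SMARTS beyond the two named classes are representative stand-ins.
* No assay-level weighting or error propagation beyond the SD gate; no
  curve refitting; censored records contribute no numeric potency.
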