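# kinicurate

Curation, aggregation and analogue-series analysis of protein kinase
inhibitor (PKI) activity data in R.

## What it does

Raw kinase bioactivity exports are messy: IC50/Ki/Kd measurements in mixed
units and relations, salts and stereoisomeric drawings of one compound,
unreliable assay annotations, and repeated or contradictory measurements per
compound–kinase pair. `kinicurate` turns two such tab-separated exports — a
ChEMBL-like dialect and a BindingDB-like dialect — into a curated data set:

1. **Qualification** — keeps single-protein, high-confidence (score 9)
   IC50/Ki/Kd records in nM-convertible units, drops blacklisted comments,
   inconsistent labels and uninformative censored relations; every discard is
   counted by reason and the report always balances.
2. **Standardization & merging** — each SMILES is reduced to a non-stereo
   canonical key (largest organic fragment → neutralize → strip stereo →
   canonical aromatic SMILES); records from both sources merge on the key.
3. **Aggregation** — per (compound, kinase) pair, `=` measurements are pooled
   by type and averaged as negative decadic log molar potency,
   `pPot = 9 − log10(value/nM)`; a type with log-SD > 1 is rejected;
   assay-independent Kd/Ki outrank IC50; pairs with conflicting quantitative
   and censored evidence, or nothing but over-dispersed types, are discarded.
4. **Classification** — selected mean log potency ≥ 5.0 (≤ 10,000 nM) is
   ACTIVE, below is INACTIVE; censored-only pairs are qualitative inactives.
5. **Analogue series** — retrosynthetic fragmentation (RECAP-style cuttable
   bonds, up to 2 cuts) enumerates every compound's candidate cores; a greedy
   compound–core intersection partitions the set into series and singletons,
   with per-member R-group tables that reassemble each member exactly.
6. **Warheads** — 14 covalent warhead SMARTS patterns (registry shipped as
   editable data) flag potential covalent inhibitors (CPKI) in the human
   active set.
7. **Export** — the four-file deposition schema (`human_PKI_active.tsv`,
   `human_PKI_inactive.tsv`, `mouse_PKI_active.tsv`, `mouse_PKI_inactive.tsv`)
   with verbatim column names, plus a readme and a JSON summary (potency
   distribution, series counts, warhead histogram, kinome coverage).

A seeded synthetic-corpus generator (`generate_fixtures()`) plants analogue
series, potencies, decorated record variants and curation pathologies with
recorded ground truth, so the whole pipeline is testable without any database
download. Chemistry (canonical SMILES, neutralization, substructure search)
runs on Open Babel via ChemmineR/ChemmineOB.

## Worked example

```r
library(kinicurate)

fx <- generate_fixtures(fixture_spec(seed = 3, n_series = 3, n_singletons = 2,
                                     n_kinases = 6), out_dir = "corpus")
res <- run_pipeline(fx$paths["chembl"], fx$paths["bindingdb"],
                    fx$paths["kinases"], out_dir = "curated")
s <- res$summary
cat("records qualified:", res$report$n_qualified, "of", res$report$n_read, "\n")
cat("unique compounds: ", nrow(res$compounds), "\n")
cat("human active pairs:", s$human$n_active_interactions,
    "| median log potency:", round(s$human$potency$median, 2), "\n")
cat("analogue series:   ", s$analog_series$n_series,
    "| singletons:", s$analog_series$n_singletons,
    "| distinct cores:", s$analog_series$n_distinct_cores, "\n")
cat("covalent (CPKI):   ", s$warheads$n_cpki, "\n")
```

prints

```
records qualified: 51 of 51
unique compounds:  16
human active pairs: 17 | median log potency: 7.52
analogue series:    3 | singletons: 2 | distinct cores: 5
covalent (CPKI):    2
```

Reading the numbers: the 51 generated records collapse to 16 unique compounds
after salt/stereo/charge standardization; 17 human compound–kinase pairs are
active at the 10 µM threshold with a median potency near log 7.5 (~30 nM);
the three planted three-to-four-member series and both singletons are
recovered exactly (distinct cores = series + singletons), and the two
compounds carrying the planted acrylamide R-group are flagged CPKI.
`curated/` now holds the four deposition TSVs, `readme.txt` and
`summary.json`.

A thin CLI wraps the same functions
(`inst/scripts/kinicurate {fixtures,ingest,analogs,warheads,run}`).

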