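Curated protein kinase inhibitor (PKI) data sets
================================================

Four tab-separated files, one row per compound-kinase pair:

  human_PKI_active.tsv    {{human_active_pairs}} pairs, {{human_active_compounds}} compounds
  human_PKI_inactive.tsv  {{human_inactive_pairs}} pairs, {{human_inactive_compounds}} compounds
  mouse_PKI_active.tsv    {{mouse_active_pairs}} pairs, {{mouse_active_compounds}} compounds
  mouse_PKI_inactive.tsv  {{mouse_inactive_pairs}} pairs, {{mouse_inactive_compounds}} compounds

Columns:
  Compound_new_ID           internal ID assigned to each compound
  nonstereo_aromatic_smile  standardized compound SMILES
  Uniprot_ID                UniProtKB kinase accession
  pref_name                 preferred/full name of the kinase
  activity_id               reference to the source activity records
  mean_log                  mean negative logarithmic potency value
                            (NaN: qualitative measurement)
  selected_stvalue          standard value used (Kd, Ki, IC50, qualitative)
  ORGANISM                  organism of the kinase
  CPKI                      warhead flag (human active file only):
                            True if the compound contains a covalent warhead

Activity classification uses a 10,000 nM threshold (log potency 5.0).
Generated by the kinicurate package.
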