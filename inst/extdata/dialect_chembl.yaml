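dialect: chembl
columns:
  record_id: activity_id
  compound_smiles: canonical_smiles
  kinase_uniprot: accession
  measurement_type: standard_type
  relation: standard_relation
  value: standard_value
  units: standard_units
  target_category: target_type
  confidence_score: confidence_score
  activity_comment: activity_comment
  activity_label: activity_label
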