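dialect: bindingdb
columns:
  record_id: reactant_set_id
  compound_smiles: ligand_smiles
  kinase_uniprot: uniprot_id
  measurement_type: measurement_type
  relation: relation
  value: value_nM
  n_chains: n_protein_chains
constants:
  units: nM
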