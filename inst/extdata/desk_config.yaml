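# Default desk-scale screen configuration: 384-well plates, four siRNAs per
# gene in quadruplicate, published exclusion and hit thresholds.
plate_format: 384
sirnas_per_gene: 4
replicates: 4
control_layout:
  neg_ctrl: 8
  pos_ctrl_pathway: 4
  pos_ctrl_receptor: 4
  tox_ctrl: 4
thresholds:
  plate_viability_hi: 2.5
  plate_viability_lo: 0.2
  plate_viability_cv: 0.5
  well_viability_frac: 0.4
  validation_sd: 2.0
  thp1_sd: 1.5
  thp1_strong_sd: 3.0
zscore_scale: sample_mad
npi_pos_role: pos_ctrl_pathway
validation_gene_rule: strongest
rng_seed: 1
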